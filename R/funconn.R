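#' Sliding-window specification
#'
#' Defines the sliding-window functional-connectivity analysis: windows of
#' `length_l` volumes advanced by `step` volumes (default 15 and 1, i.e. a
#' 14-volume overlap; with `delta_t = 2` s volumes each window spans 30 s
#' and consecutive windows overlap by 28 s).
#'
#' @param length_l window length in volumes (`>= 2`).
#' @param step window advance in volumes (`1 <= step <= length_l`).
#' @param delta_t volume spacing in seconds (default 2).
#' @return A list of class `"window_spec"` with derived `duration_s` and
#'   `overlap_s`.
#' @export
window_spec <- function(length_l = 15, step = 1, delta_t = 2) {
  length_l <- as.integer(length_l); step <- as.integer(step)
  if (length_l < 2L) stop("'length_l' must be >= 2")
  if (step < 1L || step > length_l) stop("'step' must be in [1, length_l]")
  structure(list(length_l = length_l, step = step, delta_t = delta_t,
                 duration_s = length_l * delta_t,
                 overlap_s = (length_l - step) * delta_t),
            class = "window_spec")
}

#' Number of sliding windows
#'
#' `floor((n_vol - length_l)/step) + 1`; e.g. 128 volumes with a 15-volume
#' window advanced by 1 give 114 windows.
#'
#' @param n_vol number of volumes.
#' @param spec a [window_spec()].
#' @return Integer window count.
#' @export
n_windows <- function(n_vol, spec = window_spec()) {
  if (n_vol < spec$length_l) stop("fewer volumes than one window length")
  as.integer((n_vol - spec$length_l) %/% spec$step + 1L)
}

#' Sliding-window Pearson functional connectivity
#'
#' For each window, computes the Pearson correlation between every pair of
#' node signals over the in-window volumes, yielding a sequence of
#' symmetric functional adjacency matrices `A^win` with unit diagonal.
#' Window `win` (1-based) covers volumes
#' `(win-1)*step + 1 ... (win-1)*step + length_l`.
#'
#' A node that is constant within a window has no defined correlation
#' there; its off-diagonal entries are set to 0 for that window and a
#' warning names the node and window (a deterministic fallback, so long
#' ensemble runs do not abort on degenerate windows).
#'
#' @param Y a `"bold_ts"` (see [bold_transform()] / [bold_ts()]).
#' @param spec a [window_spec()].
#' @return An object of class `"fc_sequence"`: list with `matrices` (list
#'   of `N x N` matrices), `window_start_times`, and `spec`.
#' @export
sliding_window_corr <- function(Y, spec = window_spec()) {
  stopifnot(inherits(Y, "bold_ts"), inherits(spec, "window_spec"))
  n_vol <- ncol(Y$y)
  nw <- n_windows(n_vol, spec)
  mats <- vector("list", nw)
  starts <- numeric(nw)
  for (win in seq_len(nw)) {
    idx <- (win - 1L) * spec$step + seq_len(spec$length_l)
    seg <- t(Y$y[, idx, drop = FALSE])          # l x N
    sds <- apply(seg, 2L, stats::sd)
    degenerate <- which(sds == 0)
    A <- suppressWarnings(cor(seg))
    if (length(degenerate)) {
      warning(sprintf("zero within-window variance: node(s) %s in window %d; correlations set to 0",
                      paste(degenerate, collapse = ","), win))
      A[degenerate, ] <- 0
      A[, degenerate] <- 0
    }
    diag(A) <- 1
    mats[[win]] <- A
    starts[win] <- Y$times[idx[1L]]
  }
  structure(list(matrices = mats, window_start_times = starts, spec = spec),
            class = "fc_sequence")
}

#' @export
print.fc_sequence <- function(x, ...) {
  cat(sprintf("Functional matrix sequence: %d windows of %d volumes (step %d), %d nodes\n",
              length(x$matrices), x$spec$length_l, x$spec$step,
              nrow(x$matrices[[1]])))
  invisible(x)
}
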
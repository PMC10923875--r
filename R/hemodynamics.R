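#' Balloon-Windkessel hemodynamic parameters
#'
#' Parameters of the hemodynamic forward model that converts normalized
#' neural activity into BOLD-like signals. Per node, a flow-inducing signal
#' `s`, normalized inflow `f_in`, venous volume `v` and deoxyhemoglobin
#' content `q` evolve as
#' \deqn{\dot s = \epsilon_B \hat u - s/\tau_s - (f_{in}-1)/\tau_f,\quad
#'       \dot f_{in} = s,}
#' \deqn{\dot v = (f_{in} - v^{1/\alpha})/\tau_0,\quad
#'       \dot q = (E(f_{in})/E_0 - v^{1/\alpha} q/v)/\tau_0,}
#' with oxygen extraction \eqn{E(f_{in}) = 1 - (1-E_0)^{1/f_{in}}}, and the
#' BOLD observation
#' \deqn{y = V_0 [k_1(1-q) + k_2(1-q/v) + k_3(1-v)],}
#' where \eqn{k_1 = 7E_0}, \eqn{k_2 = 2}, \eqn{k_3 = 2E_0 - 0.2}.
#'
#' The flow-volume exponent is taken literally as `inv_alpha` (default
#' 0.32), i.e. `f_out(v) = v^0.32`. Much of the hemodynamic-modeling
#' literature instead uses Grubb's exponent alpha ~ 0.32 with
#' `f_out = v^(1/alpha)`; set `grubb_alpha = TRUE` for that reading.
#'
#' @param tau0 mean venous transit time in seconds (default 0.98).
#' @param E0 resting oxygen extraction fraction in (0,1) (default 0.34).
#' @param V0 resting blood volume fraction (default 0.02).
#' @param inv_alpha flow-volume exponent as printed (default 0.32).
#' @param tau_s signal-decay time constant in seconds (default 0.65).
#' @param tau_f flow-feedback time constant in seconds (default 0.41).
#' @param epsilon_B neural efficacy: the efficiency with which activity
#'   raises the flow signal (default 0.5; configurable, no canonical value).
#' @param grubb_alpha if `TRUE`, use `f_out(v) = v^(1/inv_alpha)` instead
#'   of `v^inv_alpha`.
#' @return A list of class `"balloon_params"` including derived `k1`, `k2`,
#'   `k3` and the effective `exponent`.
#' @export
balloon_params <- function(tau0 = 0.98, E0 = 0.34, V0 = 0.02,
                           inv_alpha = 0.32, tau_s = 0.65, tau_f = 0.41,
                           epsilon_B = 0.5, grubb_alpha = FALSE) {
  if (tau0 <= 0 || tau_s <= 0 || tau_f <= 0) stop("time constants must be > 0")
  if (E0 <= 0 || E0 >= 1) stop("'E0' must be in (0, 1)")
  if (V0 <= 0) stop("'V0' must be > 0")
  if (inv_alpha <= 0) stop("'inv_alpha' must be > 0")
  structure(list(tau0 = tau0, E0 = E0, V0 = V0, inv_alpha = inv_alpha,
                 tau_s = tau_s, tau_f = tau_f, epsilon_B = epsilon_B,
                 exponent = if (grubb_alpha) 1 / inv_alpha else inv_alpha,
                 k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2),
            class = "balloon_params")
}

#' Z-score a neural activity series
#'
#' Standardizes a series over its whole span: `(u - mean(u)) / SD(u)` with
#' the population standard deviation (divide by `n`). The result has mean 0
#' and SD 1 and is invariant to positive affine transforms of the input.
#'
#' @param u_series numeric vector, length >= 2, non-constant.
#' @param node label used in the zero-variance error message.
#' @return Standardized numeric vector.
#' @export
normalize_activity <- function(u_series, node = NA) {
  n <- length(u_series)
  if (n < 2L) stop("series too short to standardize")
  mu <- mean(u_series)
  s <- sqrt(sum((u_series - mu)^2) / n)
  if (s == 0)
    stop("constant activity series (zero SD)",
         if (!is.na(node)) paste0(" at node ", node) else "")
  (u_series - mu) / s
}

#' BOLD observation equation
#'
#' `y = V0 * (k1*(1 - q) + k2*(1 - q/v) + k3*(1 - v))`. Vectorized over
#' `v` and `q`.
#'
#' @param v normalized venous volume (`> 0`).
#' @param q normalized deoxyhemoglobin content.
#' @param params a [balloon_params()].
#' @return BOLD-like signal value(s); 0 at rest (`v = q = 1`).
#' @export
bold_signal <- function(v, q, params = balloon_params()) {
  stopifnot(inherits(params, "balloon_params"))
  if (any(v <= 0)) stop("'v' must be > 0")
  params$V0 * (params$k1 * (1 - q) + params$k2 * (1 - q / v) +
                 params$k3 * (1 - v))
}

#' Balloon-Windkessel right-hand side
#'
#' Reference R evaluation of the hemodynamic state derivative for one node;
#' the compiled integrator in [bold_transform()] is cross-checked against
#' it. The resting state `(s, f_in, v, q) = (0, 1, 1, 1)` is an exact fixed
#' point under zero drive.
#'
#' @param state list or named vector with `s`, `f_in`, `v`, `q`
#'   (`f_in, v, q > 0`).
#' @param u_hat normalized neural drive at this instant.
#' @param params a [balloon_params()].
#' @return Named list of derivatives `ds`, `df_in`, `dv`, `dq`.
#' @export
hemo_rhs <- function(state, u_hat, params = balloon_params()) {
  s <- state[["s"]]; f_in <- state[["f_in"]]; v <- state[["v"]]; q <- state[["q"]]
  if (f_in <= 0 || v <= 0 || q <= 0)
    stop("'f_in', 'v' and 'q' must be > 0")
  fout <- v^params$exponent
  E <- 1 - (1 - params$E0)^(1 / f_in)
  list(ds = params$epsilon_B * u_hat - s / params$tau_s - (f_in - 1) / params$tau_f,
       df_in = s,
       dv = (f_in - fout) / params$tau0,
       dq = (E / params$E0 - fout * q / v) / params$tau0)
}

#' Integrate the hemodynamic model under a prescribed drive
#'
#' Advances the Balloon-Windkessel states of each node from rest
#' `(s, f_in, v, q) = (0, 1, 1, 1)` under an already-normalized drive
#' matrix, with fixed-step RK4 (drive linearly interpolated at substeps),
#' and returns the BOLD observation on the same dense grid. This is the
#' core used by [bold_transform()]; calling it directly is useful for
#' fixed-point and convergence analyses where the drive is prescribed
#' rather than derived from a neural trajectory.
#'
#' @param uhat `n_nodes x (n_steps + 1)` matrix of normalized drive values
#'   on a uniform grid of step `dt`.
#' @param dt grid step in seconds.
#' @param params a [balloon_params()].
#' @return `n_nodes x (n_steps + 1)` matrix of BOLD-like signal `y` on the
#'   dense grid (0 in the first column: the resting observation).
#' @export
hemo_integrate <- function(uhat, dt, params = balloon_params()) {
  stopifnot(inherits(params, "balloon_params"))
  uhat <- as.matrix(uhat)
  if (dt <= 0) stop("'dt' must be > 0")
  if (ncol(uhat) < 2L) stop("need at least two grid points")
  hemo_integrate_cpp(uhat, dt, params$tau0, params$E0, params$V0,
                     params$exponent, params$tau_s, params$tau_f,
                     params$epsilon_B, params$k1, params$k2, params$k3)
}

#' Transform a neural trajectory into BOLD-like time series
#'
#' For each node, the activator series is z-scored over the whole span
#' ([normalize_activity()]), fed through the Balloon-Windkessel ODEs
#' integrated with fixed-step RK4 at the trajectory's `dt` from the resting
#' state (drive linearly interpolated between neural grid points at RK4
#' substeps), converted to `y` by the BOLD observation equation on the
#' dense grid, and point-sampled at `t = TR, 2*TR, ...` — one volume at the
#' end of each repetition time, with no volume at `t = 0` and no
#' anti-alias filtering.
#'
#' @param traj an `"fhn_trajectory"` from [fhn_integrate()].
#' @param params a [balloon_params()].
#' @param TR repetition time in seconds (default 2); must be an integer
#'   multiple of the trajectory `dt`.
#' @return An object of class `"bold_ts"`: list with `times` (TR grid),
#'   `y` (`n_nodes x n_vol` matrix), `TR`, and `meta`. Nodes are
#'   hemodynamically independent: node i's `y` depends only on node i's
#'   activator series.
#' @export
bold_transform <- function(traj, params = balloon_params(), TR = 2) {
  stopifnot(inherits(traj, "fhn_trajectory"), inherits(params, "balloon_params"))
  dt <- traj$meta$dt
  stride <- TR / dt
  if (abs(stride - round(stride)) > 1e-8)
    stop("'TR' must be an integer multiple of the trajectory dt")
  stride <- round(stride)
  n <- nrow(traj$u)
  uhat <- traj$u
  for (k in seq_len(n)) uhat[k, ] <- normalize_activity(traj$u[k, ], node = k)
  y_dense <- hemo_integrate(uhat, dt, params)
  n_vol <- (ncol(uhat) - 1L) %/% stride
  if (n_vol < 1L) stop("trajectory shorter than one TR")
  idx <- 1L + stride * seq_len(n_vol)
  structure(list(times = traj$times[idx],
                 y = y_dense[, idx, drop = FALSE],
                 TR = TR,
                 meta = list(dt = dt, params = params,
                             source = traj$meta$seed)),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("BOLD time series: %d nodes, %d volumes at TR = %g s\n",
              nrow(x$y), ncol(x$y), x$TR))
  invisible(x)
}

#' Construct a BOLD time-series object from a matrix
#'
#' Wraps an existing node-by-volume matrix (e.g. empirical ROI signals read
#' from CSV) so that it can enter the sliding-window pipeline.
#'
#' @param y `n_nodes x n_vol` numeric matrix.
#' @param TR repetition time in seconds.
#' @param times optional sample times; defaults to `TR, 2*TR, ...`.
#' @return A `"bold_ts"` object.
#' @export
bold_ts <- function(y, TR = 2, times = NULL) {
  y <- as.matrix(y)
  if (!is.numeric(y) || anyNA(y)) stop("'y' must be a numeric matrix without NAs")
  if (is.null(times)) times <- TR * seq_len(ncol(y))
  if (length(times) != ncol(y)) stop("'times' length must equal ncol(y)")
  structure(list(times = times, y = unname(y), TR = TR, meta = list()),
            class = "bold_ts")
}
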
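#' A-priori module template
#'
#' A binary `N x P` matrix `M` with `m_ij = 1` iff region i belongs to
#' a-priori module j (e.g. 246 atlas regions against 15 canonical
#' functional networks). Every module must contain at least one region.
#' Single membership per region is the typical case, but multi-membership
#' binary templates are accepted.
#'
#' @param M binary numeric matrix (`N x P`).
#' @param module_labels optional labels for the P modules.
#' @return An object of class `"module_template"`: list with `M`,
#'   `module_sizes` (column sums `K_j`), `module_labels`, `n_regions`,
#'   `n_modules`.
#' @export
module_template <- function(M, module_labels = NULL) {
  M <- as.matrix(M)
  if (!all(M %in% c(0, 1))) stop("template entries must be 0 or 1")
  K <- colSums(M)
  if (any(K < 1)) stop("empty module(s): ", paste(which(K < 1), collapse = ", "))
  if (is.null(module_labels)) module_labels <- paste0("M", seq_len(ncol(M)))
  if (length(module_labels) != ncol(M)) stop("'module_labels' length mismatch")
  dimnames(M) <- NULL
  structure(list(M = M, module_sizes = unname(K),
                 module_labels = as.character(module_labels),
                 n_regions = nrow(M), n_modules = ncol(M)),
            class = "module_template")
}

#' Read a module template from a text file
#'
#' Accepts either a two-column TSV `region_id<TAB>module_id` (1-based, each
#' region listed exactly once) or a full binary matrix CSV (regions in
#' rows, modules in columns).
#'
#' @param path file to read.
#' @param n_regions,n_modules optional totals for the mapping format
#'   (default: maxima present in the file).
#' @return A [module_template()].
#' @export
read_template <- function(path, n_regions = NULL, n_modules = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, sep = sep, header = FALSE)
  if (sep == "\t" && ncol(tab) == 2L) {   # mapping format is TSV-only; CSV is always a matrix
    region <- as.integer(tab[[1]]); module <- as.integer(tab[[2]])
    n <- if (is.null(n_regions)) max(region) else as.integer(n_regions)
    p <- if (is.null(n_modules)) max(module) else as.integer(n_modules)
    if (any(region < 1L | region > n)) stop("unknown region id in template")
    if (any(module < 1L | module > p)) stop("unknown module id in template")
    if (anyDuplicated(region)) stop("region listed more than once in mapping template")
    if (length(region) < n) stop("region(s) missing from mapping template")
    M <- matrix(0, n, p)
    M[cbind(region, module)] <- 1
    module_template(M)
  } else {
    module_template(as.matrix(tab))
  }
}

#' Generate a synthetic module template
#'
#' Assigns each of `N` regions to exactly one of `P` modules, uniformly at
#' random but guaranteeing every module is non-empty (the first P regions
#' seed the P modules before the rest are assigned). Reproducible by seed.
#'
#' @param n_regions number of regions `N` (`>= n_modules`).
#' @param n_modules number of modules `P` (`>= 1`).
#' @param seed integer seed.
#' @return A [module_template()] with row sums 1 and column sums >= 1.
#' @export
generate_synthetic_template <- function(n_regions, n_modules, seed = 1) {
  if (n_modules < 1L || n_regions < n_modules)
    stop("need n_regions >= n_modules >= 1")
  assign <- with_seed(seed, {
    a <- integer(n_regions)
    a[seq_len(n_modules)] <- sample.int(n_modules)   # every module non-empty
    if (n_regions > n_modules)
      a[(n_modules + 1L):n_regions] <- sample.int(n_modules,
                                                  n_regions - n_modules,
                                                  replace = TRUE)
    a
  })
  M <- matrix(0, n_regions, n_modules)
  M[cbind(seq_len(n_regions), assign)] <- 1
  module_template(M)
}

#' Node-to-module affiliation strengths
#'
#' `H' = |A| %*% M` — the total absolute functional weight each node has
#' into every a-priori module — followed by per-module normalization
#' `h_ij = h'_ij / K_j` by module size. The diagonal of `|A|` is included,
#' as the definition sums over all elements.
#'
#' @param A `N x N` functional matrix (one sliding window).
#' @param M a [module_template()].
#' @return `N x P` matrix `H` of normalized affiliation strengths.
#' @export
module_strengths <- function(A, M) {
  stopifnot(inherits(M, "module_template"))
  A <- as.matrix(A)
  if (nrow(A) != M$n_regions || ncol(A) != M$n_regions)
    stop("functional matrix size must match template regions")
  Hp <- abs(A) %*% M$M
  sweep(Hp, 2L, M$module_sizes, "/")
}

#' Dominant module affiliation per node
#'
#' Per node, the label of the module with the largest affiliation strength
#' (row-wise argmax of `H`); ties go to the smallest module index, so the
#' assignment is deterministic.
#'
#' @param H `N x P` affiliation-strength matrix from [module_strengths()].
#' @return Integer vector of length `N` with module labels in `1..P`.
#' @export
affiliation_vector <- function(H) {
  H <- as.matrix(H)
  if (anyNA(H) || any(!is.finite(H))) stop("'H' must be finite")
  max.col(H, ties.method = "first")
}

#' Template flexibility between two windows
#'
#' The fraction of nodes whose dominant a-priori module affiliation differs
#' between two consecutive windows:
#' `F = 1 - (1/N) * sum_i delta(omega_i_prev, omega_i_cur)`. Values lie on
#' the lattice `{0, 1/N, ..., 1}`.
#'
#' @param omega_prev,omega_cur affiliation vectors of equal length (from
#'   [affiliation_vector()]).
#' @return A value in `[0, 1]`, an integer multiple of `1/N`.
#' @export
template_flexibility <- function(omega_prev, omega_cur) {
  if (length(omega_prev) != length(omega_cur))
    stop("affiliation vectors must have equal length")
  1 - mean(omega_prev == omega_cur)
}

#' Distance flexibility between two windows
#'
#' The Pearson distance between two consecutive functional matrices:
#' 1 minus the Pearson correlation computed over all `N^2` elements
#' (diagonal included, as the definition sums over all i, j). A
#' template-free global measure of network reconfiguration in `[0, 2]`.
#'
#' @param A_prev,A_cur functional matrices of identical shape, each with
#'   nonzero element variance.
#' @return A value in `[0, 2]`.
#' @export
distance_flexibility <- function(A_prev, A_cur) {
  A_prev <- as.matrix(A_prev); A_cur <- as.matrix(A_cur)
  if (!identical(dim(A_prev), dim(A_cur))) stop("matrices must have the same shape")
  a <- as.vector(A_prev); b <- as.vector(A_cur)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate window: functional matrix has zero element variance")
  1 - cor(a, b)
}

#' Flexibility time series from a functional-matrix sequence
#'
#' Applies [template_flexibility()] (when a template is supplied) and
#' [distance_flexibility()] to every pair of consecutive windows,
#' producing series of length `n_windows - 1` indexed by window pair
#' `(win-1, win)`.
#'
#' @param seq an `"fc_sequence"` from [sliding_window_corr()] (>= 2
#'   windows).
#' @param M optional [module_template()]; required for the template series.
#' @return A list of class `"flexibility_series"` with elements `template`
#'   (numeric or `NULL`), `distance` (numeric), `pair_times` (start time of
#'   the later window of each pair), and `n_nodes`.
#' @export
flexibility_series <- function(seq, M = NULL) {
  stopifnot(inherits(seq, "fc_sequence"))
  nw <- length(seq$matrices)
  if (nw < 2L) stop("need at least 2 windows")
  dist <- numeric(nw - 1L)
  templ <- NULL
  if (!is.null(M)) {
    stopifnot(inherits(M, "module_template"))
    omegas <- lapply(seq$matrices,
                     function(A) affiliation_vector(module_strengths(A, M)))
    templ <- vapply(seq_len(nw - 1L), function(i)
      template_flexibility(omegas[[i]], omegas[[i + 1L]]), numeric(1))
  }
  for (i in seq_len(nw - 1L))
    dist[i] <- distance_flexibility(seq$matrices[[i]], seq$matrices[[i + 1L]])
  structure(list(template = templ, distance = dist,
                 pair_times = seq$window_start_times[-1L],
                 n_nodes = nrow(seq$matrices[[1]])),
            class = "flexibility_series")
}

#' @export
print.flexibility_series <- function(x, ...) {
  cat(sprintf("Flexibility series: %d window pairs%s\n", length(x$distance),
              if (is.null(x$template)) " (distance only)" else ""))
  invisible(x)
}
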
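#' Structural connectome objects
#'
#' A structural connectome is a weighted, undirected anatomical network:
#' an `N x N` symmetric, nonnegative weight matrix with zero diagonal
#' (self-tracts are excluded), typically derived from diffusion imaging
#' streamline counts. It couples the region-level oscillators of
#' [fhn_integrate()].
#'
#' @param weights square numeric matrix of nonnegative weights; must be
#'   symmetric to within `tol` and have an exactly zero diagonal.
#' @param node_labels optional character vector of region identifiers;
#'   defaults to `"R1" ... "RN"`.
#' @param tol symmetry tolerance (maximum allowed `|g_kl - g_lk|`).
#' @return An object of class `"connectome"`: a list with elements
#'   `weights` (the symmetrized matrix), `node_labels` and `n_nodes`.
#' @examples
#' G <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
#' G$n_nodes
#' @export
connectome <- function(weights, node_labels = NULL, tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("'weights' must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("connectome matrix must be square, got ", n, " x ", ncol(weights))
  if (n < 2L) stop("a connectome needs at least 2 nodes")
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("connectome weights must be finite")
  dev <- max(abs(weights - t(weights)))
  if (dev > tol)
    stop(sprintf("connectome matrix is asymmetric: max |g_kl - g_lk| = %g exceeds tolerance %g",
                 dev, tol))
  if (any(weights < 0))
    stop("connectome weights must be nonnegative")
  if (any(diag(weights) != 0))
    stop("connectome diagonal must be zero (self-coupling is excluded)")
  if (is.null(node_labels)) node_labels <- paste0("R", seq_len(n))
  if (length(node_labels) != n)
    stop("'node_labels' length must equal the number of nodes")
  w <- (weights + t(weights)) / 2          # remove sub-tolerance asymmetry
  dimnames(w) <- NULL
  structure(list(weights = w, node_labels = as.character(node_labels),
                 n_nodes = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Structural connectome: %d nodes, %d edges, total weight %.4g\n",
              x$n_nodes, sum(x$weights[upper.tri(x$weights)] > 0),
              sum(x$weights) / 2))
  invisible(x)
}

#' Read a structural connectome from a text file
#'
#' Two formats are supported. `"dense"`: a square numeric CSV/TSV matrix,
#' optionally preceded by a single header row of region labels. `"edgelist"`:
#' a three-column TSV `node_a<TAB>node_b<TAB>weight` with 1-based node
#' indices, each undirected pair listed at most once; entries are mirrored
#' into both triangles.
#'
#' @param path file to read.
#' @param format `"dense"` or `"edgelist"`.
#' @param n_nodes for `"edgelist"`, the declared number of nodes (defaults
#'   to the largest index present).
#' @return A [connectome()] object.
#' @export
read_connectome <- function(path, format = c("dense", "edgelist"),
                            n_nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    has_header <- anyNA(suppressWarnings(as.numeric(first)))
    m <- as.matrix(read.table(path, sep = sep, header = has_header,
                              check.names = FALSE))
    labels <- if (has_header) colnames(m) else NULL
    storage.mode(m) <- "double"
    connectome(m, node_labels = labels)
  } else {
    ed <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("node_a", "node_b", "weight"))
    if (nrow(ed) == 0L) stop("empty edge list")
    a <- as.integer(ed$node_a); b <- as.integer(ed$node_b)
    if (any(a == b)) stop("edge list contains a self-loop (zero diagonal required)")
    n <- if (is.null(n_nodes)) max(a, b) else as.integer(n_nodes)
    if (max(a, b) > n) stop("edge index exceeds declared n_nodes")
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key))
      stop("duplicate undirected edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
    w <- matrix(0, n, n)
    w[cbind(a, b)] <- ed$weight
    w[cbind(b, a)] <- ed$weight
    connectome(w)
  }
}

#' Write a connectome as a dense CSV matrix
#'
#' @param G a [connectome()] object.
#' @param path output file; a single header row carries the node labels.
#' @export
write_connectome <- function(G, path) {
  stopifnot(inherits(G, "connectome"))
  m <- G$weights
  colnames(m) <- G$node_labels
  write.table(m, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Generate a synthetic modular connectome
#'
#' Emulates the gross statistics of a group-averaged diffusion-imaging
#' connectome: heavy-tailed (log-normal) nonnegative symmetric weights with
#' modular block structure and zero diagonal. Nodes are split into
#' `n_modules` contiguous blocks of near-equal size; within-block edges draw
#' their scale from `intra_weight_scale`, between-block edges from
#' `inter_weight_scale`, and every weight is multiplied by mean-one
#' log-normal noise `exp(sigma*Z - sigma^2/2)`.
#'
#' The default scales give a typical node strength (weighted degree) of
#' order one, the usual normalization convention when a structural matrix
#' feeds a coupled-oscillator model through a single global coupling
#' constant.
#'
#' @param n_nodes number of regions (`>= 2`).
#' @param n_modules number of structural modules (`>= 1`).
#' @param intra_weight_scale,inter_weight_scale expected weight of
#'   within-module / between-module edges (both `> 0`).
#' @param lognormal_sigma log-scale standard deviation of the multiplicative
#'   noise; `0` gives deterministic weights.
#' @param density probability that a node pair is connected, in `(0, 1]`.
#' @param seed integer seed; the result is bit-reproducible for a fixed seed.
#' @return A [connectome()] object with a `modules` attribute giving the
#'   block assignment.
#' @examples
#' G <- generate_synthetic_connectome(20, 2, seed = 1)
#' @export
generate_synthetic_connectome <- function(n_nodes, n_modules = 4,
                                          intra_weight_scale = 0.04,
                                          inter_weight_scale = 0.01,
                                          lognormal_sigma = 1,
                                          density = 1, seed = 1) {
  if (n_nodes < 2L) stop("'n_nodes' must be >= 2")
  if (n_modules < 1L || n_modules > n_nodes) stop("'n_modules' must be in [1, n_nodes]")
  if (intra_weight_scale <= 0 || inter_weight_scale <= 0) stop("weight scales must be > 0")
  if (lognormal_sigma < 0) stop("'lognormal_sigma' must be >= 0")
  if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
  modules <- sort(rep_len(seq_len(n_modules), n_nodes))
  w <- with_seed(seed, {
    w <- matrix(0, n_nodes, n_nodes)
    ut <- which(upper.tri(w))
    same <- outer(modules, modules, "==")[ut]
    scale <- ifelse(same, intra_weight_scale, inter_weight_scale)
    present <- if (density < 1) runif(length(ut)) < density else rep(TRUE, length(ut))
    noise <- if (lognormal_sigma > 0)
      exp(lognormal_sigma * stats::rnorm(length(ut)) - lognormal_sigma^2 / 2)
    else rep(1, length(ut))
    w[ut] <- scale * noise * present
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    w
  })
  G <- connectome(w)
  attr(G, "modules") <- modules
  G
}

#' Shuffle-null surrogate of a connectome
#'
#' Randomly permutes the strictly-upper-triangle weights and mirrors them
#' into the lower triangle, producing a symmetric surrogate with exactly the
#' original weight multiset but destroyed topology. This is the null model
#' used to test whether flexibility patterns depend on the specific
#' connectivity rather than on the weight distribution alone.
#'
#' @param G a [connectome()] object.
#' @param seed integer seed controlling the permutation.
#' @return A [connectome()] with identical upper-triangle weight multiset.
#' @export
shuffle_connectome <- function(G, seed = 1) {
  stopifnot(inherits(G, "connectome"))
  w <- G$weights
  ut <- which(upper.tri(w))
  perm <- with_seed(seed, sample.int(length(ut)))
  w[ut] <- w[ut][perm]
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  connectome(w, node_labels = G$node_labels)
}

#' Weighted degree (node strength)
#'
#' The per-node sum of incident edge weights, `s_k = sum_l g_kl`.
#'
#' @param G a [connectome()] object.
#' @return Numeric vector of length `n_nodes`, named by node label.
#' @export
weighted_degree <- function(G) {
  stopifnot(inherits(G, "connectome"))
  setNames(rowSums(G$weights), G$node_labels)
}

#' Select stimulated nodes by weighted degree
#'
#' Picks the regions that receive the block-task input. `"light"` selects
#' the `count` nodes of smallest weighted degree, `"heavy"` the largest,
#' and `"mid"` a contiguous rank window centered on the median rank of the
#' degree-sorted node list (ranks `ceiling((N - count)/2) + 1` through
#' `ceiling((N - count)/2) + count`). Ties in degree are broken by the
#' smaller node index, so the selection is deterministic. `"custom"` (and
#' its alias `"wm"`, for an empirically derived working-memory set) takes
#' indices verbatim.
#'
#' @param G a [connectome()] object.
#' @param scenario one of `"light"`, `"mid"`, `"heavy"`, `"custom"`, `"wm"`.
#' @param count number of nodes to select (default 6).
#' @param custom_indices 1-based node indices, required for
#'   `"custom"`/`"wm"`.
#' @return An object of class `"node_selection"`: list with `indices`
#'   (1-based, in selection order), `scenario` and `count`.
#' @export
select_nodes <- function(G, scenario = c("light", "mid", "heavy", "custom", "wm"),
                         count = 6, custom_indices = NULL) {
  stopifnot(inherits(G, "connectome"))
  scenario <- match.arg(scenario)
  n <- G$n_nodes
  count <- as.integer(count)
  if (scenario %in% c("custom", "wm") && is.null(custom_indices))
    stop("scenario '", scenario, "' requires 'custom_indices'")
  if (count < 1L || count > n) stop("'count' must be in [1, n_nodes]")
  if (scenario %in% c("custom", "wm")) {
    idx <- as.integer(custom_indices)
    if (anyDuplicated(idx)) stop("duplicated custom node index")
    if (any(idx < 1L | idx > n)) stop("custom node index out of range 1..", n)
    if (length(idx) != count) count <- length(idx)
  } else {
    deg <- unname(weighted_degree(G))
    ord <- order(deg, seq_len(n))           # ascending degree, ties by index
    idx <- switch(scenario,
      light = ord[seq_len(count)],
      heavy = ord[seq(n - count + 1L, n)],
      mid   = ord[ceiling((n - count) / 2) + seq_len(count)])
  }
  structure(list(indices = idx, scenario = scenario, count = count),
            class = "node_selection")
}

#' @export
print.node_selection <- function(x, ...) {
  cat(sprintf("Node selection [%s]: %s\n", x$scenario,
              paste(x$indices, collapse = ", ")))
  invisible(x)
}
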
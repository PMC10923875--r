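# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles are deliberately scalar / loop-based so they share
# no code path with the package implementations they check.

# Two-pass scalar Pearson correlation of two vectors.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (k in seq_len(n)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    dx <- dx + (x[k] - mx)^2
    dy <- dy + (y[k] - my)^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

# Per-window Pearson matrices from a node x volume matrix, element by element.
oracle_window_corr <- function(y, l, step) {
  nw <- (ncol(y) - l) %/% step + 1L
  lapply(seq_len(nw), function(win) {
    idx <- (win - 1L) * step + seq_len(l)
    N <- nrow(y)
    A <- diag(N)
    for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
      A[i, j] <- oracle_pearson(y[i, idx], y[j, idx])
    A
  })
}

# Triple-loop normalized module strengths: h_ik = sum_j |a_ij| m_jk / K_k.
oracle_module_strengths <- function(A, M) {
  N <- nrow(A); P <- ncol(M)
  H <- matrix(0, N, P)
  for (i in seq_len(N)) for (k in seq_len(P)) {
    acc <- 0
    for (j in seq_len(N)) acc <- acc + abs(A[i, j]) * M[j, k]
    H[i, k] <- acc / sum(M[, k])
  }
  H
}

# Row-wise scan argmax with lowest-index tie-break.
oracle_affiliation <- function(H) {
  apply(H, 1L, function(row) {
    best <- 1L
    for (j in seq_along(row)) if (row[j] > row[best]) best <- j
    best
  })
}

oracle_template_flexibility <- function(om1, om2) {
  same <- 0
  for (i in seq_along(om1)) if (om1[i] == om2[i]) same <- same + 1
  1 - same / length(om1)
}

oracle_distance_flexibility <- function(A1, A2) {
  1 - oracle_pearson(as.vector(A1), as.vector(A2))
}

# Per-node double-loop FHN right-hand side (checks the vectorized/compiled
# versions).
oracle_fhn_rhs <- function(u, w, t, G, p, protocol) {
  N <- length(u)
  du <- numeric(N); dw <- numeric(N)
  for (k in seq_len(N)) {
    coup <- 0
    for (l in seq_len(N)) coup <- coup + G$weights[k, l] * u[l]
    I <- if (protocol$enabled && k %in% protocol$targets)
      -protocol$amplitude_c * (2 * floor(t / protocol$period_T) -
                                 floor(2 * t / protocol$period_T)) else 0
    du[k] <- (u[k] - u[k]^3 / 3 - w[k] + p$I0 - p$sigma * coup + I) / p$epsilon
    dw[k] <- u[k] + p$a - p$b * w[k]
  }
  list(du = du, dw = dw)
}

# Random valid connectome for property tests.
random_connectome <- function(n, seed) {
  w <- local({
    set.seed(seed)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::rexp(n * (n - 1) / 2)
    m + t(m)
  })
  connectome(w)
}

# Random symmetric unit-diagonal "functional-like" matrix.
random_fc_matrix <- function(n, seed) {
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 3 * n), n)   # n x 3n samples -> full-rank corr
  A <- stats::cor(t(y))
  diag(A) <- 1
  A
}

# A small fc_sequence built directly from random BOLD-like data.
random_fc_sequence <- function(n_nodes, n_vol, seed, l = 15, step = 1) {
  set.seed(seed)
  Y <- bold_ts(matrix(stats::rnorm(n_nodes * n_vol), n_nodes), TR = 2)
  sliding_window_corr(Y, window_spec(l, step))
}

write_lines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
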
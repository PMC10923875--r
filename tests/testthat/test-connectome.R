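test_that("dense and edge-list readers build valid connectomes", {
  p <- write_lines(c("0,1", "1,0"), ".csv")
  G <- read_connectome(p, "dense")
  expect_equal(G$n_nodes, 2L)
  expect_equal(G$weights[1, 2], 1)

  p <- write_lines(c("a,b,c", "0,1,0", "1,0,2", "0,2,0"), ".csv")
  G <- read_connectome(p, "dense")
  expect_equal(G$node_labels, c("a", "b", "c"))
  expect_equal(G$weights[2, 3], 2)

  p <- write_lines("1\t2\t0.5", ".tsv")
  G <- read_connectome(p, "edgelist", n_nodes = 3)
  expect_equal(G$n_nodes, 3L)
  expect_equal(G$weights[1, 2], 0.5)
  expect_equal(G$weights[2, 1], 0.5)
  expect_equal(sum(G$weights), 1)
})

test_that("reader rejects invalid matrices", {
  expect_error(read_connectome(write_lines(c("0,1,0", "1,0,0"), ".csv"), "dense"),
               "square")
  expect_error(read_connectome(write_lines(c("0,1", "2,0"), ".csv"), "dense"),
               "asymmetric.*1")
  expect_error(read_connectome(write_lines(c("0,-1", "-1,0"), ".csv"), "dense"),
               "nonnegative")
  expect_error(read_connectome(write_lines(c("1,2", "2,0"), ".csv"), "dense"),
               "diagonal")
  expect_error(read_connectome(write_lines(c("1\t2\t0.5", "2\t1\t0.5"), ".tsv"),
                               "edgelist"),
               "duplicate")
  expect_error(connectome(matrix(0, 1, 1)), "at least 2")
})

test_that("synthetic connectome generator honors its contracts", {
  # degenerate noise-free case: every off-diagonal weight equals the scale
  G <- generate_synthetic_connectome(5, 1, intra_weight_scale = 0.7,
                                     lognormal_sigma = 0, density = 1, seed = 1)
  off <- G$weights[upper.tri(G$weights)]
  expect_true(all(off == 0.7))

  # determinism
  G1 <- generate_synthetic_connectome(30, 3, seed = 42)
  G2 <- generate_synthetic_connectome(30, 3, seed = 42)
  expect_identical(G1$weights, G2$weights)
  G3 <- generate_synthetic_connectome(30, 3, seed = 43)
  expect_false(identical(G1$weights, G3$weights))

  # modular structure: mean within-block weight > mean between-block weight
  G <- generate_synthetic_connectome(60, 4, seed = 7)
  mod <- attr(G, "modules")
  same <- outer(mod, mod, "==") & upper.tri(G$weights)
  diff <- !outer(mod, mod, "==") & upper.tri(G$weights)
  expect_gt(mean(G$weights[same]), mean(G$weights[diff]))

  expect_error(generate_synthetic_connectome(10, 2, density = 0), "density")
  expect_error(generate_synthetic_connectome(10, 2, intra_weight_scale = -1),
               "scales")
  expect_error(generate_synthetic_connectome(1, 1), "n_nodes")
})

test_that("shuffle preserves the weight multiset and symmetry invariants", {
  # N = 2: no permutation freedom
  G <- connectome(matrix(c(0, 3, 3, 0), 2))
  expect_identical(shuffle_connectome(G, 5)$weights, G$weights)

  # all-equal upper triangle: shuffle is the identity
  w <- matrix(1, 4, 4); diag(w) <- 0
  G <- connectome(w)
  expect_identical(shuffle_connectome(G, 11)$weights, G$weights)

  # random 10x10: exact sorted-multiset equality, symmetry, zero diagonal
  G <- random_connectome(10, seed = 3)
  Gp <- shuffle_connectome(G, seed = 9)
  expect_identical(sort(Gp$weights[upper.tri(Gp$weights)]),
                   sort(G$weights[upper.tri(G$weights)]))
  expect_identical(Gp$weights, t(Gp$weights))
  expect_identical(diag(Gp$weights), rep(0, 10))
  expect_identical(sum(Gp$weights), sum(G$weights))
  # reproducible, and a genuine permutation for generic weights
  expect_identical(shuffle_connectome(G, seed = 9)$weights, Gp$weights)
  expect_false(identical(Gp$weights, G$weights))
})

test_that("weighted degree equals element-wise row sums", {
  # unit-weight ring of 5 nodes: all degrees 2
  w <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; w[i, j] <- 1; w[j, i] <- 1 }
  expect_equal(unname(weighted_degree(connectome(w))), rep(2, 5))

  # star: center 3, leaves 1
  w <- matrix(0, 4, 4); w[1, 2:4] <- 1; w[2:4, 1] <- 1
  expect_equal(unname(weighted_degree(connectome(w))), c(3, 1, 1, 1))

  # random: naive double loop
  G <- random_connectome(8, seed = 5)
  manual <- vapply(1:8, function(k) {
    acc <- 0
    for (l in 1:8) acc <- acc + G$weights[k, l]
    acc
  }, numeric(1))
  expect_equal(unname(weighted_degree(G)), manual)
})

test_that("node selection follows the rank-window rules deterministically", {
  G <- random_connectome(6, seed = 1)
  for (sc in c("light", "mid", "heavy"))
    expect_setequal(select_nodes(G, sc, count = 6)$indices, 1:6)

  # weighted star with distinct leaf degrees 1..9: heavy count=2 picks the
  # center (degree 45) and the heaviest leaf
  w <- matrix(0, 10, 10)
  w[1, 2:10] <- 1:9; w[2:10, 1] <- 1:9
  G <- connectome(w)
  expect_setequal(select_nodes(G, "heavy", count = 2)$indices, c(1L, 10L))
  expect_identical(select_nodes(G, "light", count = 2)$indices, c(2L, 3L))

  # mid scenario against the brute-force rank-window oracle
  G <- random_connectome(20, seed = 17)
  deg <- unname(weighted_degree(G))
  ord <- order(deg, seq_along(deg))
  expected <- ord[(ceiling((20 - 6) / 2) + 1):(ceiling((20 - 6) / 2) + 6)]
  expect_identical(select_nodes(G, "mid", count = 6)$indices, expected)

  # determinism and tie-breaking by node index
  w <- matrix(1, 4, 4); diag(w) <- 0
  G <- connectome(w)
  expect_identical(select_nodes(G, "light", count = 2)$indices, c(1L, 2L))
  expect_identical(select_nodes(G, "heavy", count = 2)$indices, c(3L, 4L))

  expect_error(select_nodes(G, "light", count = 5), "count")
  expect_error(select_nodes(G, "custom"), "custom_indices")
  expect_error(select_nodes(G, "custom", count = 2, custom_indices = c(1, 1)),
               "duplicated")
  expect_error(select_nodes(G, "custom", count = 2, custom_indices = c(1, 9)),
               "range")
})
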
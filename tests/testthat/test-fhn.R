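make_protocol <- function(targets = 1L, c = 3, T = 60, enabled = TRUE)
  stimulus_protocol(targets, amplitude_c = c, period_T = T, enabled = enabled)

test_that("square-wave input reproduces the block design", {
  prot <- make_protocol(targets = 2L)
  expect_equal(square_wave_input(15, prot, 2), 0)    # first half-block
  expect_equal(square_wave_input(45, prot, 2), 3)    # second half-block
  expect_equal(square_wave_input(60, prot, 2), 0)    # period wraps
  expect_equal(square_wave_input(45, prot, 1), 0)    # non-target node
  off <- make_protocol(targets = 2L, enabled = FALSE)
  expect_equal(square_wave_input(45, off, 2), 0)

  # exact periodicity I(t + T) = I(t), and values confined to {0, c}
  t <- seq(0, 120, by = 0.5)
  v <- square_wave_input(t, prot, 2)
  expect_equal(v, square_wave_input(t + 60, prot, 2))
  expect_true(all(v %in% c(0, 3)))
})

test_that("network right-hand side matches hand arithmetic and the loop oracle", {
  G <- connectome(matrix(c(0, 1, 1, 0), 2))
  p0 <- fhn_params(sigma = 0)
  off <- make_protocol(enabled = FALSE)
  d <- fhn_rhs(c(0, 0), c(0, 0), 0, G, p0, off)
  expect_equal(d$du, c(8, 8))        # I0 / epsilon
  expect_equal(d$dw, c(0.45, 0.45))  # a

  # single coupling term: node 1 feels -sigma * g_12 * u_2 = +sigma
  p <- fhn_params()
  d1 <- fhn_rhs(c(1, -1), c(0, 0), 0, G, p, off)
  d0 <- fhn_rhs(c(1, -1), c(0, 0), 0, G, p0, off)
  expect_equal(d1$du[1] - d0$du[1], p$sigma / p$epsilon)

  # random 5-node state vs per-node double loop
  G5 <- random_connectome(5, seed = 2)
  set.seed(4)
  u <- rnorm(5); w <- rnorm(5)
  prot <- make_protocol(targets = c(2L, 4L))
  got <- fhn_rhs(u, w, 45, G5, p, prot)
  want <- oracle_fhn_rhs(u, w, 45, G5, p, prot)
  expect_equal(got$du, want$du, tolerance = 1e-12)
  expect_equal(got$dw, want$dw, tolerance = 1e-12)

  expect_error(fhn_rhs(c(NaN, 0), c(0, 0), 0, G, p, off), "node 1")
})

test_that("random initial conditions are reproducible, bounded and centered", {
  a <- random_initial_conditions(10, seed = 1)
  b <- random_initial_conditions(10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, random_initial_conditions(10, seed = 2)))

  z <- random_initial_conditions(100, seed = 3, lo = 0.5, hi = 0.5 + 1e-6)
  expect_true(all(z$u0 >= 0.5 & z$u0 <= 0.5 + 1e-6))

  big <- random_initial_conditions(10000, seed = 5)
  se <- (4 / sqrt(12)) / sqrt(10000)      # SD of U(-2,2) over sqrt(n)
  expect_lt(abs(mean(big$u0) - 0), 3 * se)
  expect_lt(abs(mean(big$w0) - 0), 3 * se)
  expect_error(random_initial_conditions(5, 1, lo = 1, hi = 1), "lo")
})

test_that("compiled integrator agrees with the reference R integrator", {
  G <- random_connectome(4, seed = 8)
  prot <- make_protocol(targets = c(1L, 3L), T = 2)
  ic <- random_initial_conditions(4, seed = 6)
  a <- fhn_integrate(G, fhn_params(), prot, duration = 4, dt = 0.01,
                     u0 = ic$u0, w0 = ic$w0, engine = "cpp")
  b <- fhn_integrate(G, fhn_params(), prot, duration = 4, dt = 0.01,
                     u0 = ic$u0, w0 = ic$w0, engine = "r")
  expect_equal(a$u, b$u, tolerance = 1e-12)
  expect_equal(a$w, b$w, tolerance = 1e-12)
  expect_equal(a$times, b$times)
})

test_that("uncoupled single oscillator settles on a stable periodic orbit", {
  G <- connectome(matrix(c(0, 0, 0, 0), 2))   # two independent units
  traj <- fhn_integrate(G, fhn_params(sigma = 0),
                        stimulus_protocol(enabled = FALSE),
                        duration = 200, dt = 0.01,
                        u0 = c(0.1, 0.1), w0 = c(0, 0))
  # upward zero crossings of u over the last 50 time units
  u <- traj$u[1, traj$times >= 150]
  t <- traj$times[traj$times >= 150]
  idx <- which(u[-length(u)] < 0 & u[-1] >= 0)
  cross <- t[idx] - u[idx] * (t[idx + 1] - t[idx]) / (u[idx + 1] - u[idx])
  periods <- diff(cross)
  expect_gt(length(periods), 3)
  expect_lt((max(periods) - min(periods)) / mean(periods), 0.01)
})

test_that("step-halving keeps the end state and shows ~4th-order convergence", {
  G <- random_connectome(2, seed = 10)
  ic <- random_initial_conditions(2, seed = 11)
  run <- function(dt) {
    tr <- fhn_integrate(G, fhn_params(), stimulus_protocol(enabled = FALSE),
                        duration = 10, dt = dt, u0 = ic$u0, w0 = ic$w0)
    c(tr$u[, ncol(tr$u)], tr$w[, ncol(tr$w)])
  }
  expect_lt(max(abs(run(0.01) - run(0.005))), 1e-4)

  d1 <- max(abs(run(0.08) - run(0.04)))
  d2 <- max(abs(run(0.04) - run(0.02)))
  expect_gt(log2(d1 / d2), 3.5)
})

test_that("symmetry and locality of the dynamics are respected", {
  # identical ICs on a regular graph with identical inputs -> identical nodes
  w <- matrix(1, 4, 4); diag(w) <- 0
  G <- connectome(w)
  prot <- make_protocol(targets = 1:4, T = 4)
  traj <- fhn_integrate(G, fhn_params(), prot, duration = 8, dt = 0.01,
                        u0 = rep(0.3, 4), w0 = rep(-0.1, 4))
  for (k in 2:4) expect_equal(traj$u[k, ], traj$u[1, ], tolerance = 1e-12)

  # sigma = 0: perturbing node 2's IC leaves node 1's trajectory unchanged
  G2 <- random_connectome(3, seed = 12)
  p0 <- fhn_params(sigma = 0)
  base <- fhn_integrate(G2, p0, make_protocol(enabled = FALSE), 5, 0.01,
                        u0 = c(0.1, 0.2, 0.3), w0 = c(0, 0, 0))
  pert <- fhn_integrate(G2, p0, make_protocol(enabled = FALSE), 5, 0.01,
                        u0 = c(0.1, 1.9, 0.3), w0 = c(0, 0, 0))
  expect_identical(base$u[1, ], pert$u[1, ])
  expect_false(identical(base$u[2, ], pert$u[2, ]))

  # permutation equivariance: relabeling nodes permutes the trajectory
  perm <- c(3L, 1L, 2L)
  Gp <- connectome(G2$weights[perm, perm])
  ic <- random_initial_conditions(3, seed = 13)
  t1 <- fhn_integrate(G2, fhn_params(), make_protocol(enabled = FALSE), 3, 0.01,
                      u0 = ic$u0, w0 = ic$w0)
  t2 <- fhn_integrate(Gp, fhn_params(), make_protocol(enabled = FALSE), 3, 0.01,
                      u0 = ic$u0[perm], w0 = ic$w0[perm])
  expect_equal(t2$u, t1$u[perm, ], tolerance = 1e-12)
})

test_that("integration guards and grid constraints are enforced", {
  G <- connectome(matrix(c(0, 1, 1, 0), 2))
  ic <- random_initial_conditions(2, seed = 1)
  expect_error(fhn_integrate(G, duration = 1, dt = 0.01, u0 = ic$u0,
                             w0 = ic$w0, guard = 0.1),
               "diverged at node .*time")
  expect_error(fhn_integrate(G, fhn_params(), make_protocol(T = 1), 3, 0.3,
                             u0 = ic$u0, w0 = ic$w0),
               "grid points")
  expect_error(fhn_integrate(G, duration = 1.005, dt = 0.01,
                             u0 = ic$u0, w0 = ic$w0),
               "integer multiple")
})

test_that("ensembles are seeded deterministically and independently", {
  G <- random_connectome(3, seed = 14)
  prot <- make_protocol(enabled = FALSE)
  ens <- run_ensemble(G, fhn_params(), prot, duration = 2, dt = 0.01,
                      n_runs = 1, base_seed = 99)
  ic <- random_initial_conditions(3, seed = 99)
  direct <- fhn_integrate(G, fhn_params(), prot, 2, 0.01,
                          u0 = ic$u0, w0 = ic$w0)
  expect_identical(ens[[1]]$u, direct$u)

  ens2 <- run_ensemble(G, fhn_params(), prot, duration = 2, dt = 0.01,
                       n_runs = 3, base_seed = 99)
  expect_identical(attr(ens2, "seeds"), c(99, 100, 101))
  expect_false(identical(ens2[[1]]$u[, 1], ens2[[2]]$u[, 1]))
  # full re-run is bit-identical
  ens3 <- run_ensemble(G, fhn_params(), prot, duration = 2, dt = 0.01,
                       n_runs = 3, base_seed = 99)
  expect_identical(lapply(ens2, `[[`, "u"), lapply(ens3, `[[`, "u"))
})
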
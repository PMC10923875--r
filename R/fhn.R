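#' FitzHugh-Nagumo model parameters
#'
#' Parameters of the coupled FitzHugh-Nagumo network. Each brain region k
#' carries an activator `u_k` and inhibitor `w_k` obeying
#' \deqn{\epsilon \dot u_k = u_k - u_k^3/3 - w_k + I_0
#'       - \sigma \sum_l g_{kl} u_l + I_k(t), \quad
#'       \dot w_k = u_k + a - b w_k.}
#' Defaults place the uncoupled unit in its oscillatory regime.
#'
#' @param a,b bifurcation parameters (defaults 0.45, 0.9).
#' @param epsilon time-scale ratio of fast activator to slow inhibitor
#'   (default 0.1, must be > 0).
#' @param sigma overall coupling constant multiplying the structural
#'   weights (default 1.8).
#' @param I0 excitability parameter, a common input to every unit
#'   (default 0.8).
#' @return A list of class `"fhn_params"`.
#' @export
fhn_params <- function(a = 0.45, b = 0.9, epsilon = 0.1, sigma = 1.8,
                       I0 = 0.8) {
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  structure(list(a = a, b = b, epsilon = epsilon, sigma = sigma, I0 = I0),
            class = "fhn_params")
}

#' Block-task stimulus protocol
#'
#' Square-wave input modeling alternating task blocks (e.g. 30 s of 0-back
#' followed by 30 s of 2-back): zero during the first half-period and
#' `amplitude_c` during the second, repeating with period `period_T`,
#' delivered only to the target nodes.
#'
#' @param targets a `"node_selection"` (see [select_nodes()]) or a vector of
#'   1-based node indices.
#' @param amplitude_c input amplitude `c` (default 3).
#' @param period_T block-pair period `T` in seconds (default 60, i.e. two
#'   30 s blocks).
#' @param enabled if `FALSE` the input is identically zero for all nodes.
#' @return A list of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(targets = integer(), amplitude_c = 3,
                              period_T = 60, enabled = TRUE) {
  if (period_T <= 0) stop("'period_T' must be > 0")
  idx <- if (inherits(targets, "node_selection")) targets$indices
         else as.integer(targets)
  structure(list(amplitude_c = amplitude_c, period_T = period_T,
                 targets = idx, enabled = isTRUE(enabled)),
            class = "stimulus_protocol")
}

#' Square-wave task input
#'
#' Evaluates \eqn{I_k(t) = -c\,(2\lfloor ft\rfloor - \lfloor 2ft\rfloor)}
#' with frequency `f = 1/T`: 0 on `[0, T/2)` ("0-back" baseline) and `c` on
#' `[T/2, T)` ("2-back" block), for nodes in the protocol's target set;
#' 0 for all other nodes and whenever the protocol is disabled.
#'
#' @param t time in seconds (vectorized, `t >= 0`).
#' @param protocol a [stimulus_protocol()].
#' @param node_index 1-based node index receiving the input.
#' @return Input value(s) in `{0, c}`.
#' @export
square_wave_input <- function(t, protocol, node_index) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!protocol$enabled || !(node_index %in% protocol$targets))
    return(rep(0, length(t)))
  ft <- t / protocol$period_T
  -protocol$amplitude_c * (2 * floor(ft) - floor(2 * ft))
}

#' FitzHugh-Nagumo network right-hand side
#'
#' Reference (vectorized R) evaluation of the coupled-network derivative;
#' the compiled integrator in [fhn_integrate()] is cross-checked against it.
#' Coupling and external input enter the activator equation only.
#'
#' @param u,w numeric state vectors of length `n_nodes`.
#' @param t time in seconds.
#' @param G a [connectome()].
#' @param params an [fhn_params()].
#' @param protocol a [stimulus_protocol()].
#' @return List with derivative vectors `du` and `dw`.
#' @export
fhn_rhs <- function(u, w, t, G, params, protocol) {
  stopifnot(inherits(G, "connectome"), inherits(params, "fhn_params"))
  n <- G$n_nodes
  if (length(u) != n || length(w) != n) stop("state length must equal n_nodes")
  if (anyNA(u) || anyNA(w) || any(!is.finite(c(u, w)))) {
    bad <- which(!is.finite(u) | !is.finite(w))[1]
    stop(sprintf("non-finite state at node %d, time %g", bad, t))
  }
  I <- numeric(n)
  if (protocol$enabled && length(protocol$targets)) {
    val <- -protocol$amplitude_c *
      (2 * floor(t / protocol$period_T) - floor(2 * t / protocol$period_T))
    I[protocol$targets] <- val
  }
  coupling <- as.vector(G$weights %*% u)
  du <- (u - u^3 / 3 - w + params$I0 - params$sigma * coupling + I) / params$epsilon
  dw <- u + params$a - params$b * w
  list(du = du, dw = dw)
}

#' Random initial conditions
#'
#' Draws activator and inhibitor starting values i.i.d. uniform on
#' `[lo, hi]` (default `[-2, 2]`, covering the FitzHugh-Nagumo limit-cycle
#' range), reproducibly for a fixed seed.
#'
#' @param N number of nodes.
#' @param seed integer seed.
#' @param lo,hi bounds with `lo < hi`.
#' @return List with vectors `u0` and `w0` of length `N`.
#' @export
random_initial_conditions <- function(N, seed, lo = -2, hi = 2) {
  if (lo >= hi) stop("'lo' must be < 'hi'")
  with_seed(seed, list(u0 = runif(N, lo, hi), w0 = runif(N, lo, hi)))
}

#' Integrate the coupled FitzHugh-Nagumo network
#'
#' Fixed-step classical 4th-order Runge-Kutta on a uniform grid including
#' `t = 0`. When the stimulus is enabled, `period_T/dt` and
#' `(period_T/2)/dt` must be integers so that block edges fall exactly on
#' grid points (the input is discontinuous there).
#'
#' @param G a [connectome()].
#' @param params an [fhn_params()].
#' @param protocol a [stimulus_protocol()].
#' @param duration simulated span in seconds (`>= dt`).
#' @param dt integration step in seconds (default 0.01); `duration/dt` must
#'   be an integer.
#' @param u0,w0 initial state vectors (e.g. from
#'   [random_initial_conditions()]).
#' @param guard divergence guard: any `|u|` or `|w|` exceeding it aborts
#'   with the first offending node and time (default 1e6).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference R loop,
#'   for validation at small sizes).
#' @return An object of class `"fhn_trajectory"`: list with `times`
#'   (length `n_steps + 1`), matrices `u`, `w` (`n_nodes x (n_steps + 1)`),
#'   and `meta` (dt, params, protocol, seed if known).
#' @export
fhn_integrate <- function(G, params = fhn_params(),
                          protocol = stimulus_protocol(enabled = FALSE),
                          duration, dt = 0.01, u0, w0, guard = 1e6,
                          engine = c("cpp", "r")) {
  stopifnot(inherits(G, "connectome"), inherits(params, "fhn_params"),
            inherits(protocol, "stimulus_protocol"))
  engine <- match.arg(engine)
  if (dt <= 0) stop("'dt' must be > 0")
  if (duration < dt) stop("'duration' must be >= dt")
  nsteps <- duration / dt
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("'duration' must be an integer multiple of dt")
  nsteps <- round(nsteps)
  if (protocol$enabled) {
    half_steps <- (protocol$period_T / 2) / dt
    if (abs(half_steps - round(half_steps)) > 1e-8)
      stop("block edges must fall on grid points: (period_T/2)/dt must be an integer")
    if (any(protocol$targets < 1L | protocol$targets > G$n_nodes))
      stop("stimulus target index out of range")
  }
  n <- G$n_nodes
  if (length(u0) != n || length(w0) != n)
    stop("initial conditions must have length n_nodes")

  if (engine == "cpp") {
    res <- fhn_integrate_cpp(G$weights, params$a, params$b, params$epsilon,
                             params$sigma, params$I0,
                             protocol$amplitude_c, protocol$period_T,
                             as.integer(protocol$targets) - 1L,
                             protocol$enabled, duration, dt,
                             as.double(u0), as.double(w0), guard)
  } else {
    u <- as.double(u0); w <- as.double(w0)
    U <- matrix(NA_real_, n, nsteps + 1L); W <- U
    U[, 1] <- u; W[, 1] <- w
    for (i in seq_len(nsteps)) {
      t0 <- (i - 1) * dt
      k1 <- fhn_rhs(u, w, t0, G, params, protocol)
      k2 <- fhn_rhs(u + dt / 2 * k1$du, w + dt / 2 * k1$dw, t0 + dt / 2, G, params, protocol)
      k3 <- fhn_rhs(u + dt / 2 * k2$du, w + dt / 2 * k2$dw, t0 + dt / 2, G, params, protocol)
      k4 <- fhn_rhs(u + dt * k3$du, w + dt * k3$dw, t0 + dt, G, params, protocol)
      u <- u + dt / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
      w <- w + dt / 6 * (k1$dw + 2 * k2$dw + 2 * k3$dw + k4$dw)
      if (any(!is.finite(u)) || any(!is.finite(w)) ||
          max(abs(u), abs(w)) > guard) {
        bad <- which(!is.finite(u) | !is.finite(w) | abs(u) > guard | abs(w) > guard)[1]
        stop(sprintf("FHN trajectory diverged at node %d, time %.4f", bad, i * dt))
      }
      U[, i + 1L] <- u; W[, i + 1L] <- w
    }
    res <- list(times = (0:nsteps) * dt, u = U, w = W)
  }
  structure(list(times = res$times, u = res$u, w = res$w,
                 meta = list(dt = dt, duration = duration, params = params,
                             protocol = protocol, engine = engine)),
            class = "fhn_trajectory")
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  cat(sprintf("FHN trajectory: %d nodes, %d steps of dt = %g s (%g s total)\n",
              nrow(x$u), length(x$times) - 1L, x$meta$dt, x$meta$duration))
  invisible(x)
}

#' Run an ensemble of simulations with random initial conditions
#'
#' Repeats the integration `n_runs` times; run `r` (1-based) draws its
#' initial conditions with seed `base_seed + r - 1`, so runs are
#' independent, order-deterministic and individually reproducible. To keep
#' memory bounded for long ensembles, a per-run reducer `f` may be supplied;
#' only its value is retained.
#'
#' @inheritParams fhn_integrate
#' @param n_runs ensemble size (default 300, the headline setting; shuffle
#'   comparisons typically use 50).
#' @param base_seed seed of the first run.
#' @param f function applied to each `"fhn_trajectory"`; defaults to
#'   identity (returns the trajectories themselves).
#' @return List of length `n_runs` of `f`'s values, with attribute `seeds`.
#' @export
run_ensemble <- function(G, params = fhn_params(),
                         protocol = stimulus_protocol(enabled = FALSE),
                         duration, dt = 0.01, n_runs = 300, base_seed = 1,
                         f = identity) {
  if (n_runs < 1L) stop("'n_runs' must be >= 1")
  seeds <- base_seed + seq_len(n_runs) - 1L
  out <- lapply(seeds, function(s) {
    ic <- random_initial_conditions(G$n_nodes, seed = s)
    traj <- fhn_integrate(G, params, protocol, duration, dt,
                          u0 = ic$u0, w0 = ic$w0)
    traj$meta$seed <- s
    f(traj)
  })
  attr(out, "seeds") <- seeds
  out
}
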
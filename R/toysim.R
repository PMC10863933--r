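# Toy dynamical systems with exact equilibrium and kinetic ground truth.
#
# These engines stand in for a molecular dynamics code: they produce
# trajectories whose stationary distribution and kinetics are known in closed
# form, so every downstream estimator (MSM, TPT, kinetics, adaptive policies)
# can be validated against exact answers.

#' Construct a one-dimensional Brownian-dynamics toy system
#'
#' A `toy_system` bundles a potential energy surface \eqn{U(x)} (in kT units),
#' a thermal energy, a diffusion coefficient and an integration step for
#' overdamped Langevin dynamics on a bounded interval with reflecting walls.
#'
#' @param potential function of `x` returning the potential energy (kT units
#'   when `kT = 1`). Must be finite over `domain`.
#' @param grad function returning dU/dx. If `NULL`, a central finite
#'   difference of `potential` is used.
#' @param kT thermal energy (dimensionless, default 1).
#' @param diffusion diffusion coefficient `D` (default 1).
#' @param dt integration time step (default 1e-3, stable for barriers up to
#'   roughly 10 kT at `D = 1`).
#' @param domain numeric length-2 vector of coordinate bounds.
#' @param name label used in configs and reports.
#' @param params named list of the parameters that generated `potential`,
#'   kept so a campaign config can round-trip the system definition.
#' @return object of class `toy_system`.
#' @seealso [make_double_well()], [simulate_toy()], [analytic_stationary()]
#' @export
toy_system <- function(potential, grad = NULL, kT = 1, diffusion = 1,
                       dt = 1e-3, domain = c(-2, 2), name = "custom",
                       params = list()) {
  stopifnot(is.function(potential))
  check_scalar(kT, "kT", positive = TRUE)
  check_scalar(diffusion, "diffusion", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    stop("`domain` must be two finite increasing bounds", call. = FALSE)
  }
  if (is.null(grad)) {
    h <- 1e-6 * (domain[2] - domain[1])
    grad <- function(x) (potential(x + h) - potential(x - h)) / (2 * h)
  }
  probe <- seq(domain[1], domain[2], length.out = 101L)
  if (!all(is.finite(potential(probe)))) {
    stop("`potential` must be finite over the domain", call. = FALSE)
  }
  structure(
    list(potential = potential, grad = grad, kT = kT, diffusion = diffusion,
         dt = dt, domain = domain, name = name, params = params),
    class = "toy_system"
  )
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy_system '%s'> kT=%g D=%g dt=%g domain=[%g, %g]\n",
              x$name, x$kT, x$diffusion, x$dt, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Double-well potential system
#'
#' Builds the quartic double well
#' \deqn{U(x) = b (x^2 - 1)^2 + a x}
#' on the domain \eqn{[-2, 2]}: two minima near \eqn{x = \pm 1} separated by a
#' barrier of height `barrier_height` (at `asymmetry = 0`), the standard test
#' bed for rare-event sampling.
#'
#' @param barrier_height barrier height `b` in kT units; must be positive.
#' @param asymmetry linear tilt `a` in kT units; positive values favour the
#'   left well.
#' @param ... further arguments passed to [toy_system()] (`kT`, `dt`, ...).
#' @return a `toy_system`.
#' @examples
#' sys <- make_double_well(4, 0.5)
#' sys$potential(c(-1, 0, 1))
#' @export
make_double_well <- function(barrier_height, asymmetry = 0, ...) {
  check_scalar(barrier_height, "barrier_height")
  if (barrier_height <= 0) {
    stop("`barrier_height` must be positive", call. = FALSE)
  }
  check_scalar(asymmetry, "asymmetry")
  b <- barrier_height
  a <- asymmetry
  toy_system(
    potential = function(x) b * (x^2 - 1)^2 + a * x,
    grad = function(x) 4 * b * x * (x^2 - 1) + a,
    domain = c(-2, 2),
    name = "double_well",
    params = list(barrier_height = b, asymmetry = a),
    ...
  )
}

#' Flat (free-diffusion) system, useful for checking integrator moments
#' @param ... passed to [toy_system()].
#' @return a `toy_system` with `U(x) = 0`.
#' @export
make_flat <- function(...) {
  toy_system(potential = function(x) 0 * x, grad = function(x) 0 * x,
             name = "flat", params = list(), ...)
}

#' Simulate overdamped Langevin dynamics
#'
#' Integrates the Euler--Maruyama discretization
#' \deqn{x_{t+1} = x_t - D \, U'(x_t) \, dt / kT + \sqrt{2 D\, dt}\,\xi_t}
#' with standard normal \eqn{\xi_t} and reflecting boundaries at the domain
#' walls. Reflection keeps the invariant density normalizable without
#' materially altering well populations for barriers well inside the domain.
#'
#' @param system a [toy_system()].
#' @param x0 starting coordinate, inside the domain.
#' @param n_steps number of frames to generate (>= 2 so lagged transition
#'   counting is possible).
#' @param seed integer seed; identical seeds give bitwise-identical paths.
#' @return numeric vector of `n_steps` coordinates (the first is `x0`).
#' @export
simulate_toy <- function(system, x0, n_steps, seed) {
  stopifnot(inherits(system, "toy_system"))
  check_scalar(x0, "x0")
  if (x0 < system$domain[1] || x0 > system$domain[2]) {
    stop("`x0` must lie inside the system domain", call. = FALSE)
  }
  n_steps <- check_count(n_steps, "n_steps", min = 2L)
  lo <- system$domain[1]; hi <- system$domain[2]
  D <- system$diffusion; dt <- system$dt; kT <- system$kT
  noise_sd <- sqrt(2 * D * dt)
  xi <- with_seed(seed, stats::rnorm(n_steps - 1L))
  x <- numeric(n_steps)
  x[1] <- x0
  g <- system$grad
  for (i in seq_len(n_steps - 1L)) {
    xn <- x[i] - D * g(x[i]) * dt / kT + noise_sd * xi[i]
    # reflecting walls; repeat in case a huge kick overshoots both
    while (xn < lo || xn > hi) {
      if (xn < lo) xn <- 2 * lo - xn
      if (xn > hi) xn <- 2 * hi - xn
    }
    x[i + 1L] <- xn
  }
  x
}

#' Exact Boltzmann stationary distribution on a grid
#'
#' Integrates \eqn{\exp(-U(x)/kT)} over each cell of a coordinate partition
#' by composite midpoint quadrature, giving the exact (up to quadrature)
#' equilibrium probability of each cell. This is the ground-truth oracle
#' against which MSM stationary distributions and free energies are checked.
#'
#' @param system a [toy_system()].
#' @param grid increasing vector of cell edges covering the domain
#'   (length `n_cells + 1`).
#' @param n_quad midpoint quadrature points per cell.
#' @return probability vector of length `length(grid) - 1`, summing to 1.
#' @export
analytic_stationary <- function(system, grid, n_quad = 64L) {
  stopifnot(inherits(system, "toy_system"))
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be a strictly increasing vector of cell edges", call. = FALSE)
  }
  if (grid[1] > system$domain[1] + 1e-9 || grid[length(grid)] < system$domain[2] - 1e-9) {
    stop("`grid` must cover the system domain", call. = FALSE)
  }
  n_cells <- length(grid) - 1L
  w <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    a <- grid[i]; b <- grid[i + 1L]
    xs <- a + (b - a) * (seq_len(n_quad) - 0.5) / n_quad
    w[i] <- mean(exp(-system$potential(xs) / system$kT)) * (b - a)
  }
  w / sum(w)
}

#' Construct a discrete Markov chain with known transition matrix
#'
#' @param T_true row-stochastic transition matrix (rows sum to 1 within
#'   1e-12, all entries non-negative).
#' @return object of class `discrete_chain` with fields `T_true`, `n_states`.
#' @export
discrete_chain <- function(T_true) {
  T_true <- as.matrix(T_true)
  if (nrow(T_true) != ncol(T_true)) stop("`T_true` must be square", call. = FALSE)
  if (any(T_true < 0)) stop("`T_true` entries must be >= 0", call. = FALSE)
  if (any(abs(rowSums(T_true) - 1) > 1e-12)) {
    stop("every row of `T_true` must sum to 1 within 1e-12", call. = FALSE)
  }
  structure(list(T_true = T_true, n_states = nrow(T_true)),
            class = "discrete_chain")
}

#' Sample a path from a discrete Markov chain
#'
#' @param chain a [discrete_chain()].
#' @param s0 starting state (1-based).
#' @param n_steps path length in frames.
#' @param seed integer seed.
#' @return integer vector of `n_steps` states.
#' @export
discrete_chain_sample <- function(chain, s0, n_steps, seed) {
  stopifnot(inherits(chain, "discrete_chain"))
  s0 <- check_count(s0, "s0")
  if (s0 > chain$n_states) stop("`s0` must be <= n_states", call. = FALSE)
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  n <- chain$n_states
  # inverse-CDF sampling from pre-drawn uniforms keeps the path reproducible
  cum <- t(apply(chain$T_true, 1L, cumsum))
  u <- with_seed(seed, stats::runif(n_steps - 1L))
  path <- integer(n_steps)
  path[1] <- s0
  for (i in seq_len(n_steps - 1L)) {
    r <- cum[path[i], ]
    path[i + 1L] <- which(u[i] <= r + 1e-15)[1]
  }
  path
}

#' Stationary distribution of a discrete chain (ground truth)
#'
#' Leading left eigenvector of the true transition matrix, normalized to 1.
#'
#' @param chain a [discrete_chain()].
#' @return probability vector.
#' @export
chain_stationary <- function(chain) {
  stopifnot(inherits(chain, "discrete_chain"))
  stationary_from_T(chain$T_true)
}

# Left Perron eigenvector of a row-stochastic matrix, real and normalized.
stationary_from_T <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values) - 1e3 * abs(Im(e$values)))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}
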
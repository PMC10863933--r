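# Discretization, transition counting, MSM estimation, free energies,
# implied timescales and coarse-graining.

test_that("mini-batch k-means recovers separated clouds and degenerate cases", {
  set.seed(1)
  cloud1 <- matrix(rnorm(200, mean = 0, sd = 0.1), ncol = 2)
  cloud2 <- matrix(rnorm(200, mean = 5, sd = 0.1), ncol = 2)
  data <- rbind(cloud1, cloud2)
  truth <- rep(1:2, each = 100)
  disc <- cluster_frames(data, 2, seed = 7)
  # brute-force nearest-center check and exact cloud recovery (up to label swap)
  manual <- apply(data, 1, function(r) {
    which.min(colSums((t(disc$centers) - r)^2))
  })
  expect_equal(disc$assign, manual)
  expect_equal(length(unique(disc$assign[truth == 1])), 1L)
  expect_equal(length(unique(disc$assign[truth == 2])), 1L)
  expect_false(disc$assign[1] == disc$assign[200])

  one <- cluster_frames(data, 1, seed = 3)
  expect_equal(as.numeric(one$centers), colMeans(data), tolerance = 1e-12)

  again <- cluster_frames(data, 2, seed = 7)
  expect_identical(disc$assign, again$assign)

  expect_error(cluster_frames(data, 0, seed = 1), "k")
  expect_error(cluster_frames(data, nrow(data) + 1, seed = 1), "frames")
})

test_that("count matrix enumerates lagged transitions", {
  # states relabelled to 1-based
  expect_equal(count_matrix(c(1, 1, 2, 2), lag = 1),
               matrix(c(1L, 0L, 1L, 1L), 2))
  # lag-2 pairs of (1,2,1,2): (1,1) and (2,2)
  expect_equal(count_matrix(c(1, 2, 1, 2), lag = 2), diag(c(1L, 1L)))
  # counting identity over multiple trajectories, short ones excluded
  dtrajs <- list(sample(1:3, 40, replace = TRUE),
                 sample(1:3, 25, replace = TRUE),
                 c(2L))
  lag <- 3
  C <- count_matrix(dtrajs, lag, n_states = 3)
  expect_equal(sum(C), (40 - lag) + (25 - lag))
  expect_error(count_matrix(list(c(1, 2)), lag = 5), "shorter")
})

test_that("MSM estimation: symmetric, non-reversible, and trimming cases", {
  m <- estimate_msm(matrix(c(8, 2, 2, 8), 2), reversible = TRUE)
  expect_equal(m$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2), tolerance = 1e-10)
  expect_equal(m$mu, c(0.5, 0.5), tolerance = 1e-10)

  m2 <- estimate_msm(matrix(c(9, 1, 3, 7), 2, byrow = TRUE), reversible = FALSE)
  expect_equal(m2$T, matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE))
  expect_equal(m2$mu, c(0.75, 0.25), tolerance = 1e-10)  # left-eigenvector solve
  expect_equal(as.numeric(m2$mu %*% m2$T), m2$mu, tolerance = 1e-8)

  expect_warning(m3 <- estimate_msm(matrix(c(5, 0, 0, 4), 2)), "connected")
  expect_equal(length(m3$active_set), 1L)
})

test_that("reversible estimator satisfies detailed balance on random counts", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:8, 1)
    C <- matrix(rpois(n * n, 6) + 1, n, n)
    m <- estimate_msm(C, reversible = TRUE)
    db <- m$mu * m$T
    expect_lt(max(abs(db - t(db))), 1e-10)
    expect_equal(rowSums(m$T), rep(1, n), tolerance = 1e-10)
    expect_equal(as.numeric(m$mu %*% m$T), m$mu, tolerance = 1e-8)
  }
})

test_that("estimated stationary distribution matches long-run occupancy", {
  T_true <- matrix(c(0.90, 0.08, 0.02,
                     0.10, 0.80, 0.10,
                     0.05, 0.15, 0.80), 3, byrow = TRUE)
  ch <- discrete_chain(T_true)
  path <- discrete_chain_sample(ch, 1, 50000, seed = 13)
  m <- estimate_msm(count_matrix(path, 1), reversible = FALSE)
  occ <- tabulate(path, 3) / length(path)
  # sampling error of occupancy: crude 3-sigma bound via binomial SE
  se <- sqrt(occ * (1 - occ) / length(path)) * 5  # correlated samples
  expect_true(all(abs(m$mu - occ) < pmax(3 * se, 0.01)))
})

test_that("free energies are anchored minus-log populations", {
  m <- estimate_msm(matrix(c(8, 2, 2, 8), 2))
  expect_equal(unname(free_energy(m)$F), c(0, 0), tolerance = 1e-10)

  mu <- c(0.9, 0.1)
  m2 <- as_markov_model(matrix(c(0.95, 0.05, 0.45, 0.55), 2, byrow = TRUE), mu = mu)
  F1 <- free_energy(m2, kT = 1)
  expect_equal(unname(F1$F), c(0, log(9)), tolerance = 1e-10)
  F2 <- free_energy(m2, kT = 2)
  expect_equal(unname(F2$F), 2 * unname(F1$F), tolerance = 1e-10)
})

test_that("implied timescales follow the eigenvalue closed form and lag-invariance", {
  # direct closed form at lambda_2 = 0.6, tau = 1
  T <- matrix(c(0.8, 0.2, 0.2, 0.8), 2)  # lambda_2 = 0.6
  path <- discrete_chain_sample(discrete_chain(T), 1, 60000, seed = 4)
  it <- implied_timescales(path, lags = c(1, 2, 4, 8))
  t_at <- function(l) it$timescale[it$lag == l]
  expect_equal(t_at(1), -1 / log(0.6), tolerance = 0.1)
  # Markovian chain: flat within 10%
  expect_true(all(abs(it$timescale / t_at(1) - 1) < 0.1))

  # |lambda| -> 1 gives an infinite timescale, not a crash: the strictly
  # periodic two-state flipper has |lambda_2| = 1
  it2 <- implied_timescales(rep(1:2, 500), lags = 1)
  expect_true(is.infinite(it2$timescale))
  # very sticky (but connected) states give a large finite timescale
  it3 <- implied_timescales(c(rep(1, 1000), rep(2, 1000), 1), lags = 1)
  expect_true(is.finite(it3$timescale) && it3$timescale > 100)
})

test_that("PCCA-style coarse-graining recovers metastable blocks", {
  # two 3-state blocks with 1% inter-block leakage
  W <- matrix(0.01, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  T <- W / rowSums(W)
  m <- as_markov_model(T)
  mac <- coarse_grain(m, 2)
  expect_equal(length(unique(mac$assignment[1:3])), 1L)
  expect_equal(length(unique(mac$assignment[4:6])), 1L)
  expect_false(mac$assignment[1] == mac$assignment[4])
  expect_true(all(tabulate(mac$assignment, 2) > 0))

  expect_equal(coarse_grain(m, 1)$assignment, rep(1L, 6))
  expect_equal(coarse_grain(m, 6)$assignment, 1:6)
  expect_error(coarse_grain(m, 7), "n_macro")
})

test_that("MSM free energy recovers the exact profile of a known chain", {
  # birth-death chain whose stationary distribution is a two-well profile
  F_true <- c(0, 1.5, 3, 1.2, 0.4)
  p <- exp(-F_true); p <- p / sum(p)
  T <- matrix(0, 5, 5)
  for (i in 1:4) {
    T[i, i + 1] <- 0.2 * min(1, p[i + 1] / p[i])
    T[i + 1, i] <- 0.2 * min(1, p[i] / p[i + 1])
  }
  diag(T) <- 1 - rowSums(T)
  path <- discrete_chain_sample(discrete_chain(T), 1, 2e5, seed = 12)
  m <- estimate_msm(count_matrix(path, 1, n_states = 5), reversible = TRUE)
  F_est <- unname(free_energy(m, kT = 1)$F)
  expect_lt(max(abs(F_est - (F_true - min(F_true)))), 0.3)
})
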
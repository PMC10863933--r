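# Bulk definition, MFPTs, rate constants, binding free energy and
# trajectory bootstrap.

test_that("bulk definition is the separation predicate", {
  bd <- define_bulk(c(2, 5, 8), threshold = 4)
  expect_equal(bd$bulk, c(2L, 3L))
  expect_equal(define_bulk(c(2, 5, 8), threshold = 1)$bulk, 1:3)
  expect_error(define_bulk(c(2, 5, 8), threshold = 10), "lower")
})

test_that("MFPT solves the hitting-time system with unit conversion", {
  # geometric escape: leave state 1 with probability 0.1 per lag step
  T <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, byrow = TRUE)
  m <- as_markov_model(T, lag = 1, frame_time = 1)
  expect_equal(mfpt(m, 1, 2)$mfpt, 10)

  # deterministic hop reaches the target in exactly one lag step
  T2 <- matrix(c(0, 1, 0.5, 0.5), 2, byrow = TRUE)
  m2 <- as_markov_model(T2)
  expect_equal(mfpt(m2, 1, 2)$mfpt, 1)

  # lag and frame_time rescale physical time
  m3 <- as_markov_model(T, lag = 5, frame_time = 0.25)
  expect_equal(mfpt(m3, 1, 2)$mfpt, 10 * 5 * 0.25)

  expect_error(mfpt(m, 1, 1), "disjoint")
})

test_that("MFPT matches brute-force path simulation on a random chain", {
  T <- random_chain_T(5, seed = 77)
  m <- as_markov_model(T)
  # per-state hitting times of state 5
  res <- mfpt(m, source = 2, target = 5)
  mc <- mc_mfpt(T, start = 2, target = 5, n_walkers = 20000, seed = 3)
  expect_equal(mc$completed, 1)
  expect_lt(abs(res$mfpt - mc$mfpt), 3 * mc$se)
})

test_that("unreachable targets give an infinite MFPT", {
  T <- matrix(c(0.5, 0.5, 0, 0.5, 0.5, 0, 0, 0.5, 0.5), 3, byrow = TRUE)
  m <- as_markov_model(T, mu = c(0.5, 0.5, 0))
  expect_true(is.infinite(mfpt(m, 1, 3)$mfpt))
})

test_that("kon and koff follow the rate formulas with explicit units", {
  kon <- kon_from_mfpt(9.96e3, conc = 3.2e-3, unit = "ns")
  expect_equal(kon, 1 / (9.96e3 * 1e-9 * 3.2e-3))
  expect_equal(kon_from_mfpt(9.96e3, conc = 6.4e-3, unit = "ns"), kon / 2)
  # same answer when the MFPT is expressed in seconds
  expect_equal(kon_from_mfpt(9.96e3 * 1e-9, conc = 3.2e-3, unit = "s"), kon)

  expect_equal(koff_from_mfpt(2e-4, unit = "s"), 5e3)
  expect_equal(koff_from_mfpt(Inf), 0)
  x <- 3.7e-5
  expect_equal(koff_from_mfpt(1 / x, unit = "s") * (1 / x), 1)
})

test_that("binding free energy splits population and volume terms", {
  T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  m <- as_markov_model(T)  # mu = (0.5, 0.5)
  g0 <- free_energy_of_binding(m, bound_set = 1, bulk_set = 2, kT = 0.6,
                               box_volume = 1661, standard_volume = 1661)
  expect_equal(g0$dG, 0)

  # population ratio e with equal volumes: dG = -kT
  mu <- c(exp(1), 1) / (exp(1) + 1)
  Tq <- matrix(c(1 - 0.1 / exp(1), 0.1 / exp(1), 0.1, 0.9), 2, byrow = TRUE)
  mq <- as_markov_model(Tq, mu = mu)
  g1 <- free_energy_of_binding(mq, 1, 2, kT = 0.6163,
                               box_volume = 1661, standard_volume = 1661)
  expect_equal(g1$dG, -0.6163, tolerance = 1e-6)
  expect_equal(g1$dG_volume, 0)

  # hand-set binding chain populations
  Tb <- binding_chain_T()
  mb <- as_markov_model(Tb)
  mu_b <- mb$mu
  g2 <- free_energy_of_binding(mb, bound_set = 3, bulk_set = 1, kT = 1,
                               box_volume = 2 * 1661, standard_volume = 1661)
  expect_equal(g2$dG_population, -log(mu_b[3] / mu_b[1]))
  expect_equal(g2$dG_volume, -log(1661 / (2 * 1661)))
  expect_equal(g2$dG, g2$dG_population + g2$dG_volume)
})

test_that("kinetics from simulated data converge to ground truth", {
  Tb <- binding_chain_T()
  chain <- discrete_chain(Tb)
  mb <- as_markov_model(Tb)
  true_on <- mfpt(mb, source = 1, target = 3)$mfpt
  true_off <- mfpt(mb, source = 3, target = 1)$mfpt

  paths <- lapply(1:20, function(s) discrete_chain_sample(chain, 1, 10000, seed = s))
  m_est <- estimate_msm(count_matrix(paths, 1, n_states = 3), reversible = TRUE)
  est_on <- mfpt(m_est, 1, 3)$mfpt
  est_off <- mfpt(m_est, 3, 1)$mfpt
  expect_lt(abs(est_on - true_on) / true_on, 0.1)
  expect_lt(abs(est_off - true_off) / true_off, 0.1)
  expect_lt(max(abs(m_est$mu - chain_stationary(chain))), 0.01)
})

test_that("dG stabilizes once the bulk threshold passes the interaction range", {
  # linear chain: coordinate = separation distance; attractive interaction
  # only below separation 4, and the fully separated end dominates the
  # unbound mass (it aggregates the box's free volume)
  n <- 10
  sep <- seq_len(n)
  w <- c(exp(c(6, 4, 2)), rep(1, 6), 15)
  p <- w / sum(w)
  # reversible birth-death chain with this stationary distribution
  T <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    T[i, i + 1] <- 0.1 * min(1, p[i + 1] / p[i])
    T[i + 1, i] <- 0.1 * min(1, p[i] / p[i + 1])
  }
  diag(T) <- 1 - rowSums(T)
  m <- as_markov_model(T)
  dg_at <- function(thr) {
    bulk <- define_bulk(sep, thr)$bulk
    bound <- which(sep <= 2)
    free_energy_of_binding(m, bound, bulk, kT = 1,
                           box_volume = 1661, standard_volume = 1661)$dG
  }
  dg_beyond <- vapply(c(4.5, 5.5, 6.5, 7.5), dg_at, numeric(1))
  # plateau beyond the interaction range ...
  expect_lt(max(abs(diff(dg_beyond))), 0.1)
  # ... but strong threshold dependence while inside it
  expect_gt(abs(dg_at(2.5) - dg_at(3.5)), 0.2)
})

test_that("trajectory bootstrap resamples whole trajectories deterministically", {
  trajs <- lapply(1:10, function(i) rep(i, 5))
  est <- function(tr) c(m = mean(unlist(tr)), n = length(tr))
  bs <- bootstrap_kinetics(trajs, est, frac = 0.8, n_reps = 50, seed = 2)
  expect_equal(nrow(bs$replicates), 50L)
  expect_true(all(bs$replicates$n == 8))  # 80% of 10 trajectories
  expect_identical(bs, bootstrap_kinetics(trajs, est, frac = 0.8, n_reps = 50, seed = 2))

  # frac = 1 makes a deterministic estimator exactly constant
  bs1 <- bootstrap_kinetics(trajs, est, frac = 1, n_reps = 10, seed = 1)
  expect_equal(unname(bs1$sd["m"]), 0)
})
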
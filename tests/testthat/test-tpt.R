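# Transition path theory: committors, flux conservation, coarse-graining
# and observable-conditioned decomposition, checked against brute-force
# path simulation.

test_that("committors obey symmetry and boundary conditions", {
  # symmetric A - I - B chain: the middle state is a coin flip
  T <- matrix(c(0.8, 0.2, 0.0,
                0.1, 0.8, 0.1,
                0.0, 0.2, 0.8), 3, byrow = TRUE)
  m <- as_markov_model(T)
  qp <- committor(m, A = 1, B = 3)
  expect_equal(qp, c(0, 0.5, 1))
  qm <- committor(m, A = 1, B = 3, direction = "backward")
  expect_equal(qm, c(1, 0.5, 0))

  # a state whose mass all flows to B commits fully
  T2 <- matrix(c(0.9, 0.1, 0.0, 0.0,
                 0.2, 0.6, 0.2, 0.0,
                 0.0, 0.0, 0.1, 0.9,
                 0.0, 0.0, 0.1, 0.9), 4, byrow = TRUE)
  m2 <- as_markov_model(T2, mu = stats::setNames(rep(0.25, 4), NULL))
  qp2 <- committor(m2, A = 1, B = 4)
  expect_equal(qp2[3], 1)

  expect_error(committor(m, A = 1, B = 1), "disjoint")
})

test_that("committors match Monte Carlo first-hit probabilities", {
  T <- random_reversible_T(5, seed = 42)
  m <- as_markov_model(T)
  qp <- committor(m, A = 1, B = 5)
  for (s in 2:4) {
    mc <- mc_committor(T, A = 1, B = 5, start = s, n_walkers = 20000, seed = s)
    expect_lt(abs(qp[s] - mc$q), 3 * mc$se + 1e-6)
  }
})

test_that("committor is monotone along a birth-death chain", {
  T <- birth_death_T(8, p_up = 0.25, p_down = 0.2)
  m <- as_markov_model(T)
  qp <- committor(m, A = 1, B = 8)
  expect_true(all(diff(qp) >= -1e-12))
})

test_that("reactive flux formula and conservation identities hold", {
  # 2-state: f_AB = mu_A T_AB with unit committors
  T <- matrix(c(0.8, 0.2, 0.2, 0.8), 2)
  m <- as_markov_model(T)
  fl <- reactive_flux(m, A = 1, B = 2)
  expect_equal(fl$gross_flux[1, 2], 0.5 * 0.2)
  expect_equal(fl$total_flux, 0.1)

  # random reversible chains: conservation to 1e-10 (property test)
  for (seed in 1:200) {
    n <- 3 + (seed %% 18)  # up to 20 states
    T <- random_reversible_T(n, seed = seed)
    m <- as_markov_model(T)
    A <- 1; B <- n
    fl <- reactive_flux(m, A, B)
    expect_true(all(fl$q_plus >= -1e-12 & fl$q_plus <= 1 + 1e-12))
    expect_true(all(fl$q_minus >= -1e-12 & fl$q_minus <= 1 + 1e-12))
    out_A <- sum(fl$net_flux[A, -A]) - sum(fl$net_flux[-A, A])
    in_B <- sum(fl$net_flux[-B, B]) - sum(fl$net_flux[B, -B])
    expect_lt(abs(out_A - fl$total_flux), 1e-10)
    expect_lt(abs(in_B - fl$total_flux), 1e-10)
    inter <- setdiff(seq_len(n), c(A, B))
    div <- rowSums(fl$net_flux) - colSums(fl$net_flux)
    expect_lt(max(abs(div[inter])), 1e-10)
  }
})

test_that("total reactive flux matches brute-force reactive-path counting", {
  # two parallel paths with asymmetric rates
  T <- matrix(c(0.80, 0.15, 0.05, 0.00,
                0.30, 0.60, 0.00, 0.10,
                0.10, 0.00, 0.80, 0.10,
                0.00, 0.15, 0.15, 0.70), 4, byrow = TRUE)
  T <- T / rowSums(T)
  m <- as_markov_model(T)
  fl <- reactive_flux(m, A = 1, B = 4)
  mc <- vapply(1:6, function(s) mc_total_flux(T, A = 1, B = 4, n_steps = 1.5e5,
                                              seed = 1000 + s), numeric(1))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(fl$total_flux - mean(mc)), 3 * se + 0.05 * fl$total_flux)
})

test_that("coarse-grained fluxes conserve totals and flag small edges", {
  T <- random_reversible_T(9, seed = 9)
  m <- as_markov_model(T)
  fl <- reactive_flux(m, A = 1, B = 9)

  # identity coarse-graining leaves the net flux unchanged
  cf_id <- coarse_flux(fl, seq_len(9))
  expect_equal(cf_id$net_flux, fl$net_flux, tolerance = 1e-12)

  macro <- c(1, 2, 2, 2, 2, 3, 3, 3, 4)
  cf <- coarse_flux(fl, macro)
  # source macrostate has no incoming flux: its outgoing percentages sum to 100
  out_src <- cf$edges[cf$edges$from == 1, ]
  expect_equal(sum(out_src$percent_total), 100, tolerance = 1e-8)
  expect_true(all(cf$edges$shown == (cf$edges$percent_total >= 5)))
  cf0 <- coarse_flux(fl, macro, display_threshold = 0)
  expect_true(all(cf0$edges$shown))
  # both percentage conventions are reported
  expect_true(all(c("percent_total", "percent_outflow") %in% names(cf0$edges)))
})

test_that("observable decomposition reduces to coarse flux at k = 1", {
  T <- random_reversible_T(8, seed = 17)
  m <- as_markov_model(T)
  macro <- c(1, 1, 2, 2, 2, 3, 3, 3)
  obs <- c(0.1, 0.2, 0.5, 0.6, 0.55, 0.9, 0.95, 0.85)
  fl <- reactive_flux(m, A = 1, B = 8)
  cf <- coarse_flux(fl, macro, display_threshold = 0)
  od <- observable_flux_decomposition(m, A = 1, B = 8, macro, obs, k = 1)
  expect_equal(od$net_flux, cf$net_flux, tolerance = 1e-12)
  expect_equal(nrow(od$nodes), 3L)

  # constant observable: one cluster per macrostate regardless of k
  od2 <- suppressMessages(
    observable_flux_decomposition(m, A = 1, B = 8, macro, rep(1, 8), k = 4)
  )
  expect_equal(nrow(od2$nodes), 3L)
})

test_that("flux through high-observable channels matches path counting", {
  # binding chain with two parallel intermediate channels: 1 (bulk) ->
  # {2 unfolded, 3 folded} -> 4 (bound); the folded channel carries more rate
  T <- matrix(c(0.80, 0.14, 0.06, 0.00,
                0.20, 0.70, 0.00, 0.10,
                0.10, 0.00, 0.60, 0.30,
                0.00, 0.05, 0.15, 0.80), 4, byrow = TRUE)
  m <- as_markov_model(T)
  foldedness <- c(0, 0, 1, 1)
  macro <- c(1, 2, 2, 3)
  od <- observable_flux_decomposition(m, A = 1, B = 4, macro, foldedness, k = 2)
  # fraction of total flux leaving bulk through the folded intermediate
  folded_node <- od$nodes$node[od$nodes$macro == 2 & od$nodes$obs_mean == 1]
  unfolded_node <- od$nodes$node[od$nodes$macro == 2 & od$nodes$obs_mean == 0]
  bulk_node <- od$nodes$node[od$nodes$macro == 1]
  f_folded <- od$net_flux[bulk_node, folded_node]
  f_unfolded <- od$net_flux[bulk_node, unfolded_node]
  frac_folded <- f_folded / (f_folded + f_unfolded)

  # brute-force: long path, count which intermediate each reactive 1->4
  # segment passed through last
  set.seed(99)
  cum <- t(apply(T, 1, cumsum))
  s <- 1L; last_A <- TRUE; via <- integer(0); inter_seen <- NA_integer_
  for (i in 1:200000) {
    s <- which(runif(1) <= cum[s, ] + 1e-15)[1]
    if (s %in% c(2L, 3L) && last_A) inter_seen <- s
    if (s == 1L) { last_A <- TRUE; inter_seen <- NA_integer_ }
    if (s == 4L && last_A) {
      via <- c(via, inter_seen)
      last_A <- FALSE
    }
  }
  frac_mc <- mean(via == 3L, na.rm = TRUE)
  se <- sqrt(frac_mc * (1 - frac_mc) / length(via))
  expect_lt(abs(frac_folded - frac_mc), 3 * se + 0.02)
})

test_that("maximum-flux pathway follows the widest channel", {
  T <- matrix(c(0.80, 0.15, 0.05, 0.00,
                0.10, 0.80, 0.00, 0.10,
                0.10, 0.00, 0.88, 0.02,
                0.00, 0.10, 0.05, 0.85), 4, byrow = TRUE)
  m <- as_markov_model(T)
  fl <- reactive_flux(m, A = 1, B = 4)
  p <- max_flux_path(fl$net_flux, A = 1, B = 4)
  expect_equal(p$path[1], 1)
  expect_equal(p$path[length(p$path)], 4)
  expect_gt(p$bottleneck, 0)
})
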
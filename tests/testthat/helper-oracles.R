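# Brute-force simulation oracles, independent of the linear-algebra code
# paths they validate. All are vectorized over many parallel walkers: at
# each step, walkers in the same state draw their next state together.

# Step a population of walkers one transition under T.
step_walkers <- function(states, T) {
  out <- states
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(ncol(T), length(idx), replace = TRUE, prob = T[s, ])
  }
  out
}

# Monte Carlo forward committor: fraction of walkers from `start` hitting B
# before A. Returns estimate and its binomial standard error.
mc_committor <- function(T, A, B, start, n_walkers = 20000L, max_steps = 10000L,
                         seed = 1L) {
  set.seed(seed)
  states <- rep(start, n_walkers)
  hitB <- rep(NA, n_walkers)
  active <- rep(TRUE, n_walkers)
  hitB[states %in% A] <- FALSE
  hitB[states %in% B] <- TRUE
  active[!is.na(hitB)] <- FALSE
  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    states[active] <- step_walkers(states[active], T)
    inA <- active & states %in% A
    inB <- active & states %in% B
    hitB[inA] <- FALSE
    hitB[inB] <- TRUE
    active[inA | inB] <- FALSE
  }
  p <- mean(hitB, na.rm = TRUE)
  list(q = p, se = sqrt(p * (1 - p) / sum(!is.na(hitB))))
}

# Monte Carlo mean first passage time (in steps of T) from `start` to the
# target set; returns mean and standard error of the hitting time.
mc_mfpt <- function(T, start, target, n_walkers = 20000L, max_steps = 50000L,
                    seed = 1L) {
  set.seed(seed)
  states <- rep(start, n_walkers)
  hit_time <- rep(NA_real_, n_walkers)
  hit_time[states %in% target] <- 0
  active <- is.na(hit_time)
  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    states[active] <- step_walkers(states[active], T)
    done <- active & states %in% target
    hit_time[done] <- it
    active[done] <- FALSE
  }
  h <- hit_time[!is.na(hit_time)]
  list(mfpt = mean(h), se = stats::sd(h) / sqrt(length(h)),
       completed = length(h) / n_walkers)
}

# Long-run reactive flux oracle: simulates one long path, chops it into
# reactive A->B segments and counts (a) transitions per ordered state pair
# inside reactive segments, (b) the A->B transition rate. Returns the
# empirical total flux (reactive A->B completions per step).
mc_total_flux <- function(T, A, B, n_steps = 2e5, seed = 1L) {
  set.seed(seed)
  cum <- t(apply(T, 1, cumsum))
  s <- A[1]
  last_core <- "A"
  completions <- 0L
  u <- runif(n_steps)
  for (i in seq_len(n_steps)) {
    s <- which(u[i] <= cum[s, ] + 1e-15)[1]
    if (s %in% A) last_core <- "A"
    else if (s %in% B) {
      if (last_core == "A") completions <- completions + 1L
      last_core <- "B"
    }
  }
  completions / n_steps
}

# Random reversible chain: symmetric positive weights plus a diagonal.
random_reversible_T <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.01, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- diag(W) + runif(n, 0.5, 2)
  W / rowSums(W)
}

# Random (possibly non-reversible) chain with all-positive entries.
random_chain_T <- function(n, seed) {
  set.seed(seed)
  W <- matrix(rexp(n * n) + 0.02, n, n)
  W / rowSums(W)
}

# One-dimensional birth-death chain with given up/down rates.
birth_death_T <- function(n, p_up = 0.3, p_down = 0.2) {
  T <- matrix(0, n, n)
  for (i in seq_len(n)) {
    up <- if (i < n) p_up else 0
    down <- if (i > 1) p_down else 0
    T[i, i] <- 1 - up - down
    if (i < n) T[i, i + 1] <- up
    if (i > 1) T[i, i - 1] <- down
  }
  T
}

# Toy binding chain: bulk (1) <-> encounter (2) <-> bound (3), with slow
# unbinding; detailed-balance by construction (tridiagonal).
binding_chain_T <- function(k_on = 0.05, k_enc_off = 0.1, k_fold = 0.2,
                            k_unfold = 0.01) {
  matrix(c(
    1 - k_on,      k_on,                        0,
    k_enc_off,     1 - k_enc_off - k_fold,      k_fold,
    0,             k_unfold,                    1 - k_unfold
  ), 3, 3, byrow = TRUE)
}
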
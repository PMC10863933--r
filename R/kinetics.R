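# Binding kinetics from MSMs: bulk-state construction, mean first passage
# times, association/dissociation rates, binding free energy with
# standard-state correction, and trajectory-bootstrap uncertainty.

#' Define the bulk (fully separated) state set
#'
#' The bulk is the unbound reference: all microstates whose minimum
#' inter-unit separation exceeds a distance threshold.
#'
#' @param separation per-microstate minimum separation (length units).
#' @param threshold separation cutoff (> 0); states strictly above it form
#'   the bulk.
#' @return object of class `bulk_definition`: `bulk` (state indices),
#'   `threshold`, `separation`.
#' @export
define_bulk <- function(separation, threshold) {
  check_scalar(threshold, "threshold", positive = TRUE)
  if (!is.numeric(separation) || length(separation) < 1L) {
    stop("`separation` must be a numeric per-state vector", call. = FALSE)
  }
  bulk <- which(separation > threshold)
  if (length(bulk) == 0L) {
    stop("no state exceeds the separation threshold; lower `threshold` to obtain a non-empty bulk",
         call. = FALSE)
  }
  structure(list(bulk = bulk, threshold = threshold, separation = separation),
            class = "bulk_definition")
}

#' Mean first passage time between state sets
#'
#' Solves the standard hitting-time linear system
#' \eqn{(I - T_{CC})\, h = 1} on the complement of the target set; `h` is in
#' lag units and is converted to frames (`x lag`) and physical time
#' (`x lag x frame_time`). The source-set value is the average over source
#' states weighted by the stationary distribution restricted to the source.
#'
#' @param model a `markov_model`.
#' @param source,target disjoint non-empty sets of active-state indices.
#' @return list with `mfpt` (physical time), `mfpt_frames`, `per_state`
#'   (hitting time from each state, physical time), `unit_note`. An
#'   unreachable target gives `Inf`.
#' @export
mfpt <- function(model, source, target) {
  stopifnot(inherits(model, "markov_model"))
  n <- nrow(model$T)
  source <- check_state_set(source, n, "source")
  target <- check_state_set(target, n, "target")
  if (length(intersect(source, target)) > 0L) {
    stop("`source` and `target` must be disjoint", call. = FALSE)
  }
  C <- setdiff(seq_len(n), target)
  h <- rep(0, n)
  Tcc <- model$T[C, C, drop = FALSE]
  hc <- tryCatch(
    solve(diag(length(C)) - Tcc, rep(1, length(C))),
    error = function(e) rep(Inf, length(C))
  )
  if (any(hc < 0)) hc <- rep(Inf, length(C))  # singular up to round-off
  h[C] <- hc
  w <- model$mu[source]
  # degenerate stationary weight (e.g. absorbing chains): fall back to uniform
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(source), length(source))
  m_lag <- sum(w * h[source])
  per_state <- h * model$lag * model$frame_time
  list(
    mfpt = m_lag * model$lag * model$frame_time,
    mfpt_frames = m_lag * model$lag,
    per_state = per_state,
    unit_note = sprintf("physical time = hitting time (lag units) x lag (%d frames) x frame_time (%g)",
                        model$lag, model$frame_time)
  )
}

# Time-unit conversions to seconds for rate constants.
.time_to_seconds <- c(s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9, ps = 1e-12,
                      fs = 1e-15)

to_seconds <- function(time, unit) {
  if (!unit %in% names(.time_to_seconds)) {
    stop(sprintf("unknown time unit '%s' (use one of %s)", unit,
                 paste(names(.time_to_seconds), collapse = ", ")), call. = FALSE)
  }
  time * .time_to_seconds[[unit]]
}

#' Association rate from the binding MFPT
#'
#' \eqn{k_{on} = 1 / (\mathrm{MFPT}_{on} \cdot C)} in \eqn{M^{-1} s^{-1}}:
#' under pseudo-first-order conditions the binding MFPT at simulated
#' concentration `conc` determines the bimolecular on-rate.
#'
#' @param mfpt_on mean first passage time from bulk to bound.
#' @param conc effective concentration in molar.
#' @param unit time unit of `mfpt_on` ("s", "ms", "us", "ns", "ps", "fs").
#' @return kon in per-molar per-second.
#' @export
kon_from_mfpt <- function(mfpt_on, conc, unit = "ns") {
  check_scalar(mfpt_on, "mfpt_on", positive = TRUE, finite = FALSE)
  check_scalar(conc, "conc", positive = TRUE)
  1 / (to_seconds(mfpt_on, unit) * conc)
}

#' Dissociation rate from the unbinding MFPT
#'
#' \eqn{k_{off} = 1 / \mathrm{MFPT}_{off}} in \eqn{s^{-1}}.
#'
#' @param mfpt_off mean first passage time from bound to bulk.
#' @param unit time unit of `mfpt_off`.
#' @return koff in per-second (0 when the MFPT is infinite).
#' @export
koff_from_mfpt <- function(mfpt_off, unit = "s") {
  check_scalar(mfpt_off, "mfpt_off", positive = TRUE, finite = FALSE)
  if (is.infinite(mfpt_off)) return(0)
  1 / to_seconds(mfpt_off, unit)
}

#' Binding free energy from MSM populations
#'
#' \deqn{\Delta G = -kT \ln\frac{\mu(\mathrm{bound})}{\mu(\mathrm{bulk})}
#'       - kT \ln\frac{V_0}{V_\mathrm{box}}}
#' The first term is the population ratio at the simulated concentration;
#' the second is the standard-state volume correction that converts it to a
#' reference concentration (1 M corresponds to `standard_volume` = 1661
#' cubic Angstrom per molecule). Both contributions are reported separately.
#'
#' @param model a `markov_model`.
#' @param bound_set,bulk_set active-state index sets.
#' @param kT thermal energy in the output energy unit (e.g. 0.6163 kcal/mol
#'   at 310 K).
#' @param box_volume simulation box volume per complex (same units as
#'   `standard_volume`).
#' @param standard_volume standard-state volume (default 1661 cubic
#'   Angstrom, i.e. 1 M).
#' @return list with `dG`, `dG_population`, `dG_volume`, `mu_bound`,
#'   `mu_bulk`.
#' @export
free_energy_of_binding <- function(model, bound_set, bulk_set, kT,
                                   box_volume, standard_volume = 1661) {
  stopifnot(inherits(model, "markov_model"))
  n <- nrow(model$T)
  bound_set <- check_state_set(bound_set, n, "bound_set")
  bulk_set <- check_state_set(bulk_set, n, "bulk_set")
  check_scalar(kT, "kT", positive = TRUE)
  check_scalar(box_volume, "box_volume", positive = TRUE)
  check_scalar(standard_volume, "standard_volume", positive = TRUE)
  mu_bound <- sum(model$mu[bound_set])
  mu_bulk <- sum(model$mu[bulk_set])
  if (mu_bound <= 0 || mu_bulk <= 0) {
    stop("bound and bulk sets must both carry non-zero stationary population",
         call. = FALSE)
  }
  dG_pop <- -kT * log(mu_bound / mu_bulk)
  dG_vol <- -kT * log(standard_volume / box_volume)
  list(dG = dG_pop + dG_vol, dG_population = dG_pop, dG_volume = dG_vol,
       mu_bound = mu_bound, mu_bulk = mu_bulk)
}

#' Trajectory-bootstrap uncertainty for kinetic estimates
#'
#' Resamples whole trajectories (preserving temporal correlation), re-runs
#' the full estimation pipeline on each replicate and reports the replicate
#' table with per-quantity mean and standard deviation. Each replicate
#' draws `ceiling(frac * n_traj)` trajectories without replacement.
#'
#' @param trajs list of trajectories (any type the estimator accepts).
#' @param estimator function taking a list of trajectories and returning a
#'   named numeric vector of kinetic quantities.
#' @param frac fraction of trajectories per replicate (default 0.8).
#' @param n_reps number of replicates (default 50).
#' @param seed integer seed.
#' @return list with `replicates` (n_reps x quantities data.frame), `mean`,
#'   `sd`.
#' @export
bootstrap_kinetics <- function(trajs, estimator, frac = 0.8, n_reps = 50L,
                               seed = 1L) {
  stopifnot(is.list(trajs), is.function(estimator))
  check_scalar(frac, "frac", positive = TRUE)
  if (frac > 1) stop("`frac` must be <= 1", call. = FALSE)
  n_reps <- check_count(n_reps, "n_reps")
  n <- length(trajs)
  m <- ceiling(frac * n)
  idx_sets <- with_seed(seed, lapply(seq_len(n_reps), function(i) sample.int(n, m)))
  rows <- lapply(idx_sets, function(idx) estimator(trajs[idx]))
  tab <- as.data.frame(do.call(rbind, rows))
  list(replicates = tab,
       mean = vapply(tab, mean, numeric(1)),
       sd = vapply(tab, stats::sd, numeric(1)))
}
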
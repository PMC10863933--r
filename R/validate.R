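# Validation against exact ground truth: free-energy recovery error of a
# sampling campaign relative to the Boltzmann distribution of its system.

#' Free-energy recovery error of a campaign
#'
#' Discretizes all campaign frames onto a fixed uniform grid over the
#' system domain, estimates a reversible MSM at the campaign lag, and
#' compares the per-bin free energies with the exact Boltzmann values from
#' [analytic_stationary()]. Bins never visited get a smoothed occupancy of
#' half a pseudo-frame (`0.5 / n_frames`), so unexplored regions contribute
#' a large but finite error. Both profiles are anchored at their minimum.
#'
#' @param record a [run_campaign()] `campaign_record`.
#' @param system the [toy_system()] the campaign sampled.
#' @param n_bins number of uniform grid bins (default 30).
#' @param mu_min only bins whose true equilibrium probability exceeds this
#'   enter the error (default 1e-3).
#' @param lag MSM lag in frames (default: the campaign lag).
#' @return list with `rmse` (kT units), `F_model`, `F_true`, `bins_used`.
#' @export
free_energy_rmse <- function(record, system, n_bins = 30L, mu_min = 1e-3,
                             lag = NULL) {
  stopifnot(inherits(record, "campaign_record"), inherits(system, "toy_system"))
  if (is.null(lag)) lag <- record$config$lag
  edges <- seq(system$domain[1], system$domain[2], length.out = n_bins + 1L)
  p_true <- analytic_stationary(system, edges)
  F_true <- -system$kT * log(p_true)
  F_true <- F_true - min(F_true)

  dtrajs <- lapply(record$trajectories, function(tr) {
    pmin(pmax(findInterval(tr$x, edges, rightmost.closed = TRUE), 1L), n_bins)
  })
  n_frames <- sum(lengths(dtrajs))
  C <- count_matrix(dtrajs, lag, n_states = n_bins)
  model <- suppressWarnings(estimate_msm(C, reversible = TRUE, lag = lag))
  mu_hat <- rep(0, n_bins)
  mu_hat[model$active_set] <- model$mu
  # additive smoothing: unvisited bins carry half a pseudo-frame
  mu_hat <- mu_hat + 0.5 / n_frames
  mu_hat <- mu_hat / sum(mu_hat)
  F_model <- -system$kT * log(mu_hat)
  F_model <- F_model - min(F_model)

  use <- p_true > mu_min
  list(rmse = sqrt(mean((F_model[use] - F_true[use])^2)),
       F_model = F_model, F_true = F_true, bins_used = which(use))
}
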
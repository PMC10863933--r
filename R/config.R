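# Campaign configuration: human-editable YAML with schema validation and
# defaults.

# Allowed keys and defaults per config section. Defaults follow the method's
# reference settings: exploration constant c = 0.01, 40 epochs, and 2,000
# analysis microstates.
config_schema <- function() {
  list(
    system = list(
      name = "double_well", barrier_height = 5, asymmetry = 0,
      kT = 1, diffusion = 1, dt = 1e-3
    ),
    policy = list(
      name = "bandit", c = 0.01, n_macro = 4, counts_mode = "frames",
      reward_mode = "recompute"
    ),
    sampling = list(
      epochs = 40, sims_per_epoch = 4, traj_length = 500, x0 = -1
    ),
    msm = list(
      lag = 20, k = 50, k_analysis = 2000, tica_lag = 20, n_components = 3,
      reversible_analysis = TRUE, frame_time = 1
    ),
    kinetics = list(
      threshold = 4, conc = 3.2e-3, kT = 0.6163, box_volume = 262144,
      standard_volume = 1661, bootstrap_reps = 50, bootstrap_frac = 0.8
    ),
    seed = 1
  )
}

#' Load and validate a campaign configuration
#'
#' Reads a YAML campaign config, validates every key against the published
#' schema (unknown keys are rejected, naming the offender) and fills in
#' defaults for anything omitted.
#'
#' @param path path to a YAML file.
#' @return object of class `campaign_config` (a named list mirroring the
#'   schema sections).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Validate a configuration list against the schema
#'
#' @param raw named list of config sections (as parsed from YAML).
#' @return a `campaign_config` with defaults filled in.
#' @export
validate_config <- function(raw) {
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key: '%s'", unknown[1]), call. = FALSE)
  }
  out <- schema
  for (section in names(raw)) {
    if (section == "seed") {
      out$seed <- raw$seed
      next
    }
    sec <- raw[[section]]
    if (!is.list(sec)) stop(sprintf("config section '%s' must be a mapping", section), call. = FALSE)
    bad <- setdiff(names(sec), names(schema[[section]]))
    if (length(bad) > 0L) {
      stop(sprintf("unknown config key: '%s.%s'", section, bad[1]), call. = FALSE)
    }
    out[[section]][names(sec)] <- sec
  }
  check_count(out$seed, "seed", min = 0L)
  check_count(out$sampling$epochs, "sampling.epochs")
  check_count(out$sampling$sims_per_epoch, "sampling.sims_per_epoch")
  check_count(out$sampling$traj_length, "sampling.traj_length", min = 2L)
  if (!out$policy$name %in% c("bandit", "counts", "random")) {
    stop("policy.name must be one of 'bandit', 'counts', 'random'", call. = FALSE)
  }
  structure(out, class = "campaign_config")
}

#' Write a configuration back to YAML
#'
#' `load_config(save_config(cfg, path))` is the identity.
#'
#' @param config a `campaign_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "campaign_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the toy system described by a configuration
#'
#' @param config a `campaign_config`.
#' @return a [toy_system()].
#' @export
system_from_config <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  s <- config$system
  switch(s$name,
    double_well = make_double_well(s$barrier_height, s$asymmetry,
                                   kT = s$kT, diffusion = s$diffusion, dt = s$dt),
    flat = make_flat(kT = s$kT, diffusion = s$diffusion, dt = s$dt),
    stop(sprintf("unknown system name '%s'", s$name), call. = FALSE)
  )
}

#' Build a campaign definition from a configuration
#'
#' @param config a `campaign_config`.
#' @return a [campaign()].
#' @export
campaign_from_config <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  campaign(
    epochs = config$sampling$epochs,
    sims_per_epoch = config$sampling$sims_per_epoch,
    traj_length = config$sampling$traj_length,
    policy = config$policy$name,
    c = config$policy$c,
    x0 = config$sampling$x0,
    lag = config$msm$lag,
    k = config$msm$k,
    n_macro = config$policy$n_macro,
    reward_mode = config$policy$reward_mode,
    seed = config$seed,
    frame_time = config$msm$frame_time
  )
}
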
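# Campaign reports: a machine-readable JSON document plus a human-readable
# print method. Reports contain no timestamps so a rerun from the same
# config and seed reproduces the file bit-for-bit.

#' Summarize a campaign into a report
#'
#' Collects per-epoch state-discovery counts, the frame-budget accounting,
#' optional kinetics and flux results, and the seeds/versions needed to
#' reproduce the run.
#'
#' @param record a [run_campaign()] `campaign_record` (or `NULL` for an
#'   empty report).
#' @param kinetics optional named list of kinetic quantities (e.g. from the
#'   kinetics module) to embed.
#' @param flux_edges optional data.frame of flux edges (from
#'   [coarse_flux()]) to embed.
#' @param discovery_bins number of uniform coordinate bins used for the
#'   per-epoch discovered-state count (default 20).
#' @return object of class `campaign_report` (a named list); serialize with
#'   [write_report()].
#' @export
make_report <- function(record = NULL, kinetics = NULL, flux_edges = NULL,
                        discovery_bins = 20L) {
  rep <- list(
    package = "banditmsm",
    version = as.character(utils::packageVersion("banditmsm")),
    n_trajectories = 0L,
    n_frames = 0L,
    seed = NA_integer_,
    policy = NA_character_,
    epochs = list()
  )
  if (!is.null(record)) {
    stopifnot(inherits(record, "campaign_record"))
    lens <- vapply(record$trajectories, function(tr) length(tr$x), numeric(1))
    rep$n_trajectories <- length(record$trajectories)
    rep$n_frames <- as.integer(sum(lens))
    rep$seed <- record$config$seed
    rep$policy <- record$config$policy
    rep$config <- unclass(record$config)
    rep$system <- record$system_name
    rep$frame_budget <- record$config$epochs * record$config$sims_per_epoch *
      record$config$traj_length
    # per-epoch discovery: number of coordinate bins visited so far
    all_epochs <- vapply(record$trajectories, function(tr) tr$epoch, integer(1))
    rng <- range(unlist(lapply(record$trajectories, `[[`, "x")))
    edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = discovery_bins + 1L)
    rep$epochs <- lapply(sort(unique(all_epochs)), function(e) {
      xs <- unlist(lapply(record$trajectories[all_epochs <= e], `[[`, "x"))
      list(epoch = e,
           n_traj = sum(all_epochs <= e),
           states_discovered = length(unique(findInterval(xs, edges,
                                                          rightmost.closed = TRUE))),
           max_coordinate = max(xs))
    })
  }
  if (!is.null(kinetics)) rep$kinetics <- kinetics
  if (!is.null(flux_edges)) rep$flux_edges <- flux_edges
  structure(rep, class = "campaign_report")
}

#' Write a report as JSON
#'
#' @param report a [make_report()] `campaign_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "campaign_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf("Campaign report (banditmsm %s)\n", x$version))
  cat(sprintf("  policy: %s | seed: %s\n", x$policy, x$seed))
  cat(sprintf("  trajectories: %d | frames: %d\n", x$n_trajectories, x$n_frames))
  if (length(x$epochs) > 0L) {
    last <- x$epochs[[length(x$epochs)]]
    cat(sprintf("  states discovered by final epoch: %d (max coordinate %.3f)\n",
                last$states_discovered, last$max_coordinate))
  }
  if (!is.null(x$kinetics)) {
    cat("  kinetics:\n")
    for (nm in names(x$kinetics)) {
      cat(sprintf("    %s: %s\n", nm, format(x$kinetics[[nm]], digits = 4)))
    }
  }
  invisible(x)
}
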
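# Trajectory persistence: plain-text frame arrays with JSON sidecars.
#
# Each trajectory is stored as a CSV of frames plus a JSON sidecar holding
# its provenance (epoch, spawning action, seed, frame_time). Numeric values
# round-trip losslessly (full double precision via 17 significant digits).

#' Open (or create) a trajectory store
#'
#' @param root directory path; created if missing.
#' @return object of class `trajectory_store`.
#' @export
trajectory_store <- function(root) {
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  structure(list(root = root), class = "trajectory_store")
}

#' Persist a batch of trajectories
#'
#' @param store a [trajectory_store()].
#' @param batch list of trajectories, each a list with `x` (numeric vector
#'   or matrix of frames), `epoch`, `action` (`NA` for seeded starts),
#'   `seed`, and optionally `frame_time` (default 1).
#' @return invisibly, the trajectory ids written.
#' @export
save_batch <- function(store, batch) {
  stopifnot(inherits(store, "trajectory_store"), is.list(batch))
  existing <- list_traj_ids(store)
  next_id <- if (length(existing) == 0L) 1L else max(existing) + 1L
  ids <- integer(0)
  for (tr in batch) {
    id <- next_id
    next_id <- next_id + 1L
    x <- tr$x
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(x)))
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(store$root, sprintf("traj_%06d.csv", id)),
                     row.names = FALSE, quote = FALSE)
    meta <- list(
      id = id,
      epoch = as.integer(tr$epoch),
      action = if (is.null(tr$action) || is.na(tr$action)) NA_integer_ else as.integer(tr$action),
      seed = as.integer(tr$seed),
      frame_time = if (is.null(tr$frame_time)) 1 else tr$frame_time,
      n_frames = nrow(x),
      n_features = ncol(x)
    )
    jsonlite::write_json(meta, file.path(store$root, sprintf("traj_%06d.json", id)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    ids <- c(ids, id)
  }
  invisible(ids)
}

list_traj_ids <- function(store) {
  files <- list.files(store$root, pattern = "^traj_[0-9]+\\.csv$")
  as.integer(sub("^traj_([0-9]+)\\.csv$", "\\1", files))
}

#' Load trajectories from a store
#'
#' @param store a [trajectory_store()].
#' @param epochs optional integer vector: return only trajectories from
#'   these epochs.
#' @return list of trajectories (`x`, `epoch`, `action`, `seed`,
#'   `frame_time`), ordered by id. A trajectory whose JSON sidecar is
#'   missing aborts the load.
#' @export
load_batch <- function(store, epochs = NULL) {
  stopifnot(inherits(store, "trajectory_store"))
  ids <- sort(list_traj_ids(store))
  out <- list()
  for (id in ids) {
    meta_path <- file.path(store$root, sprintf("traj_%06d.json", id))
    if (!file.exists(meta_path)) {
      stop(sprintf("trajectory %d has no metadata sidecar; refusing to load", id),
           call. = FALSE)
    }
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(epochs) && !(meta$epoch %in% epochs)) next
    df <- utils::read.csv(file.path(store$root, sprintf("traj_%06d.csv", id)))
    x <- as.matrix(df)
    dimnames(x) <- NULL
    if (ncol(x) == 1L) x <- as.numeric(x)
    out[[length(out) + 1L]] <- list(
      x = x, epoch = meta$epoch,
      action = if (is.null(meta$action) || is.na(meta$action)) NA_integer_ else meta$action,
      seed = meta$seed, frame_time = meta$frame_time
    )
  }
  out
}
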
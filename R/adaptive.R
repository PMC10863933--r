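# Adaptive sampling policies and the epochal campaign loop.
#
# The acquisition problem is framed as a multi-armed bandit: each MSM
# microstate is an action, spawning a trajectory from a state is a pick, and
# the reward is minus the MSM free energy averaged over the frames the
# trajectory visits. UCB1 balances exploiting low-free-energy (stable)
# states with exploring rarely picked ones; with fully discounted returns
# (discount gamma = 0) each pick is judged only by its own trajectory.

#' Create an empty bandit state
#'
#' @param n_actions number of actions (MSM states).
#' @param c exploration constant (dimensionless, default 0.01).
#' @return object of class `bandit_state`: `Q` (value estimates, `NA` until
#'   first visit), `N` (pick counts), `t` (total picks), `c`, `gamma`
#'   (fixed 0: totally discounted rewards).
#' @export
bandit_state <- function(n_actions, c = 0.01) {
  n_actions <- check_count(n_actions, "n_actions")
  check_scalar(c, "c")
  if (c < 0) stop("`c` must be >= 0", call. = FALSE)
  structure(list(Q = rep(NA_real_, n_actions), N = rep(0L, n_actions),
                 t = 0L, c = c, gamma = 0),
            class = "bandit_state")
}

#' @export
print.bandit_state <- function(x, ...) {
  cat(sprintf("<bandit_state> %d actions, t=%d picks, c=%g, %d visited\n",
              length(x$Q), x$t, x$c, sum(x$N > 0)))
  invisible(x)
}

#' Reward of a trajectory under a free-energy profile
#'
#' The reward is minus the free energy averaged over the frames of the
#' trajectory: \eqn{r = \mathrm{mean}_t( -F_{s_t} )}. Because profiles are
#' anchored at `min F = 0`, the maximum achievable reward is 0 (a
#' trajectory that never leaves the most stable state). Frames whose state
#' is outside the profile's active set are skipped; if no frame remains the
#' reward is undefined (`NA`) and the caller should skip the update.
#'
#' @param dtraj integer state sequence (original state indices).
#' @param F a [free_energy()] `free_energy_profile`.
#' @return scalar reward (kT units), or `NA` with a warning when no frame
#'   lies in the active set.
#' @export
trajectory_reward <- function(dtraj, F) {
  stopifnot(inherits(F, "free_energy_profile"))
  pos <- match(as.integer(dtraj), F$active_set)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L) {
    warning("no frame of the trajectory lies in the active set; reward undefined",
            call. = FALSE)
    return(NA_real_)
  }
  -mean(F$F[pos])
}

#' UCB1 scores for every action
#'
#' \deqn{\mathrm{score}(a) = Q_t(a) + c \sqrt{\ln t / N_t(a)}}
#' Unvisited actions (`N = 0`) score \eqn{+\infty} so they dominate any
#' visited action; with `c = 0` the score is pure greedy exploitation.
#'
#' @param state a [bandit_state()].
#' @return numeric vector of per-action scores.
#' @export
ucb_scores <- function(state) {
  stopifnot(inherits(state, "bandit_state"))
  t <- max(state$t, 1L)
  bonus <- ifelse(state$N > 0, state$c * sqrt(log(t) / state$N), Inf)
  score <- ifelse(state$N > 0, state$Q + bonus, Inf)
  score
}

#' Select actions by UCB score
#'
#' Picks the `n_pick` actions with the highest UCB scores; ties (including
#' ties at \eqn{+\infty} among unvisited actions) are broken uniformly at
#' random under the seed.
#'
#' @param state a `bandit_state`.
#' @param n_pick number of actions to select.
#' @param seed integer seed for tie-breaking.
#' @return integer vector of `n_pick` action indices (may repeat only if
#'   `n_pick` exceeds the number of actions).
#' @export
bandit_select <- function(state, n_pick, seed) {
  stopifnot(inherits(state, "bandit_state"))
  n_pick <- check_count(n_pick, "n_pick")
  n <- length(state$Q)
  score <- ucb_scores(state)
  with_seed(seed, {
    jitter <- stats::runif(n)
    ord <- order(-score, jitter)
    if (n_pick <= n) ord[seq_len(n_pick)]
    else c(ord, sample(ord, n_pick - n, replace = TRUE))
  })
}

#' Update the bandit after observing a reward
#'
#' Incremental-mean update: `N(a) += 1`, `t += 1`,
#' `Q(a) <- Q(a) + (r - Q(a)) / N(a)`. Other actions are untouched.
#'
#' @param state a `bandit_state`.
#' @param action action index.
#' @param reward observed reward; `NA` rewards leave the state unchanged.
#' @return updated `bandit_state`.
#' @export
bandit_update <- function(state, action, reward) {
  stopifnot(inherits(state, "bandit_state"))
  action <- check_count(action, "action")
  if (action > length(state$Q)) stop("unknown action", call. = FALSE)
  if (is.na(reward)) return(state)
  state$N[action] <- state$N[action] + 1L
  state$t <- state$t + 1L
  q <- state$Q[action]
  state$Q[action] <- if (is.na(q)) reward else q + (reward - q) / state$N[action]
  state
}

#' Counts-based acquisition over macrostates
#'
#' The low-counts baseline: macrostates are drawn with probability
#' proportional to `1 / count`, so rarely sampled metastable regions are
#' revisited preferentially.
#'
#' @param macro_frame_counts per-macrostate counts (frames by default);
#'   only macrostates with positive counts are eligible.
#' @param n_pick number of draws (with replacement).
#' @param seed integer seed.
#' @return integer vector of selected macrostate indices.
#' @export
counts_select <- function(macro_frame_counts, n_pick, seed) {
  n_pick <- check_count(n_pick, "n_pick")
  if (any(macro_frame_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  eligible <- which(macro_frame_counts > 0)
  if (length(eligible) == 0L) stop("no macrostate has been sampled yet", call. = FALSE)
  p <- 1 / macro_frame_counts[eligible]
  p <- p / sum(p)
  with_seed(seed, eligible[sample.int(length(eligible), n_pick,
                                      replace = TRUE, prob = p)])
}

#' Pick respawn frames for selected states
#'
#' For each selected state, draws one frame uniformly among the frames
#' assigned to that state. A selected state with no frames is replaced by a
#' resample of another selected (non-empty) state; if none of the selected
#' states has frames, an error is raised.
#'
#' @param selected_states integer vector of state (cluster) indices.
#' @param frames frames x features matrix of all stored frames.
#' @param assignments integer cluster index per frame (e.g.
#'   `discretization$assign`).
#' @param seed integer seed.
#' @return list with `frame_index` (one row index per selection), `state`
#'   (the state each frame was drawn for, after any resampling), and
#'   `coords` (the selected frames).
#' @export
respawn <- function(selected_states, frames, assignments, seed) {
  if (is.null(dim(frames))) frames <- matrix(frames, ncol = 1L)
  if (nrow(frames) != length(assignments)) {
    stop("`assignments` must have one entry per frame", call. = FALSE)
  }
  selected_states <- as.integer(selected_states)
  nonempty <- selected_states[selected_states %in% assignments]
  if (length(nonempty) == 0L) {
    stop("none of the selected states has any frame to respawn from", call. = FALSE)
  }
  with_seed(seed, {
    states <- vapply(selected_states, function(s) {
      if (s %in% assignments) s else nonempty[sample.int(length(nonempty), 1L)]
    }, integer(1))
    idx <- vapply(states, function(s) {
      cand <- which(assignments == s)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    list(frame_index = idx, state = states,
         coords = frames[idx, , drop = FALSE])
  })
}

#' Define an adaptive sampling campaign
#'
#' @param epochs number of sampling rounds (default 40).
#' @param sims_per_epoch trajectories spawned per round.
#' @param traj_length frames per trajectory.
#' @param policy acquisition policy: `"bandit"` (UCB1 over microstates),
#'   `"counts"` (1/counts over macrostates), or `"random"` (non-adaptive
#'   control: every round restarts from the initial coordinates).
#' @param c UCB1 exploration constant (default 0.01).
#' @param x0 starting coordinate(s) for the first epoch (recycled across
#'   `sims_per_epoch`).
#' @param lag MSM lag time in frames used during the campaign.
#' @param k number of k-means microstates per epoch (capped at the number
#'   of frames available).
#' @param n_macro macrostates for the counts policy (default 4).
#' @param reward_mode `"recompute"` (default): at every epoch all past
#'   trajectory rewards are recomputed against the current free-energy
#'   profile and the bandit is rebuilt, which also re-identifies actions
#'   after re-clustering; `"incremental"`: rewards are frozen at the epoch
#'   they were earned and carried to the nearest new cluster center.
#' @param seed campaign master seed; every stochastic step derives from it.
#' @param frame_time physical time per frame (metadata).
#' @return object of class `campaign`.
#' @export
campaign <- function(epochs = 40L, sims_per_epoch = 4L, traj_length = 500L,
                     policy = c("bandit", "counts", "random"), c = 0.01,
                     x0 = -1, lag = 20L, k = 50L, n_macro = 4L,
                     reward_mode = c("recompute", "incremental"),
                     seed = 1L, frame_time = 1) {
  policy <- match.arg(policy)
  reward_mode <- match.arg(reward_mode)
  obj <- list(
    epochs = check_count(epochs, "epochs"),
    sims_per_epoch = check_count(sims_per_epoch, "sims_per_epoch"),
    traj_length = check_count(traj_length, "traj_length", min = 2L),
    policy = policy, c = c, x0 = x0,
    lag = check_count(lag, "lag"), k = check_count(k, "k"),
    n_macro = check_count(n_macro, "n_macro"),
    reward_mode = reward_mode, seed = as.integer(seed),
    frame_time = frame_time
  )
  structure(obj, class = "campaign")
}

#' Run an adaptive sampling campaign on a toy system
#'
#' Epoch 1 seeds `sims_per_epoch` trajectories from the configured start
#' coordinates. Each later epoch: (1) discretizes all frames collected so
#' far with mini-batch k-means, (2) estimates a non-reversible MSM at the
#' campaign lag (per-epoch models are throwaway, so the cheaper estimator is
#' used), (3) anchors the free-energy profile and scores every completed
#' trajectory's reward, (4) selects the next actions with the configured
#' policy, (5) respawns one conformation per selected state and simulates.
#' If MSM estimation fails in an epoch, selection falls back to random
#' restarts for that epoch (logged in the epoch record).
#'
#' @param system a [toy_system()].
#' @param config a [campaign()].
#' @return object of class `campaign_record`: `trajectories` (list of
#'   lists: `x`, `epoch`, `action`, `seed`), `epoch_log` (data.frame),
#'   `bandit_history` (per-epoch bandit snapshots for the bandit policy),
#'   `config`, `system_name`. The total frame budget is exactly
#'   `epochs * sims_per_epoch * traj_length`.
#' @export
run_campaign <- function(system, config) {
  stopifnot(inherits(system, "toy_system"), inherits(config, "campaign"))
  n_epochs <- config$epochs
  n_sims <- config$sims_per_epoch
  seeds <- matrix(derive_seeds(config$seed, n_epochs * (n_sims + 2L)),
                  nrow = n_epochs)
  x0 <- rep_len(config$x0, n_sims)

  trajectories <- list()
  epoch_log <- list()
  bandit_history <- list()
  bandit <- NULL  # persistent state for incremental reward mode

  for (epoch in seq_len(n_epochs)) {
    sim_seeds <- seeds[epoch, seq_len(n_sims)]
    policy_seed <- seeds[epoch, n_sims + 1L]
    respawn_seed <- seeds[epoch, n_sims + 2L]
    fallback <- FALSE
    policy_used <- config$policy

    if (epoch == 1L || config$policy == "random") {
      starts <- x0
      actions <- rep(NA_integer_, n_sims)
    } else {
      frames <- unlist(lapply(trajectories, `[[`, "x"))
      model_try <- tryCatch({
        k_eff <- min(config$k, length(frames))
        disc <- cluster_frames(frames, k_eff, seed = policy_seed)
        dtrajs <- split_assignments(disc$assign, trajectories)
        C <- count_matrix(dtrajs, config$lag, n_states = k_eff)
        model <- suppressWarnings(
          estimate_msm(C, reversible = FALSE, lag = config$lag,
                       frame_time = config$frame_time)
        )
        list(disc = disc, dtrajs = dtrajs, model = model,
             F = free_energy(model, kT = system$kT))
      }, error = function(e) e)

      if (inherits(model_try, "error")) {
        fallback <- TRUE
        policy_used <- "random (fallback)"
        starts <- x0
        actions <- rep(NA_integer_, n_sims)
      } else {
        disc <- model_try$disc
        dtrajs <- model_try$dtrajs
        F <- model_try$F
        picked <- tryCatch({
          if (config$policy == "bandit") {
            sel <- bandit_epoch_select(trajectories, dtrajs, disc, F, config,
                                       bandit, policy_seed)
            bandit <- sel$bandit
            bandit_history[[length(bandit_history) + 1L]] <-
              list(epoch = epoch, Q = bandit$Q, N = bandit$N, t = bandit$t)
            sel$selected
          } else { # counts
            counts_epoch_select(model_try$model, disc, config, policy_seed)
          }
        }, error = function(e) e)
        if (inherits(picked, "error")) {
          fallback <- TRUE
          policy_used <- "random (fallback)"
          starts <- x0
          actions <- rep(NA_integer_, n_sims)
        } else {
          rs <- respawn(picked, matrix(frames, ncol = 1L), disc$assign,
                        seed = respawn_seed)
          starts <- as.numeric(rs$coords)
          actions <- rs$state
        }
      }
    }

    for (s in seq_len(n_sims)) {
      x <- simulate_toy(system, starts[s], config$traj_length,
                        seed = sim_seeds[s])
      trajectories[[length(trajectories) + 1L]] <-
        list(x = x, epoch = epoch, action = actions[s], seed = sim_seeds[s])
    }

    all_x <- unlist(lapply(trajectories, `[[`, "x"))
    epoch_log[[epoch]] <- data.frame(
      epoch = epoch, policy = policy_used, fallback = fallback,
      n_traj_total = length(trajectories),
      n_frames_total = length(all_x),
      max_coordinate = max(all_x), min_coordinate = min(all_x)
    )
  }

  structure(
    list(trajectories = trajectories,
         epoch_log = do.call(rbind, epoch_log),
         bandit_history = bandit_history,
         config = config, system_name = system$name),
    class = "campaign_record"
  )
}

#' @export
print.campaign_record <- function(x, ...) {
  cat(sprintf("<campaign_record> %s policy, %d epochs, %d trajectories, %d frames\n",
              x$config$policy, x$config$epochs, length(x$trajectories),
              sum(vapply(x$trajectories, function(tr) length(tr$x), numeric(1)))))
  invisible(x)
}

# Split a flat per-frame assignment vector back into per-trajectory
# discrete trajectories.
split_assignments <- function(assign, trajectories) {
  lens <- vapply(trajectories, function(tr) length(tr$x), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(lens), function(i) assign[starts[i]:ends[i]])
}

# Bandit selection for one epoch. In "recompute" mode the bandit is rebuilt
# from scratch: every past trajectory's action is re-identified as the
# cluster of its starting frame under the current discretization and its
# reward is recomputed against the current (re-anchored) free-energy
# profile, so value estimates stay comparable across re-clusterings. In
# "incremental" mode Q/N are carried over to the nearest new center and only
# the newest trajectories are scored.
bandit_epoch_select <- function(trajectories, dtrajs, disc, F, config,
                                prev_bandit, seed) {
  n_actions <- disc$k
  if (config$reward_mode == "recompute" || is.null(prev_bandit)) {
    b <- bandit_state(n_actions, c = config$c)
    for (i in seq_along(trajectories)) {
      a <- dtrajs[[i]][1]
      r <- suppressWarnings(trajectory_reward(dtrajs[[i]], F))
      b <- bandit_update(b, a, r)
    }
  } else {
    # carry Q/N over to the nearest new action
    b <- bandit_state(n_actions, c = config$c)
    carry <- assign_frames(matrix(attr(prev_bandit, "centers"), ncol = 1L), disc)
    for (a_old in which(prev_bandit$N > 0)) {
      a_new <- carry[a_old]
      n_old <- prev_bandit$N[a_old]
      q_old <- prev_bandit$Q[a_old]
      tot <- b$N[a_new] + n_old
      b$Q[a_new] <- if (b$N[a_new] == 0) q_old
                    else (b$Q[a_new] * b$N[a_new] + q_old * n_old) / tot
      b$N[a_new] <- tot
      b$t <- b$t + n_old
    }
    epochs_seen <- vapply(trajectories, function(tr) tr$epoch, integer(1))
    for (i in which(epochs_seen == max(epochs_seen))) {
      a <- dtrajs[[i]][1]
      r <- suppressWarnings(trajectory_reward(dtrajs[[i]], F))
      b <- bandit_update(b, a, r)
    }
  }
  attr(b, "centers") <- as.numeric(disc$centers)
  selected <- bandit_select(b, config$sims_per_epoch, seed = seed)
  list(bandit = b, selected = selected)
}

# Counts selection for one epoch: PCCA macrostates over the epoch MSM,
# 1/frame-count acquisition, then a random microstate within each chosen
# macrostate (handled by respawn via the refined assignment).
counts_epoch_select <- function(model, disc, config, seed) {
  n_active <- length(model$active_set)
  n_macro <- min(config$n_macro, n_active)
  macro <- suppressWarnings(coarse_grain(model, n_macro))
  # frame counts per macrostate (frames in trimmed-away states are ignored)
  macro_of_cluster <- rep(NA_integer_, disc$k)
  macro_of_cluster[model$active_set] <- macro$assignment
  frame_macro <- macro_of_cluster[disc$assign]
  counts <- tabulate(frame_macro, nbins = n_macro)
  picked_macros <- counts_select(counts, config$sims_per_epoch, seed = seed)
  # map each macrostate pick to a random micro (cluster) inside it
  with_seed(seed + 1L, vapply(picked_macros, function(m) {
    micro <- model$active_set[macro$assignment == m]
    micro[sample.int(length(micro), 1L)]
  }, integer(1)))
}
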
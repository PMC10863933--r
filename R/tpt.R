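# Transition path theory: committors, reactive fluxes, coarse-grained flux
# networks and observable-conditioned flux decomposition.

#' Committor probabilities
#'
#' Forward committor: probability that a path started in state `i` reaches
#' the sink set `B` before the source set `A`; solves the linear system
#' with boundary conditions `q+ = 0` on `A`, `q+ = 1` on `B`. The backward
#' committor is the forward committor of the time-reversed chain
#' \eqn{\tilde T_{ij} = \mu_j T_{ji} / \mu_i} with the roles of `A` and `B`
#' exchanged.
#'
#' @param model a `markov_model`.
#' @param A,B disjoint non-empty sets of active-state indices (positions in
#'   the active set, 1-based).
#' @param direction "forward" or "backward".
#' @return numeric vector of per-state committor probabilities.
#' @export
committor <- function(model, A, B, direction = c("forward", "backward")) {
  stopifnot(inherits(model, "markov_model"))
  direction <- match.arg(direction)
  n <- nrow(model$T)
  A <- check_state_set(A, n, "A")
  B <- check_state_set(B, n, "B")
  if (length(intersect(A, B)) > 0L) stop("`A` and `B` must be disjoint", call. = FALSE)
  if (direction == "forward") {
    solve_committor(model$T, A, B)
  } else {
    mu <- model$mu
    Trev <- t(model$T * mu) / mu  # Trev[i, j] = mu_j T_ji / mu_i
    solve_committor(Trev, B, A)   # backward: 1 on A, 0 on B
  }
}

check_state_set <- function(S, n, name) {
  S <- unique(as.integer(S))
  if (length(S) < 1L || any(S < 1L) || any(S > n)) {
    stop(sprintf("`%s` must be a non-empty set of active-state indices in 1..%d", name, n),
         call. = FALSE)
  }
  S
}

# q = 0 on zero_set, 1 on one_set; interior solves (I - T_CC) q_C = T_CB 1.
solve_committor <- function(T, zero_set, one_set) {
  n <- nrow(T)
  q <- numeric(n)
  q[one_set] <- 1
  C <- setdiff(seq_len(n), c(zero_set, one_set))
  if (length(C) > 0L) {
    Tcc <- T[C, C, drop = FALSE]
    rhs <- rowSums(T[C, one_set, drop = FALSE])
    q[C] <- solve(diag(length(C)) - Tcc, rhs)
    q[C] <- pmin(pmax(q[C], 0), 1)  # clamp round-off
  }
  q
}

#' Reactive flux network between a source and a sink set
#'
#' Computes the gross reactive flux
#' \eqn{f_{ij} = \mu_i q^-_i T_{ij} q^+_j} for \eqn{i \ne j}, the net flux
#' \eqn{f^+_{ij} = \max(f_{ij} - f_{ji}, 0)}, and the total reactive flux
#' out of `A` (probability mass per lag time). The net flux is divergence
#' free on intermediate states and conserved from `A` to `B`.
#'
#' @inheritParams committor
#' @return object of class `flux_network`: `A`, `B`, `q_plus`, `q_minus`,
#'   `gross_flux`, `net_flux`, `total_flux`, `mu`, `lag`, `frame_time`.
#' @export
reactive_flux <- function(model, A, B) {
  stopifnot(inherits(model, "markov_model"))
  n <- nrow(model$T)
  A <- check_state_set(A, n, "A")
  B <- check_state_set(B, n, "B")
  if (length(intersect(A, B)) > 0L) stop("`A` and `B` must be disjoint", call. = FALSE)
  qp <- committor(model, A, B, "forward")
  qm <- committor(model, A, B, "backward")
  mu <- model$mu
  f <- (mu * qm) * model$T * rep(qp, each = n)
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(net[A, setdiff(seq_len(n), A), drop = FALSE])
  structure(list(A = A, B = B, q_plus = qp, q_minus = qm,
                 gross_flux = f, net_flux = net, total_flux = total,
                 mu = mu, lag = model$lag, frame_time = model$frame_time),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> %d states, |A|=%d |B|=%d, total flux %.4g per lag\n",
              nrow(x$net_flux), length(x$A), length(x$B), x$total_flux))
  invisible(x)
}

#' Coarse-grain a flux network onto macrostates
#'
#' Sums the net microstate flux across macrostate pairs, re-applies the
#' positive-part netting at macro level, and reports each edge as a
#' percentage both of the total A-to-B flux and of its source node's
#' outflow. Edges below `display_threshold` percent of total flux are
#' flagged (`shown = FALSE`) but retained in the data.
#'
#' @param flux a [reactive_flux()] `flux_network`.
#' @param macro a [coarse_grain()] `macrostates` object (or an integer
#'   assignment vector over the flux network's states).
#' @param display_threshold percent-of-total-flux cutoff for flagging edges
#'   (default 5).
#' @return list with `net_flux` (macro matrix), `edges` (data.frame: `from`,
#'   `to`, `net_flux`, `percent_total`, `percent_outflow`, `shown`),
#'   `total_flux`, `assignment`.
#' @export
coarse_flux <- function(flux, macro, display_threshold = 5) {
  stopifnot(inherits(flux, "flux_network"))
  assign <- if (inherits(macro, "macrostates")) macro$assignment else as.integer(macro)
  n <- nrow(flux$net_flux)
  if (length(assign) != n) stop("macrostate assignment length must match the number of states", call. = FALSE)
  m <- max(assign)
  agg <- matrix(0, m, m)
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      if (k == l) next
      agg[k, l] <- sum(flux$net_flux[assign == k, assign == l, drop = FALSE])
    }
  }
  netM <- pmax(agg - t(agg), 0)
  idx <- which(netM > 0, arr.ind = TRUE)
  out_flow <- rowSums(netM)
  edges <- data.frame(
    from = idx[, 1], to = idx[, 2],
    net_flux = netM[idx],
    percent_total = 100 * netM[idx] / flux$total_flux,
    percent_outflow = 100 * netM[idx] / out_flow[idx[, 1]]
  )
  edges$shown <- edges$percent_total >= display_threshold
  edges <- edges[order(-edges$net_flux), , drop = FALSE]
  rownames(edges) <- NULL
  list(net_flux = netM, edges = edges, total_flux = flux$total_flux,
       assignment = assign)
}

#' Observable-conditioned intra-macrostate flux decomposition
#'
#' Splits each macrostate into sub-states by 1-D k-means on a per-microstate
#' scalar observable (e.g. a mean foldedness/helicity painted on each
#' microstate), then recomputes the net flux between the resulting
#' (macrostate, observable-cluster) nodes. With `k = 1` this reduces
#' exactly to [coarse_flux()].
#'
#' @param model a `markov_model`.
#' @param A,B source and sink sets (active-state indices).
#' @param macro a `macrostates` object (or assignment vector).
#' @param observable numeric per-microstate scalar, defined for all active
#'   states.
#' @param k target number of observable clusters per macrostate; macrostates
#'   with fewer distinct observable values get fewer clusters (logged via
#'   `message`).
#' @param centers optional fixed 1-D cluster centers shared by all
#'   macrostates (microstates join the nearest center); overrides per-macro
#'   k-means.
#' @return list with `nodes` (data.frame: `node`, `macro`, `obs_cluster`,
#'   `obs_mean`, `n_micro`), `edges` (as in [coarse_flux()]), `net_flux`
#'   (node matrix), `assignment` (microstate to node), `total_flux`.
#' @export
observable_flux_decomposition <- function(model, A, B, macro, observable,
                                          k, centers = NULL) {
  stopifnot(inherits(model, "markov_model"))
  assign_macro <- if (inherits(macro, "macrostates")) macro$assignment else as.integer(macro)
  n <- nrow(model$T)
  if (length(assign_macro) != n) stop("macrostate assignment length must match active states", call. = FALSE)
  if (length(observable) != n || any(!is.finite(observable))) {
    stop("`observable` must be finite and defined on all active microstates", call. = FALSE)
  }
  k <- check_count(k, "k")
  flux <- reactive_flux(model, A, B)

  node_of <- integer(n)
  nodes <- list()
  next_id <- 0L
  for (mstate in sort(unique(assign_macro))) {
    members <- which(assign_macro == mstate)
    obs <- observable[members]
    if (!is.null(centers)) {
      cl <- vapply(obs, function(o) which.min(abs(o - centers)), integer(1))
      used <- sort(unique(cl))
      cl <- match(cl, used)
      n_cl <- length(used)
    } else {
      n_distinct <- length(unique(obs))
      n_cl <- min(k, n_distinct)
      if (n_cl < k) {
        message(sprintf("macrostate %d: only %d distinct observable values; using %d clusters",
                        mstate, n_distinct, n_cl))
      }
      cl <- kmeans_1d(obs, n_cl)
    }
    for (j in seq_len(n_cl)) {
      next_id <- next_id + 1L
      sub <- members[cl == j]
      node_of[sub] <- next_id
      nodes[[next_id]] <- data.frame(
        node = next_id, macro = mstate, obs_cluster = j,
        obs_mean = mean(observable[sub]), n_micro = length(sub)
      )
    }
  }
  nodes <- do.call(rbind, nodes)
  cf <- coarse_flux(flux, node_of, display_threshold = 0)
  list(nodes = nodes, edges = cf$edges, net_flux = cf$net_flux,
       assignment = node_of, total_flux = flux$total_flux)
}

# Deterministic 1-D k-means: quantile-seeded Lloyd iterations.
kmeans_1d <- function(x, k) {
  if (k == 1L) return(rep(1L, length(x)))
  centers <- unname(stats::quantile(unique(x), probs = (seq_len(k) - 0.5) / k,
                                    type = 7))
  for (it in 1:100) {
    cl <- vapply(x, function(v) which.min(abs(v - centers)), integer(1))
    new_centers <- centers
    for (j in seq_len(k)) if (any(cl == j)) new_centers[j] <- mean(x[cl == j])
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  cl <- vapply(x, function(v) which.min(abs(v - centers)), integer(1))
  # renumber to drop any emptied cluster
  used <- sort(unique(cl))
  match(cl, used)
}

#' Greedy bottleneck (maximum-flux) pathway from source to sink
#'
#' Returns the path from any state in `A` to any state in `B` maximizing the
#' minimum net-flux edge along the path (the widest path), found with a
#' modified Dijkstra search on the net flux matrix.
#'
#' @param net_flux net flux matrix (e.g. `flux$net_flux` or a coarse-grained
#'   matrix).
#' @param A,B source and sink node sets.
#' @return list with `path` (node sequence) and `bottleneck` (limiting flux).
#' @export
max_flux_path <- function(net_flux, A, B) {
  n <- nrow(net_flux)
  width <- rep(-Inf, n)
  prev <- rep(NA_integer_, n)
  width[A] <- Inf
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & width > -Inf)
    if (length(cand) == 0L) break
    u <- cand[which.max(width[cand])]
    visited[u] <- TRUE
    if (u %in% B) {
      path <- u
      while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
      return(list(path = path, bottleneck = width[u]))
    }
    for (v in which(net_flux[u, ] > 0)) {
      w <- min(width[u], net_flux[u, v])
      if (w > width[v]) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
  list(path = integer(0), bottleneck = 0)
}
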
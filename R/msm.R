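# Markov state model estimation: transition counts, (reversible) maximum
# likelihood transition matrices, stationary distributions, free energies,
# implied timescales, and metastable coarse-graining.

#' Lagged transition count matrix
#'
#' Counts observed transitions \eqn{i \to j} at lag `lag` with a sliding
#' window over each trajectory independently; trajectories shorter than
#' `lag + 1` contribute nothing.
#'
#' @param dtrajs integer vector or list of integer vectors of 1-based state
#'   indices.
#' @param lag lag time in frames (>= 1).
#' @param n_states number of states; defaults to the largest index observed.
#' @return `n_states x n_states` integer count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- check_count(lag, "lag")
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  n_states <- check_count(n_states, "n_states")
  C <- matrix(0L, n_states, n_states)
  used <- FALSE
  for (d in dtrajs) {
    d <- as.integer(d)
    if (length(d) <= lag) next
    used <- TRUE
    from <- d[seq_len(length(d) - lag)]
    to <- d[seq_len(length(d) - lag) + lag]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  if (!used) stop("all trajectories are shorter than `lag` + 1; no transitions counted",
                  call. = FALSE)
  dimnames(C) <- NULL
  C
}

#' Estimate a Markov state model from transition counts
#'
#' Restricts the counts to the largest strongly connected component of the
#' transition graph (required for a well-defined stationary distribution),
#' then estimates a row-stochastic transition matrix:
#' \itemize{
#'   \item `reversible = TRUE` (default): maximum-likelihood estimate under
#'     detailed balance \eqn{\mu_i T_{ij} = \mu_j T_{ji}} via the standard
#'     self-consistent fixed-point iteration on the reversible count
#'     variables;
#'   \item `reversible = FALSE`: plain row normalization of the counts, with
#'     the stationary distribution from the leading left eigenvector.
#' }
#'
#' @param C non-negative count matrix.
#' @param reversible enforce detailed balance (default `TRUE`).
#' @param lag lag time in frames the counts were taken at (metadata).
#' @param frame_time physical time per frame (metadata, default 1).
#' @param tol convergence tolerance of the reversible fixed point.
#' @param max_iter iteration cap for the reversible fixed point.
#' @return object of class `markov_model` with fields `T` (row-stochastic,
#'   over the active set), `mu` (stationary distribution), `lag`,
#'   `frame_time`, `active_set` (original state indices retained),
#'   `reversible`, and `n_states_full`.
#' @export
estimate_msm <- function(C, reversible = TRUE, lag = 1L, frame_time = 1,
                         tol = 1e-14, max_iter = 100000L) {
  C <- as.matrix(C)
  if (any(C < 0)) stop("count matrix must be non-negative", call. = FALSE)
  n_full <- nrow(C)
  active <- largest_scc(C)
  if (length(active) < 1L) stop("no connected set of states in the counts", call. = FALSE)
  if (length(active) < n_full) {
    warning(sprintf("trimming to largest strongly connected component: %d of %d states retained",
                    length(active), n_full), call. = FALSE)
  }
  Cs <- C[active, active, drop = FALSE]

  if (reversible) {
    fit <- reversible_mle(Cs, tol = tol, max_iter = max_iter)
    T <- fit$T
    mu <- fit$mu
  } else {
    T <- Cs / rowSums(Cs)
    mu <- stationary_from_T(T)
  }
  structure(
    list(T = T, mu = mu, lag = as.integer(lag), frame_time = frame_time,
         active_set = active, reversible = reversible, n_states_full = n_full,
         counts = Cs),
    class = "markov_model"
  )
}

#' Wrap an explicit transition matrix as a Markov model
#'
#' For analysis-only use: builds a `markov_model` directly from a known
#' row-stochastic matrix (e.g. a ground-truth chain), bypassing estimation.
#'
#' @param T row-stochastic matrix.
#' @param mu stationary distribution; computed from the leading left
#'   eigenvector when `NULL`.
#' @param lag lag time in frames the matrix is valid at.
#' @param frame_time physical time per frame.
#' @param reversible whether `T` satisfies detailed balance (checked when
#'   `TRUE`).
#' @return a `markov_model` over all states.
#' @export
as_markov_model <- function(T, mu = NULL, lag = 1L, frame_time = 1,
                            reversible = NULL) {
  T <- as.matrix(T)
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-10)) {
    stop("`T` must be row-stochastic (rows sum to 1 within 1e-10)", call. = FALSE)
  }
  if (is.null(mu)) mu <- stationary_from_T(T)
  mu <- mu / sum(mu)
  if (is.null(reversible)) {
    db <- mu * T
    reversible <- max(abs(db - t(db))) < 1e-10
  }
  structure(
    list(T = T, mu = mu, lag = as.integer(lag), frame_time = frame_time,
         active_set = seq_len(nrow(T)), reversible = reversible,
         n_states_full = nrow(T), counts = NULL),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d active states (of %d), lag=%d frames, %s\n",
              length(x$active_set), x$n_states_full, x$lag,
              if (x$reversible) "reversible" else "non-reversible"))
  invisible(x)
}

# Largest strongly connected component of the C > 0 transition graph.
# Largest by state count; ties broken by total counts inside the component.
largest_scc <- function(C) {
  n <- nrow(C)
  if (n == 1L) return(if (C[1, 1] > 0) 1L else integer(0))
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    weight <- vapply(best, function(b) {
      idx <- which(comp$membership == b)
      sum(C[idx, idx])
    }, numeric(1))
    best <- best[which.max(weight)]
  }
  members <- which(comp$membership == best)
  # a singleton with no self-transition has no defined dynamics
  if (length(members) == 1L && C[members, members] == 0) {
    stop("largest connected component is a single state with no self-transitions",
         call. = FALSE)
  }
  sort(members)
}

# Self-consistent reversible maximum-likelihood estimator. Iterates the
# fixed point x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j) on the symmetric
# unnormalized flux variables x; mu is the row sum of x at convergence.
reversible_mle <- function(C, tol = 1e-14, max_iter = 100000L) {
  n <- nrow(C)
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    q <- ci / xi
    denom <- outer(q, q, "+")
    x_new <- Csym / denom
    x_new[Csym == 0] <- 0
    x_new <- x_new / sum(x_new)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < tol) break
  }
  mu <- rowSums(x)
  T <- x / mu
  # guard against round-off: renormalize rows exactly
  T <- T / rowSums(T)
  list(T = T, mu = mu / sum(mu))
}

#' Per-state free energies from an MSM
#'
#' \eqn{F_i = -kT \ln \mu_i}, shifted so the minimum is 0 (the most
#' populated state is the reference).
#'
#' @param model a [estimate_msm()] `markov_model`.
#' @param kT thermal energy the free energies are expressed in (default 1).
#' @return object of class `free_energy_profile`: list with `F` (per active
#'   state, named by original state index), `kT`, `active_set`.
#' @export
free_energy <- function(model, kT = 1) {
  stopifnot(inherits(model, "markov_model"))
  check_scalar(kT, "kT", positive = TRUE)
  F <- -kT * log(model$mu)
  F <- F - min(F)
  names(F) <- as.character(model$active_set)
  structure(list(F = F, kT = kT, active_set = model$active_set),
            class = "free_energy_profile")
}

#' Implied relaxation timescales across lag times
#'
#' For each lag \eqn{\tau}, estimates an MSM and reports
#' \eqn{t_k(\tau) = -\tau / \ln |\lambda_k(\tau)|} for the top non-unit
#' eigenvalues. Eigenvalues at or above 1 give infinite timescales (reported
#' as `Inf`, not an error). A Markovian input chain gives timescales flat in
#' the lag.
#'
#' @param dtrajs discrete trajectories (vector or list).
#' @param lags integer vector of lag times in frames.
#' @param n_timescales how many timescales to report (default 1).
#' @param reversible passed to [estimate_msm()].
#' @return data.frame with columns `lag`, `process` (2 = slowest non-unit),
#'   `eigenvalue`, `timescale` (frames).
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 1L,
                               reversible = TRUE) {
  n_timescales <- check_count(n_timescales, "n_timescales")
  out <- list()
  for (lag in lags) {
    C <- count_matrix(dtrajs, lag)
    m <- suppressWarnings(estimate_msm(C, reversible = reversible, lag = lag))
    ev <- eigen(m$T, only.values = TRUE)$values
    lam <- sort(abs(ev), decreasing = TRUE)
    lam <- lam[-1]                      # drop the unit (stationary) eigenvalue
    kmax <- min(n_timescales, length(lam))
    if (kmax < 1L) next
    lam <- lam[seq_len(kmax)]
    ts <- ifelse(lam >= 1 - 1e-15, Inf, -lag / log(lam))
    out[[length(out) + 1L]] <- data.frame(
      lag = lag, process = seq_len(kmax) + 1L, eigenvalue = lam, timescale = ts
    )
  }
  do.call(rbind, out)
}

#' Metastable coarse-graining of an MSM (PCCA-style)
#'
#' Assigns microstates to `n_macro` metastable macrostates from the dominant
#' eigenvectors of the transition matrix, using the PCCA+ inner-simplex
#' construction: the `n_macro` most spread rows of the eigenvector matrix are
#' taken as simplex vertices, fuzzy memberships follow from the linear
#' transform onto that simplex, and states are hardened by argmax
#' membership. Every macrostate is non-empty (each vertex state belongs to
#' its own macrostate).
#'
#' @param model a `markov_model`.
#' @param n_macro number of macrostates, `1 <= n_macro <=` number of active
#'   states.
#' @return object of class `macrostates`: `n_macro`, `assignment` (integer
#'   macrostate per active microstate), `membership` (fuzzy matrix),
#'   `metastability` (sum of the `n_macro` leading eigenvalues; values much
#'   below `n_macro` flag a weakly metastable split).
#' @export
coarse_grain <- function(model, n_macro) {
  stopifnot(inherits(model, "markov_model"))
  n <- nrow(model$T)
  n_macro <- check_count(n_macro, "n_macro")
  if (n_macro > n) stop("`n_macro` must not exceed the number of active states", call. = FALSE)
  if (n_macro == 1L) {
    return(structure(list(n_macro = 1L, assignment = rep(1L, n),
                          membership = matrix(1, n, 1), metastability = 1),
                     class = "macrostates"))
  }
  if (n_macro == n) {
    return(structure(list(n_macro = n, assignment = seq_len(n),
                          membership = diag(n), metastability = sum(diag(model$T))),
                     class = "macrostates"))
  }
  X <- dominant_eigenvectors(model, n_macro)
  meta <- attr(X, "eigenvalue_sum")
  verts <- inner_simplex_vertices(X)
  A <- X[verts, , drop = FALSE]
  # near-degenerate eigenvector structure makes the vertex matrix singular;
  # the pseudo-inverse still yields a usable membership transform
  chi <- tryCatch(X %*% solve(A),
                  error = function(e) X %*% MASS::ginv(A))
  assign <- max.col(chi, ties.method = "first")
  # guarantee non-empty macrostates (vertices anchor their own macro)
  for (m in seq_len(n_macro)) assign[verts[m]] <- m
  if (meta < 0.5 * n_macro) {
    warning("low metastability: the requested number of macrostates exceeds the spectral gap structure",
            call. = FALSE)
  }
  structure(list(n_macro = n_macro, assignment = assign, membership = chi,
                 metastability = meta),
            class = "macrostates")
}

# Top right eigenvectors of T, computed through the mu-symmetrized matrix
# when the model is reversible (real spectrum, orthonormal basis) and via
# real parts otherwise. First column is the constant vector.
dominant_eigenvectors <- function(model, m) {
  T <- model$T
  mu <- model$mu
  if (model$reversible) {
    s <- sqrt(mu)
    S <- (T * rep(s, times = length(s)) / rep(s, each = length(s)))
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    ord <- order(e$values, decreasing = TRUE)[seq_len(m)]
    X <- e$vectors[, ord, drop = FALSE] / s
    vals <- e$values[ord]
  } else {
    e <- eigen(T)
    ord <- order(Re(e$values), decreasing = TRUE)[seq_len(m)]
    X <- Re(e$vectors[, ord, drop = FALSE])
    vals <- Re(e$values[ord])
  }
  X[, 1] <- 1  # stationary right eigenvector, fixed sign/scale
  attr(X, "eigenvalue_sum") <- sum(vals)
  X
}

# PCCA+ "inner simplex" vertex search: pick the row farthest from the
# origin, then repeatedly the row farthest from the span of those picked.
inner_simplex_vertices <- function(X) {
  n <- nrow(X); m <- ncol(X)
  verts <- integer(m)
  Y <- X
  d <- rowSums(Y^2)
  verts[1] <- which.max(d)
  Y <- sweep(Y, 2, Y[verts[1], ])
  for (k in 2:m) {
    d <- rowSums(Y^2)
    verts[k] <- which.max(d)
    v <- Y[verts[k], ]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) {
      v <- v / nv
      Y <- Y - (Y %*% v) %*% t(v)
    }
  }
  verts
}
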
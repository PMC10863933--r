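# Time-lagged independent component analysis: linear projections maximizing
# autocorrelation at a lag, used to extract slow collective coordinates
# before clustering.

#' Fit a TICA model
#'
#' Solves the symmetrized time-lagged generalized eigenproblem
#' \deqn{C_\tau v = \lambda C_0 v}
#' where \eqn{C_0} is the instantaneous covariance and \eqn{C_\tau} the
#' symmetrized time-lagged covariance of the mean-free features, estimated
#' over all frame pairs `(t, t + lag)` pooled across trajectories. Solved
#' through the whitened symmetric form \eqn{C_0^{-1/2} C_\tau C_0^{-1/2}};
#' a ridge `epsilon` is added to \eqn{C_0} when it is (near-)singular.
#' Components are ordered by decreasing eigenvalue magnitude and signed so
#' the largest-magnitude loading of each component is positive.
#'
#' @param trajs matrix or list of matrices (frames x features).
#' @param lag lag time in frames; every trajectory must be longer than it.
#' @param n_components number of projections to keep (default: all).
#' @param epsilon ridge added to the instantaneous covariance when its
#'   reciprocal condition number falls below 1e-10 (default 1e-8 relative to
#'   the largest variance).
#' @return object of class `tica_model`: `lag`, `components` (features x
#'   n_components), `eigenvalues`, `mean`.
#' @export
tica_fit <- function(trajs, lag, n_components = NULL, epsilon = 1e-8) {
  trajs <- as_feature_list(trajs)
  lag <- check_count(lag, "lag")
  lens <- vapply(trajs, nrow, integer(1))
  if (any(lens <= lag)) stop("every trajectory must be longer than `lag`", call. = FALSE)
  d <- ncol(trajs[[1]])
  if (is.null(n_components)) n_components <- d
  n_components <- check_count(n_components, "n_components")
  if (n_components > d) stop("`n_components` must not exceed the feature dimension", call. = FALSE)

  # pooled mean over the frames entering the pair estimates (both ends)
  n_pairs <- sum(lens - lag)
  sx <- numeric(d)
  for (X in trajs) {
    h <- X[seq_len(nrow(X) - lag), , drop = FALSE]
    t2 <- X[seq_len(nrow(X) - lag) + lag, , drop = FALSE]
    sx <- sx + colSums(h) + colSums(t2)
  }
  m <- sx / (2 * n_pairs)

  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  for (X in trajs) {
    h <- sweep(X[seq_len(nrow(X) - lag), , drop = FALSE], 2, m)
    t2 <- sweep(X[seq_len(nrow(X) - lag) + lag, , drop = FALSE], 2, m)
    C0 <- C0 + (crossprod(h) + crossprod(t2)) / 2
    Ct <- Ct + (crossprod(h, t2) + crossprod(t2, h)) / 2
  }
  C0 <- C0 / n_pairs
  Ct <- Ct / n_pairs

  if (rcond(C0) < 1e-10) {
    C0 <- C0 + diag(epsilon * max(diag(C0)), d)
  }
  e0 <- eigen(C0, symmetric = TRUE)
  pos <- e0$values > 1e-12 * max(e0$values)
  W <- e0$vectors[, pos, drop = FALSE] %*% diag(1 / sqrt(e0$values[pos]),
                                                sum(pos))
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(abs(em$values), decreasing = TRUE)
  keep <- ord[seq_len(min(n_components, length(ord)))]
  comps <- W %*% em$vectors[, keep, drop = FALSE]
  vals <- em$values[keep]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(list(lag = lag, components = comps, eigenvalues = vals, mean = m),
            class = "tica_model")
}

#' Project frames onto TICA components
#'
#' @param model a [tica_fit()] `tica_model`.
#' @param data frames x features matrix (or vector for 1-D input).
#' @return frames x n_components matrix of projections.
#' @export
tica_project <- function(model, data) {
  stopifnot(inherits(model, "tica_model"))
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  sweep(as.matrix(data), 2, model$mean) %*% model$components
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> lag=%d frames, %d components, eigenvalues: %s\n",
              x$lag, ncol(x$components),
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}
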
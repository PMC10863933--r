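# Trajectory discretization: mini-batch k-means over feature frames.

#' Discretize frames with mini-batch k-means
#'
#' Runs mini-batch k-means (per-center counts as learning rates, as in
#' Sculley 2010) seeded from `k` distinct frames, then polishes with full
#' Lloyd iterations until assignments are stable. The polish step makes small
#' problems exact (a single cluster lands on the data mean, well-separated
#' clouds are recovered exactly) while the mini-batch phase keeps large
#' frame sets cheap. Fully deterministic under a fixed seed.
#'
#' @param data numeric matrix (frames x features) or vector (1-D features).
#' @param k number of clusters, `1 <= k <= n_frames`.
#' @param seed integer seed for initialization and batch draws.
#' @param batch_size mini-batch size (default 256).
#' @param n_batches number of mini-batch updates (default 50).
#' @param max_lloyd maximum full Lloyd polish iterations (default 10).
#' @return object of class `discretization` with fields `centers`
#'   (k x features), `k`, and `assign` (integer cluster index per frame).
#' @export
cluster_frames <- function(data, k, seed, batch_size = 256L, n_batches = 50L,
                           max_lloyd = 10L) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n <- nrow(data)
  k <- check_count(k, "k")
  if (k > n) stop("`k` must not exceed the number of frames", call. = FALSE)

  res <- with_seed(seed, {
    centers <- data[sample.int(n, k), , drop = FALSE]
    counts <- rep(1, k)
    if (k < n) {
      for (b in seq_len(n_batches)) {
        idx <- sample.int(n, min(batch_size, n))
        batch <- data[idx, , drop = FALSE]
        a <- nearest_center(batch, centers)
        for (j in unique(a)) {
          pts <- batch[a == j, , drop = FALSE]
          for (r in seq_len(nrow(pts))) {
            counts[j] <- counts[j] + 1
            eta <- 1 / counts[j]
            centers[j, ] <- (1 - eta) * centers[j, ] + eta * pts[r, ]
          }
        }
      }
    }
    # Lloyd polish: exact on small/easy problems, stabilizes assignments
    assign <- nearest_center(data, centers)
    for (it in seq_len(max_lloyd)) {
      for (j in seq_len(k)) {
        if (any(assign == j)) {
          centers[j, ] <- colMeans(data[assign == j, , drop = FALSE])
        } else {
          # re-seed an empty cluster on the farthest frame
          d <- rowSums((data - centers[assign, , drop = FALSE])^2)
          centers[j, ] <- data[which.max(d), ]
        }
      }
      new_assign <- nearest_center(data, centers)
      if (all(new_assign == assign)) break
      assign <- new_assign
    }
    list(centers = centers, assign = assign)
  })

  structure(list(centers = res$centers, k = k, assign = res$assign),
            class = "discretization")
}

#' Assign frames to their nearest cluster center
#'
#' @param data frames x features matrix (or vector for 1-D).
#' @param disc a `discretization` from [cluster_frames()], or a centers matrix.
#' @return integer vector of cluster indices.
#' @export
assign_frames <- function(data, disc) {
  centers <- if (inherits(disc, "discretization")) disc$centers else as.matrix(disc)
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  nearest_center(as.matrix(data), centers)
}

# Squared-distance nearest center, vectorized over frames.
nearest_center <- function(x, centers) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2 ; the ||x||^2 term is constant per row
  cross <- x %*% t(centers)
  cn <- rowSums(centers^2)
  max.col(2 * cross - rep(cn, each = nrow(x)), ties.method = "first")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("<discretization> k=%d over %d frames (%d features)\n",
              x$k, length(x$assign), ncol(x$centers)))
  invisible(x)
}
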
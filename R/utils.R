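# Internal helpers shared across modules.

#' Evaluate an expression under a local, seeded RNG stream
#'
#' All stochastic operations in the package take an explicit `seed` argument
#' and run through this helper, so no call mutates the caller's global RNG
#' state and identical seeds always give identical results.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of child seeds from one parent seed
#'
#' @param seed parent seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Single-value numeric argument checks used by the public constructors.
check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single numeric value", name), call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# Coerce a list of trajectories (vectors or matrices) to a list of matrices
# with a common number of feature columns.
as_feature_list <- function(trajs) {
  if (is.numeric(trajs) && is.null(dim(trajs))) trajs <- list(matrix(trajs, ncol = 1L))
  if (is.matrix(trajs)) trajs <- list(trajs)
  if (!is.list(trajs)) stop("trajectories must be a matrix or a list of matrices", call. = FALSE)
  out <- lapply(trajs, function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    storage.mode(x) <- "double"
    x
  })
  d <- unique(vapply(out, ncol, integer(1)))
  if (length(d) != 1L) stop("all trajectories must share the same number of feature columns", call. = FALSE)
  out
}
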
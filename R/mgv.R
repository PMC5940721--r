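#' Restricted cubic spline basis
#'
#' Builds the natural (restricted) cubic spline basis with `k` knots placed
#' at quantiles of `x`. The basis has `k - 1` columns: the identity term
#' `x` plus `k - 2` restricted cubic terms
#' \deqn{B_j(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3 \frac{t_k - t_j}{t_k - t_{k-1}}
#'   + (x-t_k)_+^3 \frac{t_{k-1} - t_j}{t_k - t_{k-1}}}{(t_k - t_1)^2},}
#' which are linear beyond the boundary knots (second derivative zero
#' outside `[t_1, t_k]`). The division by `(t_k - t_1)^2` puts the cubic
#' terms on roughly the scale of `x`.
#'
#' @param x numeric vector with at least `k` distinct values.
#' @param k knot count (>= 3), default 3.
#' @param quantiles knot-placement probabilities; default
#'   `seq(0.1, 0.9, length.out = k)`, i.e. the 10th/50th/90th percentiles
#'   for `k = 3`.
#' @return A list with `knots` (length `k`) and `basis`
#'   (`length(x) x (k-1)` matrix).
#' @examples
#' b <- rcsBasis(rnorm(50))
#' dim(b$basis)
#' @export
rcsBasis <- function(x, k = 3, quantiles = seq(0.1, 0.9, length.out = k)) {
  stopifnot(k >= 3, length(quantiles) == k)
  knots <- unname(quantile(x, probs = quantiles, type = 7, names = FALSE))
  if (anyDuplicated(knots)) {
    stop("duplicate knots (heavily tied values); use fewer knots")
  }
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  t1 <- knots[1L]
  cub <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1L)
  B[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    B[, j + 1L] <- (cub(x - tj) -
                      cub(x - tk1) * (tk - tj) / (tk - tk1) +
                      cub(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(B) <- c("x", if (k > 2) paste0("rcs", seq_len(k - 2L)))
  list(knots = knots, basis = B)
}

# first canonical variate of the basis side between B (n x q) and Y (n x r);
# ridge-jittered when the within-set covariance is numerically singular
.canonicalVariate <- function(B, Y, ridge = 1e-8) {
  n <- nrow(B)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sbb <- crossprod(Bc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sby <- crossprod(Bc, Yc) / (n - 1)
  jitter <- function(S) {
    if (rcond(S) < 1e-10) {
      warning("rank-deficient canonical system; adding ridge jitter")
      S <- S + diag(ridge, nrow(S))
    }
    S
  }
  Sbb <- jitter(Sbb)
  Syy <- jitter(Syy)
  M <- solve(Sbb, Sby) %*% solve(Syy, t(Sby))
  e <- eigen(M)
  a <- Re(e$vectors[, 1L])
  scores <- drop(Bc %*% a)
  r2 <- Re(e$values[1L])
  list(scores = scores, cancor = sqrt(max(min(r2, 1), 0)))
}

#' Maximum generalized variance transformation
#'
#' Iteratively re-expresses each congener so that it is maximally
#' predictable from the others: every column is represented by a restricted
#' cubic spline basis of its rank-normal scores, and Gauss-Seidel sweeps replace
#' each column by the basis-side first canonical variate against the
#' current transformed versions of the other columns, standardized to mean
#' zero and unit variance. Columns are initialized with rank-normal scores,
#' so the result depends on the raw data only through ranks and
#' quantile-based knots, and the sign of each transformed column is
#' anchored to a nonnegative Spearman correlation with its raw values.
#' Sweeps stop when the largest absolute change over all entries drops
#' below `tol` or after `maxIter` sweeps.
#'
#' @param X numeric subjects-by-congeners matrix (>= 2 columns,
#'   `nrow(X) >= k + 2`).
#' @param k spline knot count, default 3 (knots at the 10th/50th/90th
#'   percentiles).
#' @param tol convergence tolerance on the max entry change, default 1e-6.
#' @param maxIter maximum sweeps, default 50.
#' @param init optional starting matrix of transformed columns (same shape
#'   as `X`); defaults to the rank-normal scores. Supplying a previous
#'   run's converged scores restarts the sweeps at that fixed point.
#' @return A list with `scores` (transformed matrix, each column mean 0 /
#'   variance 1), `iterations`, `converged`, `maxDelta` (final largest
#'   change) and `log` (per-sweep data.frame of `iteration`, `max_delta`,
#'   `min_cancor`).
#' @examples
#' x <- rnorm(100)
#' X <- cbind(a = x, b = exp(x + rnorm(100, sd = 0.2)))
#' tr <- mgvTransform(X)
#' round(colMeans(tr$scores), 10)
#' @export
mgvTransform <- function(X, k = 3, tol = 1e-6, maxIter = 50, init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(p >= 2, n >= k + 2)
  R <- apply(X, 2L, rankNormal)
  # bases on the rank-normal scale: the transformation then depends on the
  # raw data only through ranks, so monotone re-expression of any input
  # cannot change the result
  bases <- lapply(seq_len(p), function(j) rcsBasis(R[, j], k = k)$basis)
  T <- if (is.null(init)) {
    R
  } else {
    stopifnot(identical(dim(init), dim(X)))
    apply(init, 2L, standardize)
  }
  colnames(T) <- colnames(X)
  log <- data.frame(iteration = integer(), max_delta = numeric(),
                    min_cancor = numeric())
  converged <- FALSE
  maxDelta <- Inf
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    maxDelta <- 0
    minCancor <- 1
    for (j in seq_len(p)) {
      cv <- .canonicalVariate(bases[[j]], T[, -j, drop = FALSE])
      new <- standardize(cv$scores)
      if (cor(rank(new), rank(X[, j])) < 0) new <- -new
      maxDelta <- max(maxDelta, max(abs(new - T[, j])))
      minCancor <- min(minCancor, cv$cancor)
      T[, j] <- new
    }
    log <- rbind(log, data.frame(iteration = iter, max_delta = maxDelta,
                                 min_cancor = minCancor))
    if (maxDelta < tol) {
      converged <- TRUE
      break
    }
  }
  list(scores = T, iterations = iter, converged = converged,
       maxDelta = maxDelta, log = log)
}
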
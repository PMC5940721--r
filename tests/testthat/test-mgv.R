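test_that("restricted cubic spline basis has the right shape and tail behavior", {
  set.seed(6)
  x <- rnorm(200)
  b <- rcsBasis(x, k = 3)
  expect_equal(ncol(b$basis), 2L)          # k - 1 columns
  expect_equal(b$basis[, 1], x)            # identity term first
  expect_equal(length(b$knots), 3L)
  expect_equal(b$knots, unname(quantile(x, c(0.1, 0.5, 0.9))))

  b4 <- rcsBasis(x, k = 4)
  expect_equal(ncol(b4$basis), 3L)

  # numerical second derivative of the cubic terms vanishes outside the
  # boundary knots
  for (k in c(3, 4, 5)) {
    bs <- rcsBasis(x, k = k)
    knots <- bs$knots
    evalBasis <- function(pts) {
      tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
      cub <- function(u) pmax(u, 0)^3
      sapply(seq_len(k - 2), function(j) {
        tj <- knots[j]
        (cub(pts - tj) - cub(pts - tk1) * (tk - tj) / (tk - tk1) +
           cub(pts - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
      })
    }
    h <- 1e-4
    for (pt in c(knots[1] - 0.5, knots[k] + 0.5)) {
      d2 <- (evalBasis(pt + h) - 2 * evalBasis(pt) + evalBasis(pt - h)) / h^2
      expect_true(all(abs(d2) < 1e-4))
    }
    # and is clearly nonzero between the knots
    mid <- mean(knots[c(1, k)])
    d2m <- (evalBasis(mid + h) - 2 * evalBasis(mid) + evalBasis(mid - h)) / h^2
    expect_gt(max(abs(d2m)), 1e-3)
  }
})

test_that("heavily tied values give a duplicate-knot error", {
  x <- c(rep(1, 45), 2:6)
  expect_error(rcsBasis(x, k = 3), "knots")
})

test_that("MGV output columns are standardized and the linear case is a fixed point", {
  # grid values equal to their own rank-normal scores, exactly linearly
  # related columns: one sweep must change nothing
  n <- 60
  # grid chosen to coincide with its own (Blom) rank-normal scores
  x <- qnorm((1:n - 3 / 8) / (n + 1 / 4))
  x <- (x - mean(x)) / sd(x)
  X <- cbind(a = x, b = 2 * x + 1)
  tr <- mgvTransform(X)
  expect_true(tr$converged)
  expect_equal(unname(colMeans(tr$scores)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(tr$scores, 2, var)), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(tr$scores[, "a"]), x, tolerance = 1e-6)
  expect_equal(unname(tr$scores[, "b"]), x, tolerance = 1e-6)
  expect_equal(abs(cor(tr$scores[, 1], tr$scores[, 2])), 1, tolerance = 1e-8)
})

test_that("MGV linearizes a monotone nonlinear relationship", {
  withr::with_seed(33, {
    x <- rnorm(200)
    y <- exp(x)
  })
  X <- cbind(a = x, b = y)
  raw <- cor(x, y)
  tr <- mgvTransform(X)
  expect_gt(cor(tr$scores[, 1], tr$scores[, 2]), raw)
  expect_gt(cor(tr$scores[, 1], tr$scores[, 2]), 0.99)
  # sign anchoring: transformed columns rank-correlate positively with raw
  expect_gt(cor(tr$scores[, 1], rank(x)), 0)
  expect_gt(cor(tr$scores[, 2], rank(y)), 0)
})

test_that("MGV is invariant to monotone re-expression of the inputs", {
  withr::with_seed(44, {
    z <- matrix(rnorm(300), 100, 3)
    X <- cbind(a = z[, 1], b = z[, 1] * 0.8 + z[, 2] * 0.6,
               c = z[, 1] * 0.5 + z[, 3] * 0.9)
  })
  Y <- cbind(a = exp(X[, 1]), b = X[, 2]^3, c = atan(X[, 3]))
  colnames(Y) <- colnames(X)
  t1 <- mgvTransform(X)
  t2 <- mgvTransform(Y)
  for (j in 1:3) {
    expect_equal(abs(cor(t1$scores[, j], t2$scores[, j])), 1, tolerance = 1e-6)
  }
})

test_that("re-running MGV on its converged output is a near-no-op", {
  withr::with_seed(55, {
    z <- rnorm(80)
    X <- cbind(a = z + rnorm(80, sd = 0.3), b = exp(z + rnorm(80, sd = 0.3)),
               c = rnorm(80))
  })
  t1 <- mgvTransform(X, tol = 1e-8, maxIter = 200)
  expect_true(t1$converged)
  # restarting the sweeps at the converged scores (same knots/bases) must
  # leave them essentially unchanged
  t2 <- mgvTransform(X, tol = 1e-8, maxIter = 200, init = t1$scores)
  expect_lt(max(abs(t2$scores - t1$scores)), 1e-7)
  expect_lte(t2$iterations, 2L)
})

test_that("canonical correlations stabilize as the sweeps converge", {
  withr::with_seed(66, {
    z <- rnorm(60)
    X <- cbind(a = z + rnorm(60, sd = 0.5), b = z^3 + rnorm(60, sd = 0.5),
               c = z + rnorm(60, sd = 1))
  })
  tr <- mgvTransform(X, tol = 1e-9, maxIter = 60)
  mc <- tr$log$min_cancor
  # the sequence settles into a narrow band rather than oscillating
  expect_lt(abs(mc[length(mc)] - mc[length(mc) - 1]), 1e-4)
  expect_gt(min(mc), 0.9 * max(mc))
  # and the sweep-to-sweep movement of the scores shrinks
  md <- tr$log$max_delta
  expect_lt(md[length(md)], md[1] / 100)
})
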
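test_that("fitAU recovers a noiseless two-term curve exactly", {
  l <- seq(0.5, 1.4, by = 0.1)
  # closed-form BP from alpha = -1, beta = 0.2
  rec <- bpRecord(pnorm(-1 * sqrt(l) + 0.2 / sqrt(l)), l, B = 1000)
  f <- fitAU(rec, weighting = "ols")
  expect_equal(f$alpha, -1, tolerance = 1e-8)
  expect_equal(f$beta, 0.2, tolerance = 1e-8)
  expect_equal(f$au, pnorm(1.2), tolerance = 1e-8)
  expect_true(f$fit_ok)

  # exact-fit property for random coefficient pairs (wls agrees too)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, -2, 0.5); b <- runif(1, -0.5, 1.5)
    bp <- pnorm(a * sqrt(l) + b / sqrt(l))
    ok <- bp > 1e-3 & bp < 1 - 1e-3
    if (sum(ok) < 3) next
    for (w in c("ols", "wls")) {
      f <- fitAU(bpRecord(bp[ok], l[ok], B = 1e6), weighting = w)
      expect_equal(f$alpha, a, tolerance = 1e-6)
      expect_equal(f$beta, b, tolerance = 1e-6)
      expect_equal(f$au, pnorm(-a + b), tolerance = 1e-6)
    }
  }
})

test_that("symmetric coefficients give AU = 0.5 and pinned BP is decisive", {
  l <- seq(0.5, 1.4, by = 0.1)
  c0 <- 0.7
  f <- fitAU(bpRecord(pnorm(c0 * sqrt(l) + c0 / sqrt(l)), l, B = 1e6),
             weighting = "ols")
  expect_equal(f$au, 0.5, tolerance = 1e-6)

  # BP = 1 everywhere: clipped majority-bound value, degenerate but decisive
  f1 <- fitAU(bpRecord(rep(1, 10), l, B = 1000))
  expect_gt(f1$au, 0.999)
  expect_true(f1$degenerate)
  expect_true(f1$fit_ok)
  f0 <- fitAU(bpRecord(rep(0, 10), l, B = 1000))
  expect_lt(f0$au, 0.001)
})

test_that("duplicate congener columns yield BP = 1 at every fraction", {
  set.seed(21)
  x <- rnorm(30)
  X <- cbind(A = x, Adup = x, B = rnorm(30), C = rnorm(30))
  rec <- bootstrapBP(X, B = 50, seed = 1)
  dup <- rec[rec$members %in% c("A;Adup", "Adup;A"), ]
  expect_equal(nrow(dup), 1L)
  expect_true(all(dup[, grep("^bp_", names(dup))] == 1))
  # the root is present in every resampled dendrogram by construction
  root <- rec[rec$size == 4, ]
  expect_true(all(root[, grep("^bp_", names(root))] == 1))
})

test_that("BP values fluctuate like binomial proportions across seeds", {
  es <- twoBlockSet(1, n = 41)
  X <- concMatrix(es, "maternal_blood")
  hc <- agglomerate(spearmanDissim(X))
  B <- 100
  bps <- vapply(1:12, function(s) {
    rec <- bootstrapBP(X, hc, lambdas = 1, B = B, seed = s)
    pair <- rec[rec$size == 2, ][1, ]
    as.numeric(pair[[grep("^bp_", names(pair))[1]]])
  }, 0)
  p <- mean(bps)
  expect_gt(p, 0.05)
  # observed sd within a generous factor of the binomial sd
  expect_lt(sd(bps), 4 * sqrt(p * (1 - p) / B))
})

test_that("stableClusters applies the AU threshold inclusively", {
  l <- seq(0.5, 1.4, by = 0.1)
  rec <- bpRecord(pnorm(0.2 * sqrt(l) + 1 / sqrt(l)), l, B = 1000,
                  members = c("A", "B"))
  rec <- rbind(rec, rec, rec)
  attr(rec, "lambdas") <- l
  rec$node <- 1:3
  rec$members <- c("A;B", "C;D", "A;B;C;D")
  rec$size <- c(2L, 2L, 4L)
  f <- fitAU(rec)
  f$au <- c(0.95, 0.96, 0.99)       # root has the largest size -> excluded
  f$fit_ok <- c(TRUE, FALSE, TRUE)
  out <- stableClusters(f, threshold = 0.95)
  expect_equal(out, list(c("A", "B")))   # au = 0.95 included, fit_ok=FALSE excluded

  empty <- f[0, ]
  expect_equal(stableClusters(empty), list())
})

test_that("planted blocks outrank spurious nodes in bootstrap support", {
  hits <- 0
  for (s in 1:6) {
    es <- twoBlockSet(s, n = 41)
    X <- concMatrix(es, "cord_blood")
    rec <- bootstrapBP(X, lambdas = 1, B = 200, seed = s)
    bp <- rec[[grep("^bp_", names(rec))[1]]]
    key <- vapply(strsplit(rec$members, ";"), function(v) paste(sort(v), collapse = ","), "")
    planted <- key %in% c("C1,C2,C3,C4", "C5,C6,C7,C8")
    spurious <- !planted & rec$size > 1 & rec$size < 8
    if (!any(spurious)) { hits <- hits + 1; next }
    if (min(bp[planted]) > max(bp[spurious])) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("skipping tiny resample sizes warns and drops the fraction", {
  set.seed(2)
  X <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, paste0("V", 1:4)))
  expect_warning(rec <- bootstrapBP(X, lambdas = c(0.4, 1), B = 20, seed = 1),
                 "resample size")
  expect_equal(attr(rec, "fractions"), 1)
})
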
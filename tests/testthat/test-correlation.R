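test_that("rhoWithCI handles the comonotone closed forms", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  r1 <- rhoWithCI(x, x * 2 + 1, B = 200, seed = 1)
  expect_equal(r1$rho, 1)
  expect_equal(c(r1$ci_low, r1$ci_high), c(1, 1))
  r2 <- rhoWithCI(x, -x, B = 50, seed = 1)
  expect_equal(r2$rho, -1)
  expect_error(rhoWithCI(rep(1, 10), rnorm(10), B = 10, seed = 1), "constant")
})

test_that("rho is invariant to monotone transforms and CI widens with level", {
  withr::with_seed(3, { x <- rexp(41); y <- x + rnorm(41, sd = 0.5) })
  a <- rhoWithCI(x, y, B = 500, seed = 9)
  b <- rhoWithCI(log(x), y^1, B = 500, seed = 9)
  expect_equal(a$rho, b$rho)
  expect_equal(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))

  lv <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  cis <- t(vapply(lv, function(l) {
    r <- rhoWithCI(x, y, B = 1000, level = l, seed = 9)
    c(r$ci_low, r$ci_high)
  }, c(0, 0)))
  expect_true(all(diff(cis[, 1]) <= 1e-12))    # lower bound non-increasing
  expect_true(all(diff(cis[, 2]) >= -1e-12))   # upper bound non-decreasing
  expect_true(all(cis[, 1] <= a$rho & cis[, 2] >= a$rho))
})

test_that("cross-matrix tables cover every congener and pair", {
  es <- imputeLOD(generateDataset(nSubjects = 20, seed = 6))
  tab <- crossMatrixTable(es)
  expect_equal(nrow(tab), nrow(es) * 3L)       # 3 matrix pairs per congener
  expect_setequal(unique(tab$pair),
                  c("maternal_blood:cord_blood", "maternal_blood:cord_tissue",
                    "cord_blood:cord_tissue"))

  # cord values as a scaled copy of maternal values -> rho = 1
  X <- concMatrix(es, "maternal_blood")
  es2 <- miniExposureSet(X, panel = congenerPanel(es),
                         scales = c(maternal_blood = 1, cord_blood = 3,
                                    cord_tissue = 0.5))
  tab2 <- crossMatrixTable(es2)
  expect_true(all(abs(tab2$rho - 1) < 1e-12, na.rm = TRUE))
  # NA only where a congener is constant within a matrix
  flat <- apply(X, 2, function(v) all(v == v[1]))
  expect_setequal(unique(tab2$congener_id[is.na(tab2$rho)]),
                  colnames(X)[flat])
})

test_that("independent matrices show near-zero cross-matrix correlation", {
  ids <- paste0("C", 1:4)
  mats <- c("maternal_blood", "cord_blood", "cord_tissue")
  lm <- matrix(0, 4, 3, dimnames = list(ids, mats))
  iq <- matrix(2, 4, 3, dimnames = dimnames(lm))
  dt <- matrix(0.995, 4, 3, dimnames = dimnames(lm))
  sp <- blockSpec(stats::setNames(as.list(ids), ids), 0.5, 0.1, lm, iq, dt,
                  crossMatrixLoading = 0)
  es <- generateDataset(miniPanel(ids, lod = 1e-6), 500, sp, seed = 13)
  tab <- crossMatrixTable(es)
  expect_lt(mean(abs(tab$rho)), 0.2)
})

test_that("marker-sum analysis emits the augmented cord-tissue row", {
  es <- imputeLOD(generateDataset(nSubjects = 41, seed = 4))
  markers <- list(maternal_blood = c("PCB118", "PCB126"),
                  cord_blood = c("PCB118", "PCB126"),
                  cord_tissue = c("PCB118", "PCB126"))
  pcddf <- rownames(es)[congenerPanel(es)$compound_class %in% c("PCDD", "PCDF")]
  res <- markerSumAnalysis(es, markers, pcddf,
                           extraCongeners = c("PCB156", "PCB189"),
                           B = 200, seed = 5)
  expect_equal(nrow(res$correlations), 4L)
  expect_equal(res$correlations$label,
               c("maternal_blood", "cord_blood", "cord_tissue",
                 "cord_tissue+extra"))
  expect_true(all(res$correlations$ci_low <= res$correlations$rho + 1e-12))
  expect_true(all(res$correlations$ci_high >= res$correlations$rho - 1e-12))
  expect_equal(nrow(res$scatter), 4L * 41L)

  # no extra congeners -> exactly one row per biological matrix
  res3 <- markerSumAnalysis(es, markers, pcddf, B = 100, seed = 5)
  expect_equal(nrow(res3$correlations), 3L)

  # perfectly rank-correlated single-congener group
  X <- concMatrix(es, "maternal_blood")
  one <- rhoWithCI(rowSums(X[, c("PCB118", "PCB126")]),
                   rank(rowSums(X[, c("PCB118", "PCB126")])),
                   B = 100, seed = 2)
  expect_equal(one$rho, 1)
})
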
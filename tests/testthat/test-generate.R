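test_that("default panel matches the standard 29-congener layout", {
  pan <- defaultPanel()
  expect_equal(nrow(pan), 29L)
  cls <- table(pan$compound_class)
  expect_equal(unname(cls[c("PCDD", "PCDF", "dlPCB")]), c(7L, 10L, 12L),
               ignore_attr = TRUE)
  expect_true(all(c("PCB77", "PCB118", "PCB126", "PCB189") %in% rownames(pan)))
  expect_true(all(pan$tef >= 0))
  expect_true(all(is.finite(pan$lod_maternal_blood) & pan$lod_maternal_blood > 0))
})

test_that("malformed TEF config is reported with the offending row", {
  bad <- data.frame(congener_id = c("X1", "X2"),
                    compound_class = c("PCDD", "weird"),
                    n_chlorines = c(4L, 5L), tef = c(1, 0.1))
  f <- tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE)
  expect_error(defaultPanel(tefFile = f), "X2")
})

test_that("generation is bit-reproducible given the seed", {
  a <- generateDataset(nSubjects = 15, seed = 99)
  b <- generateDataset(nSubjects = 15, seed = 99)
  c <- generateDataset(nSubjects = 15, seed = 100)
  for (m in biologicalMatrices(a)) {
    expect_identical(concMatrix(a, m), concMatrix(b, m))
    expect_identical(detectMatrix(a, m), detectMatrix(b, m))
  }
  expect_false(identical(concMatrix(a, "cord_blood"),
                         concMatrix(c, "cord_blood")))
})

test_that("marginals and rank correlations are calibrated", {
  ids <- paste0("C", 1:6)
  mats <- c("maternal_blood", "cord_blood", "cord_tissue")
  lm <- matrix(log(c(2, 5, 0.1, 1, 3, 0.5)), 6, 3, dimnames = list(ids, mats))
  iq <- matrix(2.5, 6, 3, dimnames = dimnames(lm))
  dt <- matrix(0.9, 6, 3, dimnames = dimnames(lm))
  sp <- blockSpec(list(A = ids[1:3], B = ids[4:6]), 0.8, 0.2, lm, iq, dt)
  es <- generateDataset(miniPanel(ids), 10000, sp, seed = 5)
  X <- concMatrix(es, "maternal_blood")

  # sample medians within 5% of the specified medians
  expect_true(all(abs(apply(X, 2, median) / exp(lm[, 1]) - 1) < 0.05))
  # concentration-scale Q3/Q1 near the specified dispersion ratio
  qr <- apply(X, 2, function(v) unname(quantile(v, 0.75) / quantile(v, 0.25)))
  expect_true(all(abs(qr / 2.5 - 1) < 0.1))
  # within-block Spearman near the sine-rule value for the latent rho
  sine <- function(r) (6 / pi) * asin(r / 2)
  rho <- cor(X, method = "spearman")
  within <- c(rho[1, 2], rho[1, 3], rho[2, 3], rho[4, 5], rho[4, 6], rho[5, 6])
  expect_true(all(abs(within - sine(0.8)) < 0.03))
  between <- rho[1:3, 4:6]
  expect_true(all(abs(between - sine(0.2)) < 0.05))
})

test_that("within-block rank correlation exceeds between-block at modest n", {
  es <- twoBlockSet(7, n = 500, rhoWithin = 0.9, rhoBetween = 0.1)
  rho <- cor(concMatrix(es, "cord_tissue"), method = "spearman")
  within <- mean(c(rho[1:4, 1:4][lower.tri(diag(4))],
                   rho[5:8, 5:8][lower.tri(diag(4))]))
  between <- mean(rho[1:4, 5:8])
  expect_gt(within, between)
  expect_gt(within, 0.7)
  expect_lt(between, 0.3)
})

test_that("detection targets control the detected fraction", {
  ids <- c("A", "B")
  mats <- c("maternal_blood", "cord_blood", "cord_tissue")
  lm <- matrix(0, 2, 3, dimnames = list(ids, mats))
  iq <- matrix(2, 2, 3, dimnames = dimnames(lm))
  dt <- matrix(0.5, 2, 3, dimnames = dimnames(lm))
  sp <- blockSpec(list(A = "A", B = "B"), 0.5, 0.1, lm, iq, dt)
  es <- generateDataset(miniPanel(ids), 1000, sp, seed = 11)
  frac <- colMeans(detectMatrix(es, "maternal_blood"))
  expect_true(all(frac > 0.45 & frac < 0.55))
})

test_that("degenerate detection targets yield infinite/zero LODs with a warning", {
  ids <- c("A", "B")
  mats <- c("maternal_blood", "cord_blood", "cord_tissue")
  lm <- matrix(0, 2, 3, dimnames = list(ids, mats))
  iq <- matrix(2, 2, 3, dimnames = dimnames(lm))
  dt <- matrix(c(0, 1), 2, 3, dimnames = dimnames(lm))
  sp <- blockSpec(list(A = "A", B = "B"), 0.5, 0.1, lm, iq, dt)
  w <- testthat::capture_warnings(
    es <- generateDataset(miniPanel(ids), 20, sp, seed = 2))
  expect_true(all(grepl("detect targets", w)))
  expect_length(w, 3L)   # one per biological matrix
  expect_false(any(detectMatrix(es, "cord_blood")[, "A"]))
  expect_true(all(detectMatrix(es, "cord_blood")[, "B"]))
})

test_that("block designs round-trip through YAML", {
  sp <- defaultBlockSpec()
  f <- tempfile(fileext = ".yaml")
  writeBlockSpec(sp, f)
  back <- readBlockSpec(f)
  expect_equal(back@rhoWithin, sp@rhoWithin)
  expect_equal(back@rhoBetween, sp@rhoBetween)
  expect_equal(back@crossMatrixLoading, sp@crossMatrixLoading)
  expect_equal(lapply(back@blocks, sort), lapply(sp@blocks, sort))
  expect_equal(back@logMedian, sp@logMedian, tolerance = 1e-12)
  expect_equal(back@detectTarget, sp@detectTarget, tolerance = 1e-12)
  # a dataset generated from the round-tripped spec is identical
  a <- generateDataset(defaultPanel(), 10, sp, seed = 3)
  b <- generateDataset(defaultPanel(), 10, back, seed = 3)
  expect_identical(concMatrix(a, "cord_tissue"), concMatrix(b, "cord_tissue"))
})

test_that("non-positive-definite designs are rejected with the eigenvalue", {
  ids <- paste0("C", 1:3)
  lm <- matrix(0, 3, 3, dimnames = list(ids, c("maternal_blood", "cord_blood", "cord_tissue")))
  iq <- matrix(2, 3, 3, dimnames = dimnames(lm))
  dt <- matrix(0.9, 3, 3, dimnames = dimnames(lm))
  expect_error(blockSpec(list(A = ids), 0.9, 0.95, lm, iq, dt), "rhoBetween")
})
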
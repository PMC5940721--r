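#' Spearman correlation with percentile bootstrap confidence interval
#'
#' Spearman's rank correlation (average ties) between two paired per-subject
#' vectors, with a nonparametric percentile bootstrap interval: subjects are
#' resampled in pairs with replacement, the correlation recomputed on each
#' resample, and the interval endpoints taken as order statistics (type-1
#' quantiles) of the resampled distribution.
#'
#' @param x,y paired numeric vectors of equal length (n >= 4).
#' @param B bootstrap replicates, default 10000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed.
#' @param label optional description of the pair.
#' @return A one-row data.frame: `label`, `rho`, `ci_low`, `ci_high`,
#'   `level`, `replicates`.
#' @examples
#' set.seed(1); x <- rnorm(41); y <- x + rnorm(41)
#' rhoWithCI(x, y, B = 500, seed = 1)
#' @export
rhoWithCI <- function(x, y, B = 10000, level = 0.95, seed, label = "") {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4, B >= 1, level > 0, level < 1)
  if (missing(seed)) stop("rhoWithCI requires a seed")
  if (all(x == x[1L]) || all(y == y[1L])) {
    stop("Spearman correlation undefined for a constant input")
  }
  rho <- cor(x, y, method = "spearman")
  reps <- withr::with_seed(stageSeed(seed, "correlate"), {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[i], y[i], method = "spearman"))
    }, 0)
  })
  reps <- reps[is.finite(reps)]
  a <- (1 - level) / 2
  ci <- quantile(reps, c(a, 1 - a), names = FALSE, type = 1)
  data.frame(label = label, rho = rho, ci_low = ci[1L], ci_high = ci[2L],
             level = level, replicates = B, stringsAsFactors = FALSE)
}

#' Cross-matrix correlation of individual congeners
#'
#' Spearman correlation of each congener between every pair of biological
#' matrices, over shared subjects — the per-congener view of how well one
#' specimen type proxies another.
#'
#' @param dataset an [ExposureSet-class] (imputed values are used as-is).
#' @return A data.frame with columns `congener_id`, `pair` (e.g.
#'   `"maternal_blood:cord_blood"`), `rho`.
#' @examples
#' es <- imputeLOD(generateDataset(nSubjects = 20, seed = 5))
#' head(crossMatrixTable(es))
#' @export
crossMatrixTable <- function(dataset) {
  stopifnot(is(dataset, "ExposureSet"))
  mats <- biologicalMatrices(dataset)
  stopifnot(length(mats) >= 2)
  pairs <- utils::combn(mats, 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    X1 <- concMatrix(dataset, pr[1L])
    X2 <- concMatrix(dataset, pr[2L])
    data.frame(
      congener_id = colnames(X1),
      pair = paste(pr, collapse = ":"),
      # congeners constant in a matrix (all values censored to lod/2)
      # have no defined rank correlation and are reported as NA
      rho = vapply(colnames(X1), function(j) {
        if (all(X1[, j] == X1[1, j]) || all(X2[, j] == X2[1, j])) {
          return(NA_real_)
        }
        cor(X1[, j], X2[, j], method = "spearman")
      }, 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  out
}

#' Marker-sum versus total PCDD/F correlation analysis
#'
#' For each biological matrix, correlates the per-subject marker PCB sum
#' (the representative subset, optionally augmented with configured extra
#' congeners such as PCB #77) with the per-subject total PCDD/F, using
#' [rhoWithCI()]. When `extraCongeners` is supplied, the matrix named by
#' `extraMatrix` (default cord tissue) is analysed twice: once with its
#' marker set alone and once with the extra congeners added to the sum.
#'
#' @param dataset an imputed [ExposureSet-class] in TEQ units.
#' @param markersPerMatrix named list (one entry per biological matrix) of
#'   marker congener ids.
#' @param pcddfGroup congener ids making up the total PCDD/F sum.
#' @param extraCongeners optional extra congener ids for the augmented sum.
#' @param extraMatrix biological matrix that receives the augmented
#'   analysis, default `"cord_tissue"`.
#' @param B,level,seed bootstrap configuration, see [rhoWithCI()].
#' @return A list with `correlations` (data.frame of [rhoWithCI()] rows)
#'   and `scatter` (per-subject sums: `subject_id`, `matrix`, `variant`,
#'   `sum_pcb`, `sum_pcddf`).
#' @export
markerSumAnalysis <- function(dataset, markersPerMatrix, pcddfGroup,
                              extraCongeners = NULL,
                              extraMatrix = "cord_tissue",
                              B = 10000, level = 0.95, seed) {
  stopifnot(is(dataset, "ExposureSet"))
  if (missing(seed)) stop("markerSumAnalysis requires a seed")
  mats <- biologicalMatrices(dataset)
  stopifnot(all(names(markersPerMatrix) %in% mats))
  if (!length(pcddfGroup)) stop("PCDD/F group must not be empty")
  rows <- list()
  scatter <- list()
  runOne <- function(m, markers, variant, seedShift) {
    if (!length(markers)) stop("marker set for ", m, " is empty")
    sums <- sumGroups(dataset, list(sum_pcb = markers, sum_pcddf = pcddfGroup))
    sums <- sums[sums$matrix == m, ]
    res <- rhoWithCI(sums$sum_pcb, sums$sum_pcddf, B = B, level = level,
                     seed = seed + seedShift,
                     label = if (variant == "base") m else paste0(m, "+extra"))
    scatter[[length(scatter) + 1L]] <<- data.frame(
      subject_id = sums$subject_id, matrix = m, variant = variant,
      sum_pcb = sums$sum_pcb, sum_pcddf = sums$sum_pcddf,
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <<- res
  }
  for (i in seq_along(markersPerMatrix)) {
    m <- names(markersPerMatrix)[i]
    runOne(m, markersPerMatrix[[m]], "base", i)
  }
  if (!is.null(extraCongeners) && extraMatrix %in% names(markersPerMatrix)) {
    runOne(extraMatrix,
           unique(c(markersPerMatrix[[extraMatrix]], extraCongeners)),
           "extra", length(markersPerMatrix) + 1L)
  }
  list(
    correlations = do.call(rbind, rows),
    scatter = do.call(rbind, scatter)
  )
}
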
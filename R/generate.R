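#' Default planted-block design for the synthetic generator
#'
#' Builds the [BlockSpec-class] that emulates the correlation structure seen
#' in three-matrix mother-infant congener panels: a low/medium chlorinated
#' dioxin-like PCB block (#105, #118, #123, #126), a medium/high chlorinated
#' block (#114, #156, #157, #167, #169, #189), a HxCDF pair
#' (1,2,3,4,7,8-/1,2,3,6,7,8-HxCDF), a PeCDD/PeCDF pair, and all remaining
#' congeners as singletons. Marginal medians, IQR ratios and detection
#' targets come from the bundled calibration table (41 subjects per matrix).
#'
#' Detection targets are the calibration detection fractions clamped to
#' \[0.005, 0.995\] so that derived LODs remain positive and finite even for
#' congeners detected in all or none of the calibration samples.
#'
#' @param panel congener panel, see [defaultPanel()].
#' @param rhoWithin,rhoBetween latent log-scale correlations inside and
#'   across blocks (defaults 0.9 and 0.3).
#' @param crossMatrixLoading shared-factor loading linking the same congener
#'   across biological matrices (default 0.8).
#' @param calibrationFile see [defaultPanel()].
#' @return A [BlockSpec-class].
#' @examples
#' spec <- defaultBlockSpec()
#' spec
#' @export
defaultBlockSpec <- function(panel = defaultPanel(),
                             rhoWithin = 0.9, rhoBetween = 0.3,
                             crossMatrixLoading = 0.8,
                             calibrationFile = system.file(
                               "extdata", "default_calibration.csv",
                               package = "congenerMarkers")) {
  cal <- defaultCalibration(calibrationFile)
  ids <- rownames(panel)
  planted <- list(
    pcb_low_medium  = c("PCB105", "PCB118", "PCB123", "PCB126"),
    pcb_medium_high = c("PCB114", "PCB156", "PCB157", "PCB167", "PCB169", "PCB189"),
    hxcdf_pair      = c("123478-HxCDF", "123678-HxCDF"),
    pecdd_pecdf     = c("12378-PeCDD", "23478-PeCDF")
  )
  planted <- lapply(planted, intersect, ids)
  planted <- planted[vapply(planted, length, 1L) > 1L]
  singletons <- setdiff(ids, unlist(planted))
  blocks <- c(planted, stats::setNames(as.list(singletons), singletons))

  grab <- function(col) {
    out <- sapply(.MATRICES, function(m) {
      cm <- cal[cal$matrix == m, ]
      cm[[col]][match(ids, cm$congener_id)]
    })
    rownames(out) <- ids
    out
  }
  med <- grab("median")
  q1 <- grab("q1")
  q3 <- grab("q3")
  nd <- grab("n_detect")
  nt <- grab("n_total")
  blockSpec(
    blocks = blocks, rhoWithin = rhoWithin, rhoBetween = rhoBetween,
    logMedian = log(med),
    logIQRFactor = pmax(q3 / q1, 1 + 1e-6),
    detectTarget = pmin(pmax(nd / nt, 0.005), 0.995),
    crossMatrixLoading = crossMatrixLoading
  )
}

#' Read and write block designs as YAML
#'
#' `writeBlockSpec()` serialises a [BlockSpec-class] to YAML;
#' `readBlockSpec()` loads one back. Marginal tables are stored as named
#' per-matrix maps keyed by congener id.
#'
#' @param spec a [BlockSpec-class].
#' @param path YAML file path.
#' @return `readBlockSpec()` returns a [BlockSpec-class].
#' @export
writeBlockSpec <- function(spec, path) {
  asMap <- function(M) {
    out <- lapply(colnames(M), function(m) as.list(stats::setNames(M[, m], rownames(M))))
    stats::setNames(out, colnames(M))
  }
  yaml::write_yaml(list(
    blocks = spec@blocks,
    rho_within = spec@rhoWithin,
    rho_between = spec@rhoBetween,
    cross_matrix_loading = spec@crossMatrixLoading,
    log_median = asMap(spec@logMedian),
    log_iqr_factor = asMap(spec@logIQRFactor),
    detect_target = asMap(spec@detectTarget)
  ), path, precision = 17)   # doubles survive the round-trip exactly
  invisible(path)
}

#' @rdname writeBlockSpec
#' @export
readBlockSpec <- function(path) {
  y <- yaml::read_yaml(path)
  asMat <- function(lst) {
    ids <- names(lst[[1L]])
    M <- sapply(lst, function(col) unlist(col)[ids])
    rownames(M) <- ids
    M
  }
  blockSpec(
    blocks = lapply(y$blocks, unlist),
    rhoWithin = y$rho_within, rhoBetween = y$rho_between,
    logMedian = asMat(y$log_median),
    logIQRFactor = asMat(y$log_iqr_factor),
    detectTarget = asMat(y$detect_target),
    crossMatrixLoading = y$cross_matrix_loading
  )
}

#' Generate a synthetic three-matrix congener dataset
#'
#' Draws correlated lognormal concentrations with a planted block structure.
#' Per subject, one shared latent Gaussian vector (block correlation matrix
#' from `spec`) links the biological matrices with loading
#' `crossMatrixLoading`; an independent per-matrix Gaussian of the same
#' correlation supplies the rest, so within-matrix congener correlations
#' follow the block design exactly while the same congener correlates
#' `crossMatrixLoading^2` across matrices on the latent scale. Latents are
#' scaled so that the concentration-scale Q3/Q1 ratio matches
#' `logIQRFactor`, shifted to the log-median, and exponentiated.
#'
#' The per-matrix LOD for each congener is placed at the theoretical
#' `1 - detectTarget` quantile of its lognormal marginal, so the expected
#' above-LOD fraction equals the target. Values at or below the LOD are
#' flagged `detected = FALSE` but stored at their true simulated value;
#' censoring is applied downstream by [imputeLOD()]. A target of exactly 0
#' or 1 sets the LOD to `+Inf` or `0` with a warning.
#'
#' @param panel congener metadata, see [defaultPanel()].
#' @param nSubjects number of subjects (>= 4); default 41 to match the
#'   calibration study size.
#' @param spec a [BlockSpec-class]; default [defaultBlockSpec()].
#' @param seed integer seed; the draw is bit-reproducible given
#'   `(panel, nSubjects, spec, seed)`.
#' @return An [ExposureSet-class] in TEQ units with panel LODs replaced by
#'   the derived per-matrix values.
#' @examples
#' es <- generateDataset(nSubjects = 41, seed = 7)
#' es
#' @export
generateDataset <- function(panel = defaultPanel(), nSubjects = 41,
                            spec = defaultBlockSpec(panel), seed) {
  stopifnot(nSubjects >= 4)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  validObject(spec)
  ids <- rownames(spec@logMedian)
  if (!setequal(ids, rownames(panel))) {
    stop("spec congeners must match the panel")
  }
  panel <- panel[ids, , drop = FALSE]
  S <- blockCorrelation(spec)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("block correlation matrix is not positive definite (smallest eigenvalue %.3g)", min(ev)))
  }
  L <- chol(S)
  p <- length(ids)
  a <- spec@crossMatrixLoading
  subjects <- sprintf("S%02d", seq_len(nSubjects))

  conc <- det <- list()
  withr::with_seed(stageSeed(seed, "generate"), {
    shared <- matrix(rnorm(nSubjects * p), nSubjects, p) %*% L
    for (m in .MATRICES) {
      own <- matrix(rnorm(nSubjects * p), nSubjects, p) %*% L
      z <- a * shared + sqrt(1 - a^2) * own
      sigma <- log(spec@logIQRFactor[ids, m]) / (2 * qnorm(0.75))
      mu <- spec@logMedian[ids, m]
      x <- exp(sweep(sweep(z, 2L, sigma, `*`), 2L, mu, `+`))
      dimnames(x) <- list(subjects, ids)
      target <- spec@detectTarget[ids, m]
      lod <- exp(mu + sigma * qnorm(1 - target))
      degLow <- target == 0
      degHigh <- target == 1
      if (any(degLow) || any(degHigh)) {
        warning(sprintf(
          "detect targets of 0/1 give infinite/zero LODs for: %s",
          paste(ids[degLow | degHigh], collapse = ", ")))
        lod[degLow] <- Inf
        lod[degHigh] <- 0
      }
      panel[[paste0("lod_", m)]] <- unname(lod)
      conc[[m]] <- x
      det[[m]] <- sweep(x, 2L, lod, `>`)
    }
  })
  ExposureSet(conc, det, panel, units = "teq", imputed = FALSE)
}
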
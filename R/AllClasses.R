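#' ExposureSet: a multi-matrix congener concentration container
#'
#' `ExposureSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' congener concentration panels measured in several biological matrices on
#' the same subjects. Rows are congeners, columns are subjects, and each
#' biological matrix (maternal blood, cord blood, cord tissue) is one assay.
#' A parallel logical matrix per assay records whether each value was measured
#' above the limit of detection (LOD); values below the LOD are left-censored.
#'
#' Congener metadata (compound class, chlorination degree, WHO 2005 TEF and
#' per-matrix LOD) live in `rowData`. The `units` slot records whether
#' concentrations are raw (`"raw"`, pg/g-fat) or TEF-weighted
#' (`"teq"`, pg-TEQ/g-fat).
#'
#' @slot detected [S4Vectors::SimpleList] of logical matrices, one per assay,
#'   with identical dimensions and dimnames; `TRUE` means above the LOD.
#' @slot units character, `"raw"` or `"teq"`.
#' @slot imputed logical; `TRUE` after LOD/2 substitution has been applied.
#'
#' @seealso [ExposureSet()], [generateDataset()], [imputeLOD()],
#'   [filterDetect()]
#' @export
setClass("ExposureSet",
  contains = "SummarizedExperiment",
  slots = c(detected = "SimpleList", units = "character", imputed = "logical"),
  prototype = prototype(units = "teq", imputed = FALSE)
)

setValidity("ExposureSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (length(an) < 1L) {
    msg <- c(msg, "at least one biological matrix assay is required")
  }
  if (!identical(sort(names(object@detected)), sort(an))) {
    msg <- c(msg, "detection flags must be present for every assay")
  }
  for (m in an) {
    a <- SummarizedExperiment::assay(object, m)
    d <- object@detected[[m]]
    if (!is.logical(d) || !identical(dim(d), dim(a))) {
      msg <- c(msg, sprintf("detection flags for '%s' must be a logical matrix of matching shape", m))
    }
    if (any(!is.finite(a)) || any(a < 0)) {
      msg <- c(msg, sprintf("concentrations in '%s' must be finite and nonnegative", m))
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("compound_class", "n_chlorines", "tef", paste0("lod_", an))
  miss <- setdiff(need, colnames(rd))
  if (length(miss)) {
    msg <- c(msg, paste("rowData is missing columns:", paste(miss, collapse = ", ")))
  } else {
    if (any(rd$tef < 0)) msg <- c(msg, "tef must be >= 0")
    for (m in an) {
      lod <- rd[[paste0("lod_", m)]]
      if (any(!is.finite(lod) & !is.infinite(lod)) || any(lod < 0)) {
        msg <- c(msg, sprintf("lod_%s must be nonnegative", m))
      }
    }
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "congener ids must be unique")
  if (!object@units %in% c("raw", "teq")) msg <- c(msg, "units must be 'raw' or 'teq'")
  if (length(msg)) msg else TRUE
})

#' Construct an ExposureSet
#'
#' @param concentrations named list of numeric subjects-by-congeners matrices
#'   (one per biological matrix; identical row and column names across
#'   matrices). Stored internally transposed, Bioconductor-style.
#' @param detected named list of logical matrices of the same shape as
#'   `concentrations`; `TRUE` where the value is above the LOD. If `NULL`,
#'   flags are inferred as value strictly greater than the panel LOD.
#' @param panel congener metadata with rownames = congener ids and columns
#'   `compound_class`, `n_chlorines`, `tef` and `lod_<matrix>` for every
#'   biological matrix (a `data.frame` or `DataFrame`); see [defaultPanel()].
#' @param units `"teq"` (pg-TEQ/g-fat) or `"raw"` (pg/g-fat).
#' @param imputed logical, whether LOD/2 substitution has already been applied.
#'
#' @return An [ExposureSet-class] object.
#' @examples
#' es <- generateDataset(nSubjects = 10, seed = 1)
#' es
#' @export
ExposureSet <- function(concentrations, detected = NULL, panel,
                        units = c("teq", "raw"), imputed = FALSE) {
  units <- match.arg(units)
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    stop("'concentrations' must be a named list of matrices")
  }
  panel <- S4Vectors::DataFrame(panel)
  congeners <- colnames(concentrations[[1L]])
  subjects <- rownames(concentrations[[1L]]) %||%
    sprintf("S%02d", seq_len(nrow(concentrations[[1L]])))
  bad <- setdiff(congeners, rownames(panel))
  if (length(bad)) {
    stop("congeners absent from panel: ", paste(bad, collapse = ", "))
  }
  panel <- panel[congeners, , drop = FALSE]
  assays <- lapply(concentrations, function(m) {
    m <- as.matrix(m)
    rownames(m) <- subjects
    t(m)[congeners, , drop = FALSE]
  })
  if (is.null(detected)) {
    detected <- lapply(names(assays), function(nm) {
      lod <- panel[[paste0("lod_", nm)]]
      if (is.null(lod)) stop("cannot infer detection flags: missing lod_", nm)
      sweep(assays[[nm]], 1L, lod, `>`)
    })
    names(detected) <- names(assays)
  } else {
    detected <- lapply(detected, function(m) {
      m <- as.matrix(m)
      if (is.null(dimnames(m))) dimnames(m) <- list(subjects, congeners)
      t(m)[congeners, , drop = FALSE]
    })
  }
  detected <- lapply(detected, function(m) {
    dimnames(m) <- dimnames(assays[[1L]])
    m
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = panel
  )
  new("ExposureSet", se,
    detected = S4Vectors::SimpleList(detected[names(assays)]),
    units = units, imputed = imputed
  )
}

#' BlockSpec: planted correlation-block design for the synthetic generator
#'
#' Describes the latent correlation structure, lognormal marginals and
#' intended detection fractions used by [generateDataset()]. Congeners are
#' partitioned into labelled blocks; the latent log-scale correlation is
#' `rhoWithin` inside a block and `rhoBetween` across blocks. Marginals are
#' specified per congener and biological matrix as a median and an IQR
#' dispersion ratio Q3/Q1 on the concentration scale; detection targets give
#' the intended fraction of values above the LOD.
#'
#' @slot blocks named list of character vectors, a partition of the congener
#'   ids into labelled groups.
#' @slot rhoWithin latent correlation inside a block, in `[0, 1)`.
#' @slot rhoBetween latent correlation across blocks, `< rhoWithin`.
#' @slot logMedian numeric matrix (congeners x biological matrices) of
#'   concentration-scale medians on the log scale.
#' @slot logIQRFactor numeric matrix of Q3/Q1 dispersion ratios (> 1).
#' @slot detectTarget numeric matrix of intended above-LOD fractions in
#'   `[0, 1]`.
#' @slot crossMatrixLoading loading of the shared per-subject latent factor
#'   that links the same congener across biological matrices (default 0.8,
#'   giving a cross-matrix latent correlation of 0.64).
#'
#' @seealso [blockSpec()], [defaultBlockSpec()]
#' @export
setClass("BlockSpec", slots = c(
  blocks = "list",
  rhoWithin = "numeric",
  rhoBetween = "numeric",
  logMedian = "matrix",
  logIQRFactor = "matrix",
  detectTarget = "matrix",
  crossMatrixLoading = "numeric"
))

setValidity("BlockSpec", function(object) {
  msg <- character()
  ids <- unlist(object@blocks, use.names = FALSE)
  if (anyDuplicated(ids)) msg <- c(msg, "blocks must be disjoint")
  if (!setequal(ids, rownames(object@logMedian))) {
    msg <- c(msg, "blocks must partition exactly the congeners of logMedian")
  }
  if (object@rhoWithin < 0 || object@rhoWithin >= 1) {
    msg <- c(msg, "rhoWithin must be in [0, 1)")
  }
  if (object@rhoBetween < 0 || object@rhoBetween > object@rhoWithin) {
    msg <- c(msg, "rhoBetween must be in [0, rhoWithin]")
  }
  if (any(object@detectTarget < 0 | object@detectTarget > 1)) {
    msg <- c(msg, "detectTarget must lie in [0, 1]")
  }
  if (any(object@logIQRFactor <= 1)) {
    msg <- c(msg, "logIQRFactor (Q3/Q1) must exceed 1")
  }
  if (object@crossMatrixLoading < 0 || object@crossMatrixLoading > 1) {
    msg <- c(msg, "crossMatrixLoading must be in [0, 1]")
  }
  ev <- min(eigen(blockCorrelation(object), symmetric = TRUE,
                  only.values = TRUE)$values)
  if (ev <= 0) {
    msg <- c(msg, sprintf("implied correlation matrix is not positive definite (smallest eigenvalue %.3g)", ev))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BlockSpec-class constructor.
#' @param blocks,rhoWithin,rhoBetween,logMedian,logIQRFactor,detectTarget,crossMatrixLoading
#'   see the corresponding slots.
#' @export
blockSpec <- function(blocks, rhoWithin, rhoBetween, logMedian, logIQRFactor,
                      detectTarget, crossMatrixLoading = 0.8) {
  new("BlockSpec",
    blocks = blocks, rhoWithin = rhoWithin, rhoBetween = rhoBetween,
    logMedian = as.matrix(logMedian), logIQRFactor = as.matrix(logIQRFactor),
    detectTarget = as.matrix(detectTarget),
    crossMatrixLoading = crossMatrixLoading
  )
}

# latent congener-by-congener correlation matrix implied by the block design
blockCorrelation <- function(spec) {
  ids <- rownames(spec@logMedian)
  p <- length(ids)
  S <- matrix(spec@rhoBetween, p, p, dimnames = list(ids, ids))
  for (b in spec@blocks) {
    S[b, b] <- spec@rhoWithin
  }
  diag(S) <- 1
  S
}

setMethod("show", "ExposureSet", function(object) {
  cat(sprintf(
    "ExposureSet: %d congeners x %d subjects in %d biological matrices\n",
    nrow(object), ncol(object), length(SummarizedExperiment::assayNames(object))
  ))
  cat("  matrices:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  cls <- table(SummarizedExperiment::rowData(object)$compound_class)
  cat("  classes:", paste(sprintf("%s (%d)", names(cls), cls), collapse = ", "), "\n")
  cat(sprintf(
    "  units: %s%s\n",
    if (object@units == "teq") "pg-TEQ/g-fat" else "pg/g-fat",
    if (object@imputed) ", LOD/2 imputed" else ""
  ))
})

setMethod("show", "BlockSpec", function(object) {
  cat(sprintf(
    "BlockSpec: %d congeners in %d blocks (rho within %.2f, between %.2f)\n",
    nrow(object@logMedian), length(object@blocks),
    object@rhoWithin, object@rhoBetween
  ))
  sizes <- vapply(object@blocks, length, 1L)
  big <- sizes[sizes > 1L]
  if (length(big)) {
    cat("  planted blocks:",
        paste(sprintf("%s (%d)", names(big), big), collapse = ", "), "\n")
  }
})

#' @rdname ExposureSet-class
#' @param x,i,j,drop,... subsetting arguments: `i` selects congeners,
#'   `j` subjects.
#' @export
setMethod("[", c("ExposureSet", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  det <- x@detected
  if (!missing(i)) det <- S4Vectors::SimpleList(lapply(det, function(m) m[i, , drop = FALSE]))
  if (!missing(j)) det <- S4Vectors::SimpleList(lapply(det, function(m) m[, j, drop = FALSE]))
  out@detected <- det
  out
})
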
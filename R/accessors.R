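#' Accessors for ExposureSet objects
#'
#' @param x an [ExposureSet-class].
#' @param matrix name of one biological matrix, e.g. `"maternal_blood"`.
#' @name ExposureSet-accessors
NULL

#' @describeIn ExposureSet-accessors names of the biological matrices held as
#'   assays.
#' @export
biologicalMatrices <- function(x) {
  stopifnot(is(x, "ExposureSet"))
  SummarizedExperiment::assayNames(x)
}

#' @describeIn ExposureSet-accessors subjects-by-congeners concentration
#'   matrix for one biological matrix (the orientation used by all the
#'   statistical stages).
#' @export
concMatrix <- function(x, matrix) {
  stopifnot(is(x, "ExposureSet"))
  t(SummarizedExperiment::assay(x, matrix))
}

#' @describeIn ExposureSet-accessors subjects-by-congeners logical matrix of
#'   above-LOD flags for one biological matrix.
#' @export
detectMatrix <- function(x, matrix) {
  stopifnot(is(x, "ExposureSet"))
  t(x@detected[[matrix]])
}

#' @describeIn ExposureSet-accessors the congener metadata panel
#'   (class, chlorination, TEF, per-matrix LOD) as a `DataFrame`.
#' @export
congenerPanel <- function(x) {
  stopifnot(is(x, "ExposureSet"))
  SummarizedExperiment::rowData(x)
}

#' @describeIn ExposureSet-accessors per-congener LOD vector for one
#'   biological matrix.
#' @export
lodValues <- function(x, matrix) {
  stopifnot(is(x, "ExposureSet"))
  lod <- SummarizedExperiment::rowData(x)[[paste0("lod_", matrix)]]
  names(lod) <- rownames(x)
  lod
}

#' @describeIn ExposureSet-accessors concentration units: `"teq"`
#'   (pg-TEQ/g-fat) or `"raw"` (pg/g-fat).
#' @export
concentrationUnits <- function(x) {
  stopifnot(is(x, "ExposureSet"))
  x@units
}

#' @describeIn ExposureSet-accessors whether LOD/2 substitution has been
#'   applied.
#' @export
isImputed <- function(x) {
  stopifnot(is(x, "ExposureSet"))
  x@imputed
}

#' @describeIn ExposureSet-accessors subject identifiers (shared across all
#'   biological matrices).
#' @export
subjectIDs <- function(x) {
  stopifnot(is(x, "ExposureSet"))
  colnames(x)
}
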
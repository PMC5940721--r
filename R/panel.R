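#' The default 29-congener panel
#'
#' Builds the metadata panel for the seven PCDDs, ten PCDFs and twelve
#' dioxin-like PCBs routinely reported in mother-infant biomonitoring
#' panels. Compound class, chlorination degree and WHO 2005 TEF values are
#' read from a bundled, user-editable config file (`who2005_tef.csv`); TEFs
#' belong to the WHO 2005 re-evaluation scheme, not to this package, and can
#' be overridden by pointing `tefFile` at an edited copy.
#'
#' Per-matrix LODs are placeholders derived from the bundled calibration
#' table: for each congener and biological matrix a lognormal is fitted to
#' the calibration median and IQR and the LOD is placed at the quantile that
#' reproduces the calibration detection fraction (clamped to \[0.005,
#' 0.995\] so the LOD stays positive and finite). Real studies should supply
#' assay LODs via [readPanel()].
#'
#' @param tefFile path to a CSV with columns `congener_id`,
#'   `compound_class`, `n_chlorines`, `tef`.
#' @param calibrationFile path to the marginal calibration CSV (columns
#'   `congener_id`, `matrix`, `median`, `q1`, `q3`, `n_detect`, `n_total`).
#'
#' @return A [S4Vectors::DataFrame] with rownames = congener ids and columns
#'   `compound_class`, `n_chlorines`, `tef`, `lod_maternal_blood`,
#'   `lod_cord_blood`, `lod_cord_tissue`.
#' @examples
#' pan <- defaultPanel()
#' table(pan$compound_class)
#' @export
defaultPanel <- function(
    tefFile = system.file("extdata", "who2005_tef.csv", package = "congenerMarkers"),
    calibrationFile = system.file("extdata", "default_calibration.csv", package = "congenerMarkers")) {
  tef <- utils::read.csv(tefFile, stringsAsFactors = FALSE)
  need <- c("congener_id", "compound_class", "n_chlorines", "tef")
  miss <- setdiff(need, colnames(tef))
  if (length(miss)) {
    stop("TEF config is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(tef$tef) | tef$tef < 0 | is.na(tef$n_chlorines) |
                 !tef$compound_class %in% c("PCDD", "PCDF", "dlPCB"))
  if (length(bad)) {
    stop("malformed TEF config rows (id ", paste(tef$congener_id[bad], collapse = ", "), ")")
  }
  if (anyDuplicated(tef$congener_id)) {
    stop("malformed TEF config: duplicated congener_id ",
         tef$congener_id[duplicated(tef$congener_id)][1L])
  }
  cal <- defaultCalibration(calibrationFile)
  panel <- S4Vectors::DataFrame(
    compound_class = tef$compound_class,
    n_chlorines = as.integer(tef$n_chlorines),
    tef = tef$tef,
    row.names = tef$congener_id
  )
  for (m in .MATRICES) {
    cm <- cal[cal$matrix == m, ]
    cm <- cm[match(tef$congener_id, cm$congener_id), ]
    sigma <- log(cm$q3 / cm$q1) / (2 * qnorm(0.75))
    target <- pmin(pmax(cm$n_detect / cm$n_total, 0.005), 0.995)
    panel[[paste0("lod_", m)]] <- exp(log(cm$median) + sigma * qnorm(1 - target))
  }
  panel
}

# read and sanity-check the bundled marginal calibration table
defaultCalibration <- function(
    file = system.file("extdata", "default_calibration.csv", package = "congenerMarkers")) {
  cal <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("congener_id", "matrix", "median", "q1", "q3", "n_detect", "n_total")
  miss <- setdiff(need, colnames(cal))
  if (length(miss)) {
    stop("calibration table is missing columns: ", paste(miss, collapse = ", "))
  }
  stopifnot(all(cal$q1 <= cal$median), all(cal$median <= cal$q3))
  cal
}

#' Read and write congener metadata panels
#'
#' `readPanel()` loads a panel CSV (`congener_id`, `compound_class`,
#' `n_chlorines`, `tef`, `lod_<matrix>` per biological matrix);
#' `writePanel()` writes one.
#'
#' @param path CSV file path.
#' @return `readPanel()` returns a `DataFrame` keyed by congener id.
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"congener_id" %in% colnames(df)) stop("panel CSV needs a congener_id column")
  if (anyDuplicated(df$congener_id)) stop("duplicated congener_id in panel CSV")
  out <- S4Vectors::DataFrame(df[setdiff(colnames(df), "congener_id")],
                              row.names = df$congener_id)
  out
}

#' @rdname readPanel
#' @param panel a panel `DataFrame` as returned by [defaultPanel()].
#' @export
writePanel <- function(panel, path) {
  df <- as.data.frame(panel)
  df <- cbind(congener_id = rownames(df), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
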
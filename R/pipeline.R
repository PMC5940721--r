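#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [runPipeline()]. Every stochastic stage draws from a documented
#' substream of the single master `seed`, so a config fully determines a
#' run. Settings can also be loaded from a YAML file with the same field
#' names; values in the file override the defaults.
#'
#' @param seed master integer seed (mandatory).
#' @param input either `"synthetic"` (default, uses the bundled generator)
#'   or a named list with paths `maternal_blood`, `cord_blood`,
#'   `cord_tissue` (wide concentration CSVs), optional matching
#'   `<matrix>_detected` flag CSVs, and `panel` (panel CSV).
#' @param nSubjects synthetic sample size, default 41.
#' @param detectionThreshold all-matrix detection-fraction cutoff,
#'   default 0.5.
#' @param linkage,tieRule clustering configuration.
#' @param lambdas multiscale sampling fractions.
#' @param bootstrapB replicates per sampling fraction.
#' @param auThreshold AU stability cutoff, default 0.95.
#' @param mgvKnots,mgvTol,mgvMaxIter MGV configuration.
#' @param r2Target marker-selection R-squared floor, default 0.95.
#' @param ciB,ciLevel correlation bootstrap configuration.
#' @param includeInSum congener ids always added to the marker sum
#'   (default `"PCB77"`).
#' @param extraCongeners extra congener ids for the augmented cord-tissue
#'   analysis (default the higher-chlorinated dioxin-like PCBs
#'   #114/#156/#157/#167/#169/#189).
#' @param yamlFile optional YAML file whose entries override the above.
#' @return A validated config list.
#' @export
runConfig <- function(seed,
                      input = "synthetic",
                      nSubjects = 41,
                      detectionThreshold = 0.5,
                      linkage = "average",
                      tieRule = "average",
                      lambdas = seq(0.5, 1.4, by = 0.1),
                      bootstrapB = 1000,
                      auThreshold = 0.95,
                      mgvKnots = 3,
                      mgvTol = 1e-6,
                      mgvMaxIter = 50,
                      r2Target = 0.95,
                      ciB = 10000,
                      ciLevel = 0.95,
                      includeInSum = "PCB77",
                      extraCongeners = c("PCB114", "PCB156", "PCB157",
                                         "PCB167", "PCB169", "PCB189"),
                      yamlFile = NULL) {
  cfg <- list(
    seed = seed, input = input, nSubjects = nSubjects,
    detectionThreshold = detectionThreshold, linkage = linkage,
    tieRule = tieRule, lambdas = lambdas, bootstrapB = bootstrapB,
    auThreshold = auThreshold, mgvKnots = mgvKnots, mgvTol = mgvTol,
    mgvMaxIter = mgvMaxIter, r2Target = r2Target, ciB = ciB,
    ciLevel = ciLevel, includeInSum = includeInSum,
    extraCongeners = extraCongeners
  )
  if (!is.null(yamlFile)) {
    over <- yaml::read_yaml(yamlFile)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config fields in YAML: ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("a master seed is mandatory")
  stopifnot(
    cfg$detectionThreshold >= 0, cfg$detectionThreshold <= 1,
    all(cfg$lambdas > 0), all(cfg$lambdas <= 2),
    cfg$bootstrapB >= 1, cfg$auThreshold > 0, cfg$auThreshold <= 1,
    cfg$mgvKnots >= 3, cfg$mgvTol > 0, cfg$mgvMaxIter >= 1,
    cfg$r2Target >= 0, cfg$r2Target <= 1,
    cfg$ciB >= 1, cfg$ciLevel > 0, cfg$ciLevel < 1
  )
  cfg
}

#' Read a three-matrix exposure dataset from CSV files
#'
#' Loads wide per-matrix concentration CSVs (a `subject_id` column plus one
#' column per congener), matched against a panel CSV by congener id.
#' Detection flags come from companion flag CSVs when given, otherwise they
#' are inferred as value strictly greater than the panel LOD (a value
#' exactly at the LOD counts as non-detected).
#'
#' @param paths named list/vector of concentration CSV paths (names are the
#'   biological matrices).
#' @param panelPath panel CSV path (see [writePanel()]).
#' @param detectedPaths optional named list of flag CSV paths.
#' @param units concentration units of the files, default `"teq"`.
#' @return An [ExposureSet-class].
#' @export
readExposureCSV <- function(paths, panelPath, detectedPaths = NULL,
                            units = "teq") {
  panel <- readPanel(panelPath)
  readWide <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"subject_id" %in% colnames(df)) stop(path, ": missing subject_id column")
    m <- as.matrix(df[setdiff(colnames(df), "subject_id")])
    bad <- which(!is.finite(suppressWarnings(as.numeric(m))))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      stop(path, ": non-numeric cell at row ", rc[1L], ", column ",
           colnames(m)[rc[2L]])
    }
    storage.mode(m) <- "double"
    rownames(m) <- df$subject_id
    m
  }
  conc <- lapply(paths, readWide)
  extra <- setdiff(colnames(conc[[1L]]), rownames(panel))
  if (length(extra)) {
    stop("congeners present in data but absent from panel: ",
         paste(extra, collapse = ", "))
  }
  ord <- intersect(rownames(panel), colnames(conc[[1L]]))
  conc <- lapply(conc, function(m) m[, ord, drop = FALSE])
  det <- NULL
  if (!is.null(detectedPaths)) {
    stopifnot(length(detectedPaths) == length(paths))
    det <- lapply(detectedPaths, function(p) {
      m <- readWide(p)[, ord, drop = FALSE]
      m > 0
    })
    names(det) <- names(conc)
  }
  ExposureSet(conc, det, panel, units = units)
}

#' Write an exposure dataset to CSV files
#'
#' Writes one wide concentration CSV and one 0/1 detection-flag CSV per
#' biological matrix, plus the panel CSV — the on-disk contract read back
#' by [readExposureCSV()].
#'
#' @param dataset an [ExposureSet-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default `"exposure"`.
#' @return Named list of written paths, invisibly.
#' @export
writeExposureCSV <- function(dataset, dir, prefix = "exposure") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (m in biologicalMatrices(dataset)) {
    X <- concMatrix(dataset, m)
    cf <- file.path(dir, sprintf("%s_%s.csv", prefix, m))
    utils::write.csv(
      data.frame(subject_id = rownames(X), X, check.names = FALSE),
      cf, row.names = FALSE)
    D <- detectMatrix(dataset, m)
    df <- file.path(dir, sprintf("%s_%s_detected.csv", prefix, m))
    utils::write.csv(
      data.frame(subject_id = rownames(D), D + 0L, check.names = FALSE),
      df, row.names = FALSE)
    paths[[m]] <- cf
    paths[[paste0(m, "_detected")]] <- df
  }
  pp <- file.path(dir, paste0(prefix, "_panel.csv"))
  writePanel(congenerPanel(dataset), pp)
  paths$panel <- pp
  invisible(paths)
}

#' Run the full marker-identification pipeline
#'
#' End-to-end composition of all stages: LOD/2 imputation, the all-matrix
#' detection filter, per-matrix Spearman-dissimilarity clustering with
#' multiscale-bootstrap stability, MGV transformation and PC1 marker
#' selection inside every stable cluster with more than two members
#' (two-member stable clusters are reported as-is), and the marker-sum /
#' cross-matrix correlation analyses. All module reports are written to
#' `outputDir` (`filter_report.csv`, `dissimilarity_<m>.csv`,
#' `dendrogram_<m>.nwk`, `stability_<m>.csv`,
#' `transformed_<m>_<cluster>.csv`, `markers.csv`, `correlations.csv`,
#' `cross_matrix_correlations.csv`, `scatter_data.csv`, `manifest.yaml`).
#' Runs are byte-reproducible given the config.
#'
#' The marker sum for each biological matrix pools the selected markers of
#' its stable all-PCB clusters, plus any `includeInSum` congeners; the
#' total PCDD/F sum pools the retained PCDD/F congeners.
#'
#' @param config a config list from [runConfig()].
#' @param outputDir output directory, created if needed.
#' @param dataset optional [ExposureSet-class]; when supplied it overrides
#'   `config$input`.
#' @return A list with elements `dataset`, `filter`, `clustering` (per
#'   matrix: dendrogram, stability records, stable member sets), `markers`
#'   (data.frame), `markerSets`, `correlations`, `crossMatrix` and
#'   `outputDir`, invisibly.
#' @examples
#' cfg <- runConfig(seed = 11, nSubjects = 41, bootstrapB = 20, ciB = 200)
#' res <- runPipeline(cfg, outputDir = tempfile("run"))
#' res$markers
#' @export
runPipeline <- function(config, outputDir, dataset = NULL) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(dataset)) {
    if (identical(config$input, "synthetic")) {
      panel <- defaultPanel()
      dataset <- generateDataset(panel, nSubjects = config$nSubjects,
                                 spec = defaultBlockSpec(panel),
                                 seed = config$seed)
    } else {
      inp <- config$input
      dp <- inp[paste0(.MATRICES, "_detected")]
      dp <- if (all(vapply(dp, is.null, TRUE))) NULL else dp
      dataset <- readExposureCSV(inp[.MATRICES], inp$panel,
                                 detectedPaths = dp,
                                 units = inp$units %||% "teq")
    }
  }

  dataset <- imputeLOD(dataset)
  flt <- filterDetect(dataset, threshold = config$detectionThreshold)
  dataset <- flt$dataset
  writeFilterReport(flt$report, file.path(outputDir, "filter_report.csv"))

  panel <- congenerPanel(dataset)
  clustering <- list()
  markerRows <- list()
  markerSets <- list()
  for (m in biologicalMatrices(dataset)) {
    t0 <- proc.time()[["elapsed"]]
    X <- concMatrix(dataset, m)
    cs <- clusterStability(
      X, lambdas = config$lambdas, B = config$bootstrapB,
      linkage = config$linkage, tieRule = config$tieRule,
      threshold = config$auThreshold, seed = config$seed
    )
    message(sprintf("[%s] clustering + stability: %.1f s", m,
                    proc.time()[["elapsed"]] - t0))
    writeDissimilarity(spearmanDissim(X, tieRule = config$tieRule,
                                      seed = config$seed),
                       file.path(outputDir, sprintf("dissimilarity_%s.csv", m)))
    writeAnnotatedNewick(cs$dendrogram, cs$stable,
                         file.path(outputDir, sprintf("dendrogram_%s.nwk", m)))
    utils::write.csv(cs$records,
                     file.path(outputDir, sprintf("stability_%s.csv", m)),
                     row.names = FALSE)
    clustering[[m]] <- cs

    pcbMarkers <- character()
    for (ci in seq_along(cs$stable)) {
      cl <- cs$stable[[ci]]
      label <- sprintf("cluster%02d", ci)
      allPCB <- all(panel[cl, "compound_class"] == "dlPCB")
      if (length(cl) > 2) {
        tr <- mgvTransform(X[, cl, drop = FALSE], k = config$mgvKnots,
                           tol = config$mgvTol, maxIter = config$mgvMaxIter)
        utils::write.csv(
          data.frame(subject_id = rownames(X), tr$scores, check.names = FALSE),
          file.path(outputDir, sprintf("transformed_%s_%s.csv", m, label)),
          row.names = FALSE)
        utils::write.csv(tr$log,
          file.path(outputDir, sprintf("mgv_log_%s_%s.csv", m, label)),
          row.names = FALSE)
        p1 <- pc1Score(tr$scores)
        sel <- selectMarkers(X[, cl, drop = FALSE], p1$scores,
                             r2Target = config$r2Target, k = config$mgvKnots)
        markerRows[[length(markerRows) + 1L]] <- data.frame(
          matrix = m, cluster = label, n_members = length(cl),
          members = paste(cl, collapse = ";"),
          pc1_var = p1$pc1Var, final_r2 = sel$finalR2,
          target_met = sel$targetMet,
          markers = paste(sel$markers, collapse = ";"),
          stringsAsFactors = FALSE
        )
        if (allPCB) pcbMarkers <- union(pcbMarkers, sel$markers)
      } else {
        # two-member stable clusters bypass PCA/selection, reported as-is
        markerRows[[length(markerRows) + 1L]] <- data.frame(
          matrix = m, cluster = label, n_members = length(cl),
          members = paste(cl, collapse = ";"),
          pc1_var = NA_real_, final_r2 = NA_real_, target_met = NA,
          markers = paste(cl, collapse = ";"),
          stringsAsFactors = FALSE
        )
        if (allPCB) pcbMarkers <- union(pcbMarkers, cl)
      }
    }
    markerSets[[m]] <- union(pcbMarkers,
                             intersect(config$includeInSum, rownames(dataset)))
  }

  markers <- if (length(markerRows)) {
    do.call(rbind, markerRows)
  } else {
    data.frame(matrix = character(), cluster = character(),
               n_members = integer(), members = character(),
               pc1_var = numeric(), final_r2 = numeric(),
               target_met = logical(), markers = character())
  }
  utils::write.csv(markers, file.path(outputDir, "markers.csv"),
                   row.names = FALSE)

  pcddf <- rownames(dataset)[panel$compound_class %in% c("PCDD", "PCDF")]
  corr <- NULL
  if (length(pcddf) && all(lengths(markerSets) > 0)) {
    extra <- intersect(config$extraCongeners, rownames(dataset))
    msa <- markerSumAnalysis(
      dataset, markerSets, pcddf,
      extraCongeners = if (length(extra)) extra else NULL,
      B = config$ciB, level = config$ciLevel, seed = config$seed
    )
    corr <- msa$correlations
    utils::write.csv(corr, file.path(outputDir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(msa$scatter, file.path(outputDir, "scatter_data.csv"),
                     row.names = FALSE)
  }
  cmt <- crossMatrixTable(dataset)
  utils::write.csv(cmt, file.path(outputDir, "cross_matrix_correlations.csv"),
                   row.names = FALSE)

  manifest <- config
  manifest$lambdas <- as.numeric(manifest$lambdas)
  manifest$package_version <- as.character(utils::packageVersion("congenerMarkers"))
  yaml::write_yaml(manifest, file.path(outputDir, "manifest.yaml"))

  invisible(list(
    dataset = dataset, filter = flt$report, clustering = clustering,
    markers = markers, markerSets = markerSets, correlations = corr,
    crossMatrix = cmt, outputDir = outputDir
  ))
}
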
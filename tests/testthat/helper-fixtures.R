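# fixtures built in code, shared across test files

# minimal congener panel for hand-built datasets
miniPanel <- function(ids, class = "dlPCB", tef = 1e-4, lod = 0.1) {
  pan <- S4Vectors::DataFrame(
    compound_class = rep(class, length.out = length(ids)),
    n_chlorines = rep(5L, length(ids)),
    tef = rep(tef, length.out = length(ids)),
    row.names = ids
  )
  for (m in c("maternal_blood", "cord_blood", "cord_tissue")) {
    pan[[paste0("lod_", m)]] <- rep(lod, length.out = length(ids))
  }
  pan
}

# hand-built ExposureSet from one subjects x congeners matrix replicated
# (with optional per-matrix scaling) across the three biological matrices
miniExposureSet <- function(X, detected = NULL, panel = NULL,
                            scales = c(maternal_blood = 1, cord_blood = 1,
                                       cord_tissue = 1), ...) {
  if (is.null(panel)) panel <- miniPanel(colnames(X))
  conc <- lapply(scales, function(s) X * s)
  det <- if (is.null(detected)) NULL else lapply(seq_along(scales), function(i) detected)
  if (!is.null(det)) names(det) <- names(scales)
  ExposureSet(conc, det, panel, ...)
}

# two planted 4-congener blocks, the stability-module study condition
twoBlockSet <- function(seed, n = 41, rhoWithin = 0.9, rhoBetween = 0.1,
                        p = 8, blockSizes = c(4, 4)) {
  ids <- paste0("C", seq_len(p))
  mats <- c("maternal_blood", "cord_blood", "cord_tissue")
  lm <- matrix(0, p, 3, dimnames = list(ids, mats))
  iq <- matrix(2, p, 3, dimnames = dimnames(lm))
  dt <- matrix(0.995, p, 3, dimnames = dimnames(lm))
  blocks <- split(ids, rep(seq_along(blockSizes), blockSizes))
  names(blocks) <- paste0("block", seq_along(blocks))
  sp <- blockSpec(blocks, rhoWithin, rhoBetween, lm, iq, dt)
  generateDataset(miniPanel(ids, lod = 1e-6), n, sp, seed = seed)
}

# detection-count fixture: flags set deterministically so that exactly
# n_detect of the 41 subjects are above the LOD for each congener/matrix,
# mirroring the bundled calibration counts
calibrationCountSet <- function() {
  cal <- read.csv(system.file("extdata", "default_calibration.csv",
                              package = "congenerMarkers"),
                  stringsAsFactors = FALSE)
  pan <- defaultPanel()
  ids <- rownames(pan)
  n <- 41L
  conc <- det <- list()
  for (m in c("maternal_blood", "cord_blood", "cord_tissue")) {
    cm <- cal[cal$matrix == m, ]
    cm <- cm[match(ids, cm$congener_id), ]
    X <- matrix(rep(cm$median, each = n), n, length(ids),
                dimnames = list(sprintf("S%02d", 1:n), ids))
    D <- matrix(FALSE, n, length(ids), dimnames = dimnames(X))
    for (j in seq_along(ids)) {
      if (cm$n_detect[j] > 0) D[seq_len(cm$n_detect[j]), j] <- TRUE
    }
    conc[[m]] <- X
    det[[m]] <- D
  }
  ExposureSet(conc, det, pan, units = "teq")
}

# the 20 congeners detected in >= 50% of subjects in all three matrices
# under the bundled calibration counts (hand count of the n_detect columns)
expectedRetained <- c(
  "12378-PeCDD", "123678-HxCDD", "123789-HxCDD", "1234678-HpCDD", "OCDD",
  "23478-PeCDF", "123478-HxCDF", "123678-HxCDF", "1234678-HpCDF",
  "PCB77", "PCB105", "PCB114", "PCB118", "PCB123", "PCB126",
  "PCB156", "PCB157", "PCB167", "PCB169", "PCB189"
)

# brute-force Spearman dissimilarity via explicitly sorted rank vectors
bruteSpearmanDissim <- function(X) {
  rankOf <- function(v) {
    ord <- sort(v)
    vapply(v, function(x) mean(which(ord == x)), 0)
  }
  R <- apply(X, 2, rankOf)
  p <- ncol(X)
  d <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ri <- R[, i] - mean(R[, i])
      rj <- R[, j] - mean(R[, j])
      rho <- sum(ri * rj) / sqrt(sum(ri^2) * sum(rj^2))
      d[i, j] <- 1 - abs(rho)
    }
  }
  diag(d) <- 0
  d
}

# naive O(n^3) agglomeration recomputing linkage from scratch between the
# raw member sets at every step (independent of the Lance-Williams update)
bruteAgglomerate <- function(D, linkage = "average") {
  labels <- rownames(D)
  clusters <- as.list(labels)
  merges <- list()
  linkFun <- switch(linkage,
    average = function(a, b) mean(D[a, b]),
    complete = function(a, b) max(D[a, b]),
    single = function(a, b) min(D[a, b])
  )
  while (length(clusters) > 1) {
    pairs <- list()
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        key <- paste(sort(c(paste(sort(clusters[[i]]), collapse = "|"),
                            paste(sort(clusters[[j]]), collapse = "|"))),
                     collapse = "\r")
        pairs[[length(pairs) + 1]] <- list(
          i = i, j = j, d = linkFun(clusters[[i]], clusters[[j]]), key = key)
      }
    }
    ds <- vapply(pairs, `[[`, 0, "d")
    cand <- which(ds <= min(ds) + 1e-10)
    keys <- vapply(pairs[cand], `[[`, "", "key")
    pick <- pairs[[cand[order(keys)[1]]]]
    merged <- c(clusters[[pick$i]], clusters[[pick$j]])
    merges[[length(merges) + 1]] <- list(members = sort(merged), height = pick$d)
    clusters <- c(clusters[-c(pick$i, pick$j)], list(merged))
  }
  merges
}
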
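#' Multiscale bootstrap probabilities for dendrogram nodes
#'
#' For each sampling fraction `lambda`, draws `B` resamples of
#' `round(lambda * n)` subjects with replacement, re-ranks, re-computes the
#' Spearman dissimilarity and re-clusters each resample with the same
#' clustering configuration, and records for every internal node of the
#' reference dendrogram the fraction of resampled dendrograms containing a
#' subtree with exactly the same member set — the bootstrap probability
#' (BP). Scanning `lambda` over a range around 1 is what lets [fitAU()]
#' separate the curvature bias of the ordinary bootstrap from the signed
#' distance to the cluster boundary.
#'
#' @param X numeric subjects-by-congeners matrix (the imputed TEQ values for
#'   one biological matrix).
#' @param reference `hclust` dendrogram of `X` (see [agglomerate()]); if
#'   missing it is computed from `X` with the same configuration.
#' @param lambdas sampling fractions in `(0, 2]`; default
#'   `seq(0.5, 1.4, by = 0.1)`.
#' @param B bootstrap replicates per sampling fraction (default 1000).
#' @param linkage,tieRule clustering configuration, as in [agglomerate()]
#'   and [spearmanDissim()].
#' @param seed integer seed; the whole bootstrap is deterministic given it.
#' @return A data.frame with one row per internal node: `node` (index into
#'   `nodeMembers(reference)`), `members` (semicolon-joined ids), `size`,
#'   then one `bp_<lambda>` and one `n_<lambda>` column per sampling
#'   fraction. Fractions where `round(lambda * n) < 3` are skipped with a
#'   warning.
#' @seealso [fitAU()], [stableClusters()], [clusterStability()]
#' @export
bootstrapBP <- function(X, reference = NULL,
                        lambdas = seq(0.5, 1.4, by = 0.1), B = 1000,
                        linkage = "average", tieRule = "average", seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4, all(lambdas > 0), all(lambdas <= 2), B >= 1)
  if (missing(seed)) stop("bootstrapBP requires a seed")
  if (is.null(reference)) {
    reference <- agglomerate(spearmanDissim(X, tieRule = tieRule, seed = seed),
                             linkage = linkage)
  }
  nodes <- nodeMembers(reference)
  keys <- vapply(nodes, memberKey, "")
  sizes <- round(lambdas * n)
  usable <- sizes >= 3
  if (any(!usable)) {
    warning("skipping sampling fractions with resample size < 3: ",
            paste(lambdas[!usable], collapse = ", "))
  }
  hits <- matrix(0L, length(nodes), sum(usable))
  withr::with_seed(stageSeed(seed, "bootstrap"), {
    col <- 0L
    for (li in which(usable)) {
      col <- col + 1L
      m <- sizes[li]
      for (b in seq_len(B)) {
        repeat {
          idx <- sample.int(n, m, replace = TRUE)
          Xb <- X[idx, , drop = FALSE]
          ranks <- apply(Xb, 2L, rank, ties.method = tieRule)
          # redraw the (measure-zero) resamples where a column is constant
          if (all(apply(Xb, 2L, function(v) any(v != v[1L])))) break
        }
        rho <- cor(ranks)
        d <- 1 - abs(rho)
        d[d < 0] <- 0
        diag(d) <- 0
        dimnames(d) <- list(colnames(X), colnames(X))
        hcb <- agglomerate(d, linkage = linkage)
        bkeys <- vapply(nodeMembers(hcb), memberKey, "")
        hits[, col] <- hits[, col] + as.integer(keys %in% bkeys)
      }
    }
  })
  bp <- hits / B
  out <- data.frame(
    node = seq_along(nodes),
    members = vapply(nodes, paste, "", collapse = ";"),
    size = lengths(nodes),
    stringsAsFactors = FALSE
  )
  lam <- lambdas[usable]
  for (i in seq_along(lam)) {
    out[[sprintf("bp_%g", lam[i])]] <- bp[, i]
    out[[sprintf("n_%g", lam[i])]] <- B
  }
  attr(out, "fractions") <- lam
  # the z-curve of fitAU() lives on the multiscale variance scale
  # sigma^2 = n / n' = 1 / sampling fraction
  attr(out, "lambdas") <- 1 / lam
  out
}

#' Assemble a bootstrap-probability record by hand
#'
#' Builds the one-node record structure consumed by [fitAU()] from raw
#' numbers — useful for closed-form checks and for importing BP values
#' computed elsewhere. `lambdas` here is the grid the z-curve is fitted
#' on (for records produced by [bootstrapBP()] that grid is the variance
#' scale, the inverse sampling fraction).
#'
#' @param bp bootstrap probabilities in `[0, 1]`, one per `lambda`.
#' @param lambdas fit grid, same length as `bp`.
#' @param B replicate count(s) behind each BP value.
#' @param members optional member ids for labelling.
#' @return A one-row records data.frame compatible with [fitAU()].
#' @export
bpRecord <- function(bp, lambdas, B = 1000, members = character()) {
  stopifnot(length(bp) == length(lambdas), all(bp >= 0), all(bp <= 1))
  B <- rep(B, length.out = length(bp))
  out <- data.frame(node = 1L, members = paste(members, collapse = ";"),
                    size = length(members), stringsAsFactors = FALSE)
  for (i in seq_along(lambdas)) {
    out[[sprintf("bp_%g", lambdas[i])]] <- bp[i]
    out[[sprintf("n_%g", lambdas[i])]] <- B[i]
  }
  attr(out, "lambdas") <- lambdas
  out
}

#' Fit the multiscale z-curve and compute AU p-values
#'
#' Converts the per-fraction bootstrap probabilities of each node to
#' z-values, `z = qnorm(BP)` with BP clipped to
#' `[1/(2B), 1 - 1/(2B)]`, fits the two-term curve
#' `z(lambda) = alpha * sqrt(lambda) + beta / sqrt(lambda)` (no intercept)
#' by least squares, and reports the approximately unbiased cluster support
#' `AU = pnorm(-alpha + beta)`. The default weighted fit uses the binomial
#' delta-method weights `B * dnorm(z)^2 / (BP (1 - BP))`; `"ols"` is the
#' unweighted alternative.
#'
#' Scales where BP is pinned at 0 or 1 (outside the clipping bounds) carry
#' no curve information and are excluded from the fit, the convention of
#' the multiscale-bootstrap software family. Nodes with at least two
#' interior scales are fitted normally. Nodes with fewer than three
#' interior scales cannot support the two-parameter curve with positive
#' residual degrees of freedom — an exact two-point interpolation is pure
#' binomial noise and misreports the support of near-unanimous nodes — so
#' they are marked
#' `degenerate = TRUE`, their AU is set to the clipped majority-bound
#' value (`1 - 1/(2B)` when the pinned BPs sit at 1, `1/(2B)` at 0) and
#' `alpha`/`beta` are `NA`. Such an assessment is still decisive — a
#' cluster recovered in essentially every resample at every scale is
#' unambiguously supported — so `fit_ok` stays `TRUE` unless the pinned
#' BPs sit at *both* bounds at once, which signals an unusable record.
#'
#' For records produced by [bootstrapBP()] the fit grid is the variance
#' scale `n / n'`, i.e. the inverse sampling fraction: that is the scale
#' on which the two-term curve is linear in the signed distance and
#' curvature of the cluster boundary, and the extrapolation
#' `AU = pnorm(-alpha + beta)` corrects the curvature bias of the
#' ordinary bootstrap.
#'
#' @param records data.frame from [bootstrapBP()] or [bpRecord()].
#' @param weighting `"wls"` (default) or `"ols"`.
#' @return The records with columns `alpha`, `beta`, `au` and `fit_ok`
#'   appended.
#' @export
fitAU <- function(records, weighting = c("wls", "ols")) {
  weighting <- match.arg(weighting)
  lambdas <- attr(records, "lambdas")
  if (is.null(lambdas)) stop("records must come from bootstrapBP() or bpRecord()")
  if (length(lambdas) < 2) stop("at least two scales are required")
  bpcols <- grep("^bp_", names(records))
  ncols <- grep("^n_", names(records))
  stopifnot(length(bpcols) == length(lambdas), length(ncols) == length(lambdas))
  u <- sqrt(lambdas)
  Xd <- cbind(sqrt_lambda = u, inv_sqrt_lambda = 1 / u)
  alpha <- beta <- au <- rep(NA_real_, nrow(records))
  fit_ok <- degenerate <- logical(nrow(records))
  for (r in seq_len(nrow(records))) {
    bp <- as.numeric(records[r, bpcols])
    Bv <- as.numeric(records[r, ncols])
    lo <- 1 / (2 * Bv)
    hi <- 1 - lo
    clipped <- pmin(pmax(bp, lo), hi)
    interior <- clipped > lo & clipped < hi
    if (sum(interior) < 3) {
      # too few interior scales for the two-term curve: decisive majority
      # vote at the clipped bound, usable unless both bounds are present
      atHi <- clipped[!interior] >= hi[!interior]
      au[r] <- if (mean(bp) >= 0.5) hi[1L] else lo[1L]
      degenerate[r] <- TRUE
      fit_ok[r] <- all(atHi) || all(!atHi)
      next
    }
    z <- qnorm(clipped[interior])
    w <- if (weighting == "wls") {
      (Bv * dnorm(qnorm(clipped))^2 / (clipped * (1 - clipped)))[interior]
    } else {
      rep(1, sum(interior))
    }
    fit <- stats::lm.wfit(Xd[interior, , drop = FALSE], z, w)
    alpha[r] <- fit$coefficients[1L]
    beta[r] <- fit$coefficients[2L]
    au[r] <- pnorm(-alpha[r] + beta[r])
    fit_ok[r] <- TRUE
  }
  records$alpha <- alpha
  records$beta <- beta
  records$au <- au
  records$fit_ok <- fit_ok
  records$degenerate <- degenerate
  records
}

#' Stable clusters at a given AU threshold
#'
#' Returns the member sets of the internal dendrogram nodes whose fitted AU
#' support reaches the threshold (`>=`, default 0.95) with a valid fit.
#' The root (all congeners) is excluded; single congeners are not nodes.
#'
#' @param records fitted records from [fitAU()].
#' @param threshold AU cutoff, default 0.95.
#' @return A list of character vectors (member sets), ordered by decreasing
#'   AU.
#' @export
stableClusters <- function(records, threshold = 0.95) {
  if (is.null(records$au)) stop("records must be fitted with fitAU()")
  if (nrow(records) == 0L) return(list())
  isRoot <- records$size == max(records$size)
  keep <- records$fit_ok & !is.na(records$au) &
    records$au >= threshold & !isRoot
  kept <- records[keep, , drop = FALSE]
  kept <- kept[order(-kept$au), , drop = FALSE]
  lapply(strsplit(kept$members, ";", fixed = TRUE), identity)
}

#' One-call cluster stability assessment
#'
#' Convenience wrapper: clusters `X`, runs the multiscale bootstrap, fits
#' AU values and flags stable nodes.
#'
#' @inheritParams bootstrapBP
#' @param threshold AU threshold for stability (default 0.95).
#' @param weighting passed to [fitAU()].
#' @return A list with `dendrogram` (`hclust`), `records` (fitted
#'   data.frame, with a `stable` column) and `stable` (list of member
#'   sets).
#' @examples
#' es <- imputeLOD(generateDataset(nSubjects = 41, seed = 3))
#' X <- concMatrix(es, "maternal_blood")[, c("PCB105", "PCB118", "PCB123",
#'                                           "PCB126", "OCDD", "2378-TeCDF")]
#' cs <- clusterStability(X, B = 50, seed = 3)
#' cs$stable
#' @export
clusterStability <- function(X, lambdas = seq(0.5, 1.4, by = 0.1), B = 1000,
                             linkage = "average", tieRule = "average",
                             threshold = 0.95, weighting = "wls", seed) {
  if (missing(seed)) stop("clusterStability requires a seed")
  hc <- agglomerate(spearmanDissim(X, tieRule = tieRule, seed = seed),
                    linkage = linkage)
  rec <- bootstrapBP(X, hc, lambdas = lambdas, B = B, linkage = linkage,
                     tieRule = tieRule, seed = seed)
  rec <- fitAU(rec, weighting = weighting)
  rec$stable <- rec$fit_ok & !is.na(rec$au) & rec$au >= threshold &
    rec$size < max(rec$size)
  list(dendrogram = hc, records = rec,
       stable = stableClusters(rec, threshold = threshold))
}
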
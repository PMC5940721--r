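#' First principal component of a cluster
#'
#' Represents a stable cluster by the first principal component of its
#' (MGV-transformed, standardized) congener scores: eigen-decomposition of
#' the correlation matrix, projection of the columns on the leading
#' eigenvector, sign fixed so the loading sum is positive. Restricted to
#' clusters with more than two members — a two-member "component" is just a
#' rescaled average and is reported as-is upstream.
#'
#' @param T numeric subjects-by-members matrix of standardized scores
#'   (> 2 columns).
#' @return A list with `scores` (per-subject PC1 values), `pc1Var`
#'   (fraction of total variance carried by PC1, the cluster's
#'   \eqn{R^2_{PC1}}) and `loadings`.
#' @examples
#' es <- imputeLOD(generateDataset(nSubjects = 41, seed = 2))
#' X <- concMatrix(es, "cord_blood")[, c("PCB105", "PCB118", "PCB123", "PCB126")]
#' p1 <- pc1Score(mgvTransform(X)$scores)
#' p1$pc1Var
#' @export
pc1Score <- function(T) {
  T <- as.matrix(T)
  p <- ncol(T)
  if (p < 3) {
    stop("principal component summaries are restricted to clusters with more than two members")
  }
  C <- cor(T)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  Ts <- scale(T)
  list(
    scores = drop(Ts %*% v),
    pc1Var = e$values[1L] / p,
    loadings = stats::setNames(v, colnames(T))
  )
}

# R^2 of an OLS fit of y on the concatenated spline bases of cols
.splineR2 <- function(y, bases, cols) {
  Xd <- cbind(1, do.call(cbind, bases[cols]))
  fit <- stats::lm.fit(Xd, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Marker subset selection by backward deletion
#'
#' Finds the smallest-practicable subset of a cluster's congeners whose
#' restricted cubic spline regression still explains the cluster's first
#' principal component almost completely. The full model regresses the PC1
#' scores on the concatenated 3-knot spline bases (knots at each congener's
#' own 10th/50th/90th percentiles on the original imputed TEQ scale; two
#' terms per congener) of every member. Backward deletion then repeatedly
#' removes the congener whose removal leaves the largest refitted
#' \eqn{R^2}, stopping before a deletion would push \eqn{R^2} below
#' `r2Target`. Deletion ties are broken by current member order.
#'
#' @param Xraw numeric subjects-by-members matrix on the original
#'   (imputed TEQ) scale.
#' @param scores per-subject PC1 scores from [pc1Score()].
#' @param r2Target \eqn{R^2} floor, default 0.95.
#' @param k,quantiles spline configuration, see [rcsBasis()].
#' @return A list with `cluster` (all member ids), `markers` (retained
#'   ids), `finalR2`, `fullR2`, `r2Path` (data.frame: `deleted`,
#'   `r2_after`) and `targetMet` (`FALSE` when even the full model misses
#'   the target, in which case all members are kept).
#' @examples
#' es <- imputeLOD(generateDataset(nSubjects = 41, seed = 2))
#' X <- concMatrix(es, "cord_blood")[, c("PCB105", "PCB118", "PCB123", "PCB126")]
#' tr <- mgvTransform(X)
#' sel <- selectMarkers(X, pc1Score(tr$scores)$scores)
#' sel$markers
#' @export
selectMarkers <- function(Xraw, scores, r2Target = 0.95, k = 3,
                          quantiles = seq(0.1, 0.9, length.out = k)) {
  Xraw <- as.matrix(Xraw)
  stopifnot(ncol(Xraw) >= 2, length(scores) == nrow(Xraw))
  ids <- colnames(Xraw) %||% paste0("V", seq_len(ncol(Xraw)))
  colnames(Xraw) <- ids
  bases <- lapply(ids, function(j) rcsBasis(Xraw[, j], k = k, quantiles = quantiles)$basis)
  names(bases) <- ids
  fullR2 <- .splineR2(scores, bases, ids)
  path <- data.frame(deleted = character(), r2_after = numeric(),
                     stringsAsFactors = FALSE)
  if (fullR2 < r2Target) {
    return(list(cluster = ids, markers = ids, finalR2 = fullR2,
                fullR2 = fullR2, r2Path = path, targetMet = FALSE))
  }
  members <- ids
  current <- fullR2
  while (length(members) > 1L) {
    r2s <- vapply(seq_along(members), function(i) {
      .splineR2(scores, bases, members[-i])
    }, 0)
    best <- which.max(r2s)
    if (r2s[best] < r2Target) break
    path <- rbind(path, data.frame(deleted = members[best],
                                   r2_after = r2s[best],
                                   stringsAsFactors = FALSE))
    current <- r2s[best]
    members <- members[-best]
  }
  list(cluster = ids, markers = members, finalR2 = current, fullR2 = fullR2,
       r2Path = path, targetMet = TRUE)
}
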
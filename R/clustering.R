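#' Spearman dissimilarity between congeners
#'
#' Computes the dissimilarity `d = 1 - |rho|` between every pair of
#' congeners, where `rho` is Spearman's rank correlation over subjects. The
#' absolute value makes strongly anti-correlated congeners as "close" as
#' strongly correlated ones; only the strength of the monotone association
#' matters. Ranks are computed per congener; ties are resolved by midranks
#' (`tie_rule = "average"`, deterministic) or split uniformly at random
#' (`tie_rule = "random"`, seeded), the latter matching the convention of
#' splitting LOD/2-tied values randomly.
#'
#' @param X numeric subjects-by-congeners matrix (>= 3 subjects, >= 2
#'   congeners).
#' @param tieRule `"average"` or `"random"`.
#' @param seed integer seed, required when `tieRule = "random"`.
#' @return A symmetric congeners-by-congeners matrix with zero diagonal and
#'   entries in `[0, 1]`.
#' @examples
#' X <- concMatrix(imputeLOD(generateDataset(nSubjects = 20, seed = 1)),
#'                 "maternal_blood")
#' D <- spearmanDissim(X)
#' range(D)
#' @export
spearmanDissim <- function(X, tieRule = c("average", "random"), seed = NULL) {
  tieRule <- match.arg(tieRule)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3, ncol(X) >= 2)
  ranks <- if (tieRule == "average") {
    apply(X, 2L, rank, ties.method = "average")
  } else {
    if (is.null(seed)) stop("random tie splitting requires a seed")
    withr::with_seed(stageSeed(seed, "tie"),
                     apply(X, 2L, rank, ties.method = "random"))
  }
  sds <- apply(ranks, 2L, sd)
  if (any(sds == 0)) {
    stop("Spearman correlation undefined for constant congener(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  rho <- cor(ranks)
  d <- 1 - abs(rho)
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(colnames(X), colnames(X))
  d
}

#' Agglomerative clustering of congeners
#'
#' Standard agglomerative hierarchical clustering on a congener
#' dissimilarity matrix. The default average linkage follows the convention
#' of the multiscale-bootstrap cluster-stability literature. Ties in the
#' merge criterion are broken deterministically: among equally close pairs,
#' the lexicographically smallest pair of member sets merges first, so the
#' dendrogram is fully reproducible.
#'
#' @param D symmetric dissimilarity matrix with dimnames (see
#'   [spearmanDissim()]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `hclust` (merge, height, order, labels), as
#'   produced by [stats::hclust()], usable with `plot()`,
#'   [stats::as.dendrogram()] and [ape::as.phylo()].
#' @examples
#' X <- concMatrix(imputeLOD(generateDataset(nSubjects = 20, seed = 1)),
#'                 "cord_blood")
#' hc <- agglomerate(spearmanDissim(X))
#' @export
agglomerate <- function(D, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D) %||% as.character(seq_len(n))
  stopifnot(n >= 2, isTRUE(all.equal(D, t(D), tolerance = 1e-12)))

  # active cluster bookkeeping: id < 0 => singleton -i, id > 0 => merge row
  work <- D
  diag(work) <- Inf
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  keys <- labels                 # lexicographic member-set key per cluster
  members <- as.list(labels)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- min(work)
    # rank-correlation distances tie exactly in math but can differ in the
    # last ulp after linkage updates; group near-equal minima before the
    # deterministic tie-break
    cand <- which(work <= m + 1e-10, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      # deterministic tie-break: lexicographically smallest member-set pair
      pairKey <- apply(cand, 1L, function(ij) {
        ks <- sort(c(keys[ij[1L]], keys[ij[2L]]))
        paste(ks, collapse = "\r")
      })
      cand <- cand[order(pairKey)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- m
    other <- setdiff(which(!is.na(ids)), c(i, j))
    newd <- switch(linkage,
      average  = (sizes[i] * work[i, other] + sizes[j] * work[j, other]) /
                 (sizes[i] + sizes[j]),
      complete = pmax(work[i, other], work[j, other]),
      single   = pmin(work[i, other], work[j, other])
    )
    work[i, other] <- newd
    work[other, i] <- newd
    work[i, j] <- work[j, i] <- Inf
    work[j, ] <- Inf
    work[, j] <- Inf
    ids[i] <- step
    ids[j] <- NA_integer_
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    keys[i] <- memberKey(members[[i]])
  }

  structure(
    list(
      merge = merge, height = height, order = .dendroOrder(merge, n),
      labels = labels, method = linkage,
      call = match.call(), dist.method = "1 - |spearman rho|"
    ),
    class = "hclust"
  )
}

# leaf ordering by left-to-right traversal of the merge tree
.dendroOrder <- function(merge, n) {
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(n - 1L)
}

#' Member sets of dendrogram nodes
#'
#' Lists, for each internal node of a dendrogram, the congener ids in its
#' subtree. Node `k` corresponds to row `k` of `hc$merge`; the last node is
#' the root.
#'
#' @param hc an `hclust` object.
#' @return A list of character vectors, one per internal node, in merge
#'   order.
#' @export
nodeMembers <- function(hc) {
  n <- length(hc$labels)
  out <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    grab <- function(id) if (id < 0L) hc$labels[-id] else out[[id]]
    out[[k]] <- c(grab(hc$merge[k, 1L]), grab(hc$merge[k, 2L]))
  }
  out
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights (via [ape::as.phylo()]),
#' preserving the raw dissimilarity scale without rescaling.
#'
#' @param hc an `hclust` object.
#' @param path output file path (`.nwk`).
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a dendrogram in Newick format with stable subtrees annotated
#'
#' Like [writeNewick()], but labels every internal node whose member set
#' is one of `stableSets` with `stable` (others get an empty label), so
#' stability survives the export.
#'
#' @param hc an `hclust` object.
#' @param stableSets list of character vectors (member sets), e.g. from
#'   [stableClusters()].
#' @param path output file path.
#' @export
writeAnnotatedNewick <- function(hc, stableSets, path) {
  phy <- ape::as.phylo(hc)
  parts <- ape::prop.part(phy)
  keys <- vapply(parts, function(idx) memberKey(attr(parts, "labels")[idx]), "")
  stableKeys <- vapply(stableSets, memberKey, "")
  phy$node.label <- ifelse(keys %in% stableKeys, "stable", "")
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a dissimilarity matrix as square CSV
#'
#' @param D symmetric dissimilarity matrix.
#' @param path output CSV path.
#' @export
writeDissimilarity <- function(D, path) {
  utils::write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}
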
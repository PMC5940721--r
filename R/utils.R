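#' @importFrom stats qnorm pnorm dnorm cor quantile rnorm sd var
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame SimpleList
NULL

# canonical biological matrix names, in fixed order
.MATRICES <- c("maternal_blood", "cord_blood", "cord_tissue")

# deterministic per-stage seed substreams derived from one master seed;
# kept below 2^31 - 1 so they are valid R integer seeds
.STAGE_OFFSETS <- c(
  generate   = 101L,
  tie        = 211L,
  bootstrap  = 307L,
  mgv        = 401L,
  correlate  = 503L
)

stageSeed <- function(seed, stage) {
  off <- .STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Blom-type rank-normal scores, standardized to mean 0 / unit sd
rankNormal <- function(x) {
  n <- length(x)
  z <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  (z - mean(z)) / sd(z)
}

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant column")
  }
  (x - mean(x)) / s
}

# canonical string key for a member set (used to match clusters across
# bootstrap replicates by exact member-set identity)
memberKey <- function(members) paste(sort(members), collapse = "|")

`%||%` <- function(a, b) if (is.null(a)) b else a
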
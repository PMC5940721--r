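---
title: "Identifying fetal exposure marker congeners: methods and design notes"
author: "congenerMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fetal exposure marker congeners: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congenerMarkers)
```

## The problem

Dioxins (PCDD/Fs) and dioxin-like PCBs are persistent, lipophilic
contaminants that cross the placenta and accumulate in fetal tissue.
Biomonitoring panels measure dozens of congeners — here seven PCDDs, ten
PCDFs and twelve dioxin-like PCBs — in maternal blood, umbilical cord
blood and umbilical cord tissue, typically on small cohorts (tens of
mother–infant pairs). Because congeners within a chlorination class
co-vary strongly, a small *marker subset* can stand in for the whole
mixture, reducing assay cost in follow-up studies. This package
implements a complete, reproducible workflow for finding such markers and
quantifying how well marker sums proxy total PCDD/F exposure.

All concentrations are handled as TEQs (toxic equivalents): the raw
concentration times the congener's WHO 2005 TEF, so group sums are
toxicologically meaningful. TEF values ship as an editable config file
(`inst/extdata/who2005_tef.csv`); they belong to the WHO re-evaluation,
not to this package.

## Pipeline overview

1. **Left-censoring.** Values below the assay's limit of detection (LOD)
   are substituted at LOD/2 (`imputeLOD()`), the standard simple
   treatment for left-censored biomonitoring data. No model-based
   censored imputation is offered — the workflow is rank-based downstream,
   and LOD/2 ties are the accepted cost.
2. **Detection filter.** A congener is retained only if at least 50% of
   subjects are above the LOD in *every* biological matrix
   (`filterDetect()`, comparison `>=`). Under the bundled calibration
   counts (41 subjects), 20 of 29 congeners survive: 9 PCDD/Fs and 11
   dioxin-like PCBs.
3. **Clustering.** Within each matrix, congeners are clustered on the
   dissimilarity `d = 1 - |rho|`, `rho` being Spearman's rank
   correlation over subjects (`spearmanDissim()`), with average-linkage
   agglomeration (`agglomerate()`).
4. **Stability.** Each dendrogram node's support is assessed by
   multiscale bootstrap (`bootstrapBP()`, `fitAU()`): nodes with an
   approximately unbiased (AU) p-value of at least 0.95 are *stable*.
5. **Within-cluster summary.** Each stable cluster with more than two
   members is transformed by the maximum generalized variance (MGV)
   method (`mgvTransform()`) and summarised by its first principal
   component (`pc1Score()`).
6. **Marker selection.** The PC1 score is regressed on restricted cubic
   spline bases of each member's (imputed TEQ) concentrations; backward
   deletion removes congeners while the model R² stays at or above 0.95
   (`selectMarkers()`). The congeners remaining are the cluster's
   markers.
7. **Marker sums.** Per matrix, the marker-PCB sum (optionally augmented
   with configured congeners such as PCB #77) is correlated with the
   total PCDD/F using Spearman's rho and a 10,000-replicate percentile
   bootstrap CI (`rhoWithCI()`, `markerSumAnalysis()`); individual
   congeners are also correlated across matrices
   (`crossMatrixTable()`).

`runPipeline()` composes all stages, writes every module report
(dissimilarity CSVs, Newick dendrograms, stability tables, marker and
correlation tables, a YAML manifest) and is byte-reproducible from the
single master seed in its config.

## Cluster stability: the multiscale bootstrap in detail

For sampling fractions `r` between 0.5 and 1.4 (step 0.1), `B = 1000`
resamples of `round(r * n)` subjects are drawn with replacement;
each resample is re-ranked, re-dissimilarized and re-clustered with the
identical configuration. The bootstrap probability BP of a node at one
fraction is the share of resampled dendrograms containing *exactly* its
member set.

The AU computation converts BP to z-values, `z = qnorm(BP)`, and fits

\[ z(\lambda) = \alpha\sqrt{\lambda} + \beta/\sqrt{\lambda}, \qquad
   \mathrm{AU} = \Phi(-\alpha + \beta), \]

where `lambda` is the **variance scale** of the resample, `n / n'`,
i.e. the *inverse* of the sampling fraction. On that scale the two
coefficients estimate the curvature of the cluster-hypothesis boundary
and the signed distance to it, and the AU value extrapolates the
boundary-crossing probability to infinite sample size, correcting the
well-known conservative bias of the ordinary bootstrap probability. The
orientation matters: fitted on the sampling fraction itself, the two
terms swap roles and strongly supported clusters would be *penalised*.
`fitAU()` is agnostic — it fits whatever grid accompanies its input —
and records produced by `bootstrapBP()` carry the inverse-fraction grid.

Numerical choices, all visible in the stability report:

* BP values are clipped to `[1/(2B), 1 - 1/(2B)]` before `qnorm`.
* Fractions whose BP is pinned at 0 or 1 carry no curve information and
  are excluded from the fit.
* The curve is only trusted when at least **three** interior fractions
  remain (positive residual degrees of freedom). A two-point fit is an
  exact interpolation of binomial noise and can report AU near 0.8 for a
  node supported in more than 99.8% of all resamples at every scale.
  With fewer than three interior fractions the node is `degenerate`:
  its AU is the clipped majority-bound value (so a node at BP = 1
  everywhere gets AU = 1 - 1/(2B), decisively stable), and it is marked
  unusable (`fit_ok = FALSE`) only if its pinned BPs sit at both bounds
  at once.
* The default fit is weighted least squares with binomial delta-method
  weights `B * dnorm(z)^2 / (BP (1 - BP))`; `"ols"` is available.
* Dendrogram ties (equal merge criteria) break deterministically toward
  the lexicographically smallest member-set pair, so reference and
  resample dendrograms are reproducible.

The resampling, like the rest of the pipeline, treats tied
concentrations (mostly LOD/2 substitutes and resampled duplicate
subjects) with midranks by default; seeded random tie-splitting
(`tieRule = "random"`) is available, and marker conclusions should be
checked across tie seeds when many values sit at the LOD.

## The MGV transformation

The MGV step re-expresses each congener so the congeners are maximally
mutually predictable before the PCA summary — without it, a congener
related to its cluster on a different scale (e.g. exponentially) would
leak variance out of PC1. Each column is represented by a restricted
cubic spline basis with `k = 3` knots (`k - 1 = 2` terms: the identity
plus one restricted cubic term, linear beyond the boundary knots);
Gauss–Seidel sweeps replace each column with the basis-side first
canonical variate against the current versions of the other columns,
standardized to mean 0 / variance 1, until the largest entry change
falls below `tol = 1e-6` (at most 50 sweeps).

Design choices:

* **Rank-normal initialization and rank-normal bases.** Columns start at
  their Blom rank-normal scores, and the spline bases are built on those
  scores with knots at their 10th/50th/90th percentiles. The transform
  therefore depends on the raw data only through ranks, and is invariant
  to monotone re-expression of any input — the natural behaviour for a
  step feeding a rank-based pipeline. (Spline bases on the raw scale are
  *not* rank-invariant: cubic polynomials in `x` and in `exp(x)` span
  different spaces even with quantile knots.)
* **Sign anchoring.** Canonical variates are sign-indeterminate; each
  transformed column is flipped, if needed, to correlate positively (in
  ranks) with its raw congener.
* **Sequential sweeps in fixed column order**, for exact
  reproducibility; a rank-deficient canonical system gets a `1e-8` ridge
  with a warning.
* The sweep-minimum canonical correlation is logged per iteration; it
  converges but is not exactly monotone (each column's step is optimal
  given the others, and the others move between its updates).

Whether the transformation is applied jointly to all congeners or
within each cluster is genuinely open; the pipeline transforms **within
each stable cluster**, which matches the cluster-wise PCA it feeds and
keeps clusters independent of one another. `mgvTransform()` can equally
be called on any column set for a joint analysis.

## Marker selection

The PC1 score of a stable cluster (loading sum fixed positive, share of
variance reported as R²_PC1) is regressed on the pooled spline bases of
all members — here on the **original imputed TEQ scale** with knots at
each congener's own 10th/50th/90th percentiles, since the published rule
for this regression stage is explicit about the percentile knots.
Backward deletion removes, at each step, the congener whose removal
leaves the largest refitted R², and stops before R² would drop below the
target (0.95 by default, treated as a hard floor; deletion ties break
toward the earlier column). Whole congeners (both spline terms) are
removed at once, matching the congener-level marker reporting the
procedure exists for. Greedy deletion can in principle miss the optimal
subset; the test suite compares it with exhaustive subset search on
planted two-driver clusters and requires at least 80% agreement, with
disagreements printed, not hidden.

Two-member stable clusters bypass the PCA/selection stage and are
reported as-is: a first principal component of two standardized columns
is just their rescaled average, and deleting one of two members is not a
meaningful reduction.

## The synthetic generator

`generateDataset()` emulates the structure of a three-matrix
mother–infant congener study so that every downstream stage is testable
without access to any cohort data:

* **Lognormal marginals** per congener and matrix, calibrated by a
  median and a Q3/Q1 dispersion ratio (the bundled defaults reproduce
  the medians, IQRs and detection counts of a 41-subject, 29-congener
  panel; placeholder values fill the handful of never-detected rows).
* **Planted correlation blocks** on the latent log scale: by default a
  low/medium chlorinated PCB block (#105/#118/#123/#126), a medium/high
  chlorinated block (#114/#156/#157/#167/#169/#189), an HxCDF pair and a
  PeCDD/PeCDF pair, with `rhoWithin = 0.9` inside blocks and
  `rhoBetween = 0.3` across (singletons elsewhere). These are the
  co-variation patterns such panels show; `rhoBetween = 0.3` yields
  moderate positive PCB-versus-PCDD/F marker-sum correlations.
* **Cross-matrix coupling** by one shared per-subject latent vector with
  loading 0.8 per matrix (latent cross-matrix correlation 0.64),
  emulating the high observed cross-matrix congener correlations. No
  pharmacokinetic or placental-transfer mechanism is modelled — the
  generator imitates correlation structure only.
* **LOD placement at a quantile**: the per-matrix LOD is the theoretical
  `1 - detectTarget` quantile of each congener's lognormal marginal, so
  detection fractions are dialled exactly; censored values are stored at
  their simulated truth and only flagged, with censoring applied by
  `imputeLOD()`. Default targets are the calibration detection counts
  clamped to `[0.005, 0.995]` so LODs stay positive and finite.

What passing tests on this generator do **not** show: robustness to
missing whole specimens (subjects are complete by construction), to
non-lognormal heavy tails, to assay batch effects, or to correlation
structure that is not block-exchangeable. Conclusions about real cohorts
still require the real measurements.

## Problem sizes and budgets used by the test suite

The suite exercises the study scale directly: planted-block stability
runs 20 seeds at `n = 41`, `B = 1000`, ten sampling fractions; CI
coverage uses 500 simulations with `B = 2000`; brute-force clustering
oracles run 100 random instances at 5–6 congeners; the end-to-end
determinism check runs the full synthetic pipeline twice at reduced
bootstrap depth (`B = 30`, CI `B = 200`), which exercises every code
path while keeping the default `R CMD check` wall time modest. The
`scripts/acceptance.R` entry point runs the complete pipeline at full
depth (`B = 1000`, CI `B = 10000`).

## Known limitations

* AU p-values are reported without standard errors or curvature
  diagnostics beyond the `fit_ok`/`degenerate` flags.
* LOD/2 substitution plus midranks can dilute associations among poorly
  detected congeners; heavily censored congeners should be read with
  care even when they pass the 50% filter.
* The exact-member-set definition of cluster identity makes BP strict:
  a cluster that gains or loses one congener in a resample counts as
  absent.
* Greedy backward deletion is not guaranteed minimal; the reported
  deletion path makes the trajectory auditable.
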
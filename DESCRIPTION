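Package: congenerMarkers
Title: Fetal Exposure Marker Selection for Dioxin and Dioxin-Like PCB Congener Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies representative marker congeners among dioxins
    (PCDD/Fs) and dioxin-like PCBs measured in maternal blood, umbilical
    cord blood and umbilical cord tissue. Implements detection-rate
    filtering with LOD/2 substitution for left-censored values,
    hierarchical clustering of congeners on the Spearman dissimilarity
    1 - |rho|, cluster-stability assessment by multiscale bootstrap AU
    p-values, maximum generalized variance (MGV) optimal transformation
    via restricted cubic splines and canonical variates, marker subset
    selection by backward deletion of spline regression terms against the
    first principal component of each stable cluster, and marker-sum
    correlation analysis with percentile bootstrap confidence intervals.
    Includes a synthetic three-matrix congener data generator with planted
    correlation-block structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Clustering, Epidemiology, Preprocessing, PrincipalComponent
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
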
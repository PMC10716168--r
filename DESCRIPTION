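Package: connectodev
Title: Developmental Trajectories of Weighted White-Matter Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for longitudinal development of weighted white-matter
    structural connectomes. Computes weighted graph-theoretical properties (global,
    local and nodal efficiency, path length, strength, Onnela clustering, betweenness)
    with small-world normalisation against degree-preserving matched random networks;
    classifies edges into rich-club/feeder/local, within/between-module and long/short
    types; fits linear and quadratic mixed-effect developmental trajectories with AIC
    model selection and Bonferroni-corrected standardized slope maps; links slope maps
    to regional gene expression through partial least squares with variogram-matched
    spatially autocorrelated surrogate maps, bootstrap gene-weight z-scores, cell-type
    and category enrichment; and correlates slope maps with cytoarchitectural cortical
    maps. Includes a synthetic longitudinal cohort generator with planted ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
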
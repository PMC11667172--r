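Package: dyadak
Title: Dyad-Level Inter-Subject Dissimilarity Analysis of Mentalizing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing Anna Karenina ("AnnaK") structure in
    inter-subject data: per-subject neural features (functional
    connectivity, strength centrality, temporal inter-subject
    correlation) from ROI time series, gaze-trajectory and
    semantic-embedding dissimilarities, dyad-level dissimilarity
    matrices, and inference via symmetric dyadic linear mixed-effects
    models with participant random effects entering through both dyad
    members, degrees-of-freedom correction, pairwise group contrasts
    with FDR adjustment, and Mantel permutation tests. A
    synthetic-cohort generator reproduces
    the variability structure the analysis assumes so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
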
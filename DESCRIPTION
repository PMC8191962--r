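Package: strainsel
Title: Strain-Curve Feature Extraction and Feature Selection for CRT Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts a 158-element feature set from segmental longitudinal
    strain curves acquired in the three standard apical echocardiographic
    views (4-, 3- and 2-chamber): peak contraction magnitudes and timings,
    contraction heterogeneity and dyssynchrony markers, dead-zone-masked
    strain integrals up to aortic valve closure and up to the strain peak,
    the per-segment mechanical-efficiency marker derived from their
    difference, and wall (side) sums and differences. Provides a
    multi-method feature-importance stage for cardiac resynchronization
    therapy (CRT) response analysis: out-of-bag random-forest permutation
    importance, a thresholded feature-correlation graph, five filter and
    wrapper rankers (correlation with target, Welch t, ANOVA F, recursive
    feature elimination, ReliefF) and their rank combination, together with
    readers and writers for delimited-text strain exports and a synthetic
    cohort generator emulating left-bundle-branch-block strain mechanics
    with a controllable responder effect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
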
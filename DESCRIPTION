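Package: groomnet
Title: Multi-Group Grooming Social Network Analysis for Group-Living Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, weighted grooming networks from scan-sampling
    observation tables of multiple primate groups, standardizing dyadic edge
    weights by joint observability (the index of interactions). Computes five
    node-level network measures (out-strength, in-strength, disparity,
    affinity, eigenvector centrality) with group-size standardizations, runs
    randomization-tested dominance analyses (normalized David's scores,
    hierarchy steepness, Landau linearity with correction for unknown and tied
    dyads), and fits linear mixed models with AIC backward reduction to relate
    individual traits (sex, age, rearing history) and group traits (group
    size, sex ratio) to network position. Includes a seeded synthetic-data
    generator with planted effects so the whole pipeline is testable end to
    end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
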
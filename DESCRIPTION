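Package: tractopo
Title: Tractwise Connectome Statistics and Persistent Homology for
    Alzheimer's Disease Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for structural brain connectomes built from
    tractwise mean generalized fractional anisotropy (GFA). Provides
    quality control of sparse connectivity matrices (island detection,
    coverage and template filters), normative w-score modelling against a
    cognitively normal reference group, mass-univariate tractwise
    contrasts with false-discovery-rate control and Tukey post-hoc tests,
    linear mixed-effects models coupling grey-matter atrophy to
    white-matter degeneration, and persistent-homology analysis of brain
    graphs: Betti-0/Betti-1 curves over graph filtrations with exact
    topological inference by banded lattice-path enumeration. A synthetic
    cohort generator reproduces the statistical structure the pipeline
    assumes, so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    lme4,
    lmerTest,
    emmeans
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
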
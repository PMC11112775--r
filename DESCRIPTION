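Package: admixsib
Title: Admixed Full-Sibling Design for Ancestry Differences in Mean
    Genotypic Value
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for the admixed full-sibling
    design, which estimates the difference in mean genotypic value between
    two ancestral populations from the regression of within-sibling-pair
    phenotype differences on within-pair differences in genome-wide ancestry
    proportion. Includes a pedigree and local-ancestry simulator (Poisson
    crossover meiosis on a genetic map, Balding-Nichols ancestral allele
    frequencies), two-way admixture proportion estimation by EM, an
    admixture-aware IBD-coefficient estimator with full-sibling
    classification and filtering rules, the within-pair, population-level
    and mixed-model regression estimators with rank-based inverse-normal
    transformation and FDR correction, and simulation-based sensitivity
    analyses for ancestry-by-environment interaction, participation bias and
    ancestry-estimation error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
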
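Package: csense
Title: Community Sensitivity Analysis Linking Microbiome and Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting gut microbial community structure from
    metabolomic environments. Builds a signed, directed, bipartite
    species-metabolite sensitivity graph by coupling flux balance analysis
    of genome-scale-style metabolic models with Latin-hypercube global
    sensitivity analysis (partial rank correlation coefficients), runs a
    signed network propagation with negative-weight clamping to obtain
    steady-state community weights from metabolite seed sets, and compares
    predicted against observed species abundances with the top-down
    concordance coefficient (Savage scores). Also implements the standard
    untargeted LC-MS preprocessing chain: probabilistic quotient
    normalization, QC-based robust LOESS drift correction, and a QC
    coefficient-of-variation filter. Ships seeded synthetic-data
    generators (toy metabolic models, community scenarios, LC-MS runs
    with planted dilution and drift) so the whole pipeline is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
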
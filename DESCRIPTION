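Package: sigdecon
Title: Risk-Factor Expression Signatures, Perturbation Matching and Drug
    Target Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates landmark-gene mRNA signatures of clinical and genetic
    tumour risk factors by low-rank latent-factor regression across patient
    cohorts, matches the signatures against a z-transformed drug-perturbation
    expression compendium with a calibrated, bounded match score, and
    deconvolves enriched protein targets from chemical-protein link tables
    using one-tailed two-sample Kolmogorov-Smirnov tests with false discovery
    rate control. Includes a fully synthetic data generator with planted
    ground truth, permutation null calibration, Cox proportional-hazards risk
    features, minimum-spanning-tree summaries of significant targets over
    protein-link graphs, and an exponential-decay morphology score for cell
    protrusion measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
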
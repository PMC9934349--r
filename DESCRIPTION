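Package: SlePhenotyper
Title: Phenotype Algorithms for Systemic Lupus Erythematosus in
    Observational Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements four phenotype algorithms for systemic lupus
    erythematosus (SLE) over simplified OMOP-style observational data
    (incident/prevalent entry, single or confirmed diagnosis code, each
    with correction of index-date misclassification from prodromal signs,
    symptoms and treatment drugs), plus two published comparator
    algorithms requiring three diagnosis codes and antimalarial exposure.
    Ships a seeded synthetic claims simulator with latent ground truth,
    performance estimation (sensitivity, specificity, PPV, NPV, F1 with
    Wilson intervals), cohort diagnostics (counts, overlap, incidence
    rates, index-event breakdown, temporal characterization, standardized
    differences, 1:k matched comparators), and quantitative bias analysis
    via the Rogan-Gladen correction with probabilistic intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
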
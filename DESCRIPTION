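Package: gdrisk
Title: Polygenic Risk, Physical Activity, and Gestational Diabetes Risk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible pipeline for studying the joint association of
    polygenic risk and physical activity with gestational diabetes in a
    nulliparous cohort: genotype quality control and weighted-allele polygenic
    risk scoring, METs-based activity classification, glucose-tolerance-test
    case definition, subgroup odds ratios and positive likelihood ratios with
    bootstrap null inference, a PRS-by-activity interaction logistic model,
    and a cross-validated AUC harness. A synthetic-cohort generator emulates
    the statistical structure of the study population so every stage is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
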
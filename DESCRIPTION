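Package: pfascohort
Title: Register-Based Cohort Analysis of Prenatal PFAS Exposure and
    Childhood Asthma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for register-based open-cohort studies of prenatal
    drinking-water PFAS exposure and childhood respiratory outcomes.
    Provides a synthetic linked-register generator (births, annual maternal
    address snapshots with waterworks flags, diagnosis and drug-dispensation
    streams, vital events, serum biomarker samples), an address-based
    four-level prenatal exposure classifier, declarative ICD-10/ATC outcome
    phenotyping algorithms for wheeze, asthma and persistent asthma,
    open-cohort follow-up construction, Kaplan-Meier and Cox
    proportional-hazards estimation with sex-by-parity stratified baselines
    and sibling-cluster-robust variance, chained-equations multiple
    imputation with Rubin's-rules pooling, robust rank-based Mahalanobis
    3:1 matching with Fisherian randomization inference on the
    cumulative-incidence difference, and validation statistics
    (Jonckheere-Terpstra trend test, sensitivity/specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    nnet,
    MASS
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
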
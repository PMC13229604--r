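Package: sleepdex
Title: Multidimensional Sleep Health Scoring and Phenome-Wide Association Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing a multidimensional sleep lifestyle index
    from self-reported bed and wake clock times and electronic health record
    (EHR) billing codes, computing a standardized polygenic sleep health score
    from a variant weight table and genotype dosages, calling phecode-based
    case/control phenotypes under windowed counting rules, and running
    phenome-wide logistic association scans (PheWAS) with Bonferroni control
    and polygenic-score-by-lifestyle interaction tests. Includes a synthetic
    biobank cohort generator with planted effect sizes so the whole pipeline
    can be exercised and validated end to end without access to restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
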
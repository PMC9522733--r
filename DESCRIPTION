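Package: octscreen
Title: OCT-Based Screening for Intracranial Hypertension in Craniosynostosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening children with sagittal suture synostosis for
    intracranial hypertension using peripapillary optical coherence tomography
    (OCT). Provides non-parametric bootstrap reference intervals (with endpoint
    confidence intervals) for total retinal thickness and volume on the
    eight-sector peripapillary grid, quantile-regression covariate screening,
    cut-off classification of patient scans, operationalised clinical signs
    (occipitofrontal-circumference growth-arrest detection, fingerprinting
    scale collapse, Cohen kappa interrater agreement), exact 2x2 association
    statistics with conditional maximum-likelihood odds ratios and exact
    confidence intervals, and a calibrated synthetic-cohort generator so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    optparse
Config/testthat/edition: 3
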
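Package: pdaclose
Title: Predicting Early Spontaneous Closure of the Patent Ductus Arteriosus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for neonatal hemodynamic assessment and prediction of early
    spontaneous closure of the patent ductus arteriosus (PDA) in very preterm
    infants. Implements derived echocardiographic quantities (left ventricular
    output, superior vena cava flow, and their ratio), a 0-11 ductal disease
    staging score with support for user-defined staging schemes, a published
    logistic model combining gestational age and the screening PDA score,
    maximum-likelihood logistic fitting with Wald-statistic backward
    elimination, ROC analysis with Youden cut-off selection and Wilson score
    intervals for diagnostic performance, nonparametric two-group cohort
    comparisons, and a seedable synthetic cohort generator calibrated to the
    published group medians and interquartile ranges so the full analysis
    chain can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
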
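Package: pcrsig
Title: Gene-Expression Classifiers of Pathological Complete Response to Chemoradiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and application of pretreatment gene-expression
    classifiers of pathological complete response (pCR) to neoadjuvant
    chemoradiotherapy in rectal cancer. Implements resampled hill-climbing
    wrapper feature selection optimising sensitivity at a zero false-positive
    rate, linear support-vector-machine classification with quantile
    normalization anchored to a frozen reference distribution, a
    normalization-free ratio-of-sums score classifier trained by
    random-restart local search, and score-based prognosis via Kaplan-Meier
    and log-rank analysis. Ships a synthetic-cohort generator emulating the
    extreme-response discovery design, batch-shifted validation cohorts and
    survival cohorts, so the whole pipeline is testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    survival,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
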
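Package: apocrineR
Title: Identification of Molecular Apocrine Breast Tumors from qRT-PCR and
    Immunohistochemistry Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify molecular apocrine (MA) versus basal-like (BL)
    estrogen-receptor-negative breast tumors from quantitative RT-PCR
    expression ratios and immunohistochemical marker panels. Implements
    reference-gene ratio quantification, two-component Gaussian-mixture
    estimation of positivity cutoffs at the density intersection, the
    multi-gene androgen-receptor-pathway signature call, exact diagnostic
    statistics for composite marker rules (Fisher exact tests,
    Clopper-Pearson intervals, binary-rule AUC), deviance-based
    classification trees with cross-validated cost-complexity pruning,
    Kaplan-Meier survival summaries with log-rank comparison, multiple
    correspondence analysis of marker panels, and a calibrated synthetic
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    tree,
    jsonlite,
    withr
Config/testthat/edition: 3
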
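Package: methpanel
Title: Tumor-Specific CpG Methylation Panels and Surrogate-Specimen Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tumor-specific CpG methylation panels from 450K-style
    beta-value matrices and evaluates whether bronchoscopic specimens
    (bronchial biopsy, bronchial washing, sputum) are valid surrogates for
    resected tumor tissue. Implements beta-value computation and QC against
    methylation standards, dichotomized differential-methylation testing with
    Bonferroni family-wise error control (Pearson chi-square with exact Fisher
    routing), removal of age-correlated CpGs, gene-ontology-constrained
    feature selection with within-term correlation pruning, logistic-regression
    panel fitting ranked by likelihood-ratio evidence, ROC/AUC evaluation, and
    Wilcoxon rank-sum / signed-rank surrogate comparisons. Ships a synthetic
    cohort generator with tumor-purity dilution, background-signal inflation
    and age-drift structure, including planted ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
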
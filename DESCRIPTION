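Package: glycoMRM
Title: Drift-Normalized MRM Glycoproteomics of Liver Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for targeted (MRM/dMRM) serum glycoproteomics of
    fatty-liver disease progression. Parses 4-digit glycan composition
    codes (Hex/HexNAc/Fuc/NeuAc) and glycopeptide marker identifiers,
    corrects raw peak areas for within-run drift using interspersed
    reference-pool injections, computes relative abundances, performs
    covariate-adjusted differential abundance testing with
    Benjamini-Hochberg FDR control and a significance-intersection
    cascade, screens for unidirectional progression markers across the
    control/NASH/HCC cascade, summarizes glycan motif groups
    (fucosylation by sialylation), and classifies phenotypes with
    LASSO-regularized logistic regression under leave-one-out
    cross-validation with ROC/AUROC evaluation. Includes a synthetic
    cohort generator emulating randomized injection order, periodic QC
    pools, multiplicative drift, and phenotype-linked glycoform shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
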
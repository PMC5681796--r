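Package: mirpanel
Title: Whole-Blood miRNA qRT-PCR Panel Analysis with Stability-Based
    Reference Selection and KS-Cutoff Biomarker Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for targeted whole-blood microRNA qRT-PCR
    panels across clinical groups (healthy controls, rheumatoid arthritis
    patients, and seropositive first-degree relatives). Implements
    candidate reference-gene stability ranking (geNorm, NormFinder,
    BestKeeper, comparative delta-Ct, with geometric-mean rank
    aggregation), the delta-Ct / global-mean / delta-delta-Ct
    normalization cascade with a detectability filter, nonparametric
    differential expression (Mann-Whitney U with Benjamini-Hochberg
    control, Kruskal-Wallis with Dunn's post hoc test, Spearman
    correlation), Kolmogorov-Smirnov-distance biomarker cutoffs with ROC
    and AUC, fold-change clustering summaries, and a seeded synthetic
    cohort generator that emulates the study design for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
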
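#!/usr/bin/env Rscript
# Biomarker evaluation of miR-103a-3p: signed Kolmogorov-Smirnov
# distance between group ECDFs of normalized delta-Ct, the delta-Ct
# cutoff attaining it, sensitivity/specificity at that cutoff, and the
# ROC/AUC, for each of the three group contrasts. |D| > 0.5 is treated
# as a significant separation.

library(mirpanel)

norm_df <- read_result_table("results/normalized_dct.tsv")
norm <- as.matrix(norm_df[, -1])
rownames(norm) <- norm_df$sample_id
sheet <- read_sample_sheet("results/cohort_samples.csv")

marker <- "hsa-miR-103a-3p"
contrasts <- list(c("RA", "HC"), c("FDR", "HC"), c("FDR", "RA"))

rows <- list()
roc_rows <- list()
for (cmp in contrasts) {
  ev <- evaluate_marker(norm, sheet, marker, cmp[1], cmp[2])
  print(ev)
  key <- paste0(cmp[1], "_vs_", cmp[2])
  rows[[key]] <- data.frame(marker = marker, case = cmp[1], control = cmp[2],
                            direction = ev$direction, D = ev$D,
                            cutoff = ev$cutoff,
                            sensitivity = ev$sensitivity,
                            specificity = ev$specificity, auc = ev$auc,
                            significant = ev$significant,
                            stringsAsFactors = FALSE)
  pts <- ev$roc_points
  pts$comparison <- key
  roc_rows[[key]] <- pts
}
write_result_table(do.call(rbind, rows), "results/ks_evaluations.tsv")
write_result_table(do.call(rbind, roc_rows), "results/roc_points.tsv")
cat("Wrote results/ks_evaluations.tsv and results/roc_points.tsv\n")
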
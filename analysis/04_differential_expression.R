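#!/usr/bin/env Rscript
# Differential expression over the three clinical comparisons: per
# miRNA, Mann-Whitney U on normalized delta-Ct, median-based signed fold
# change, BH adjustment within each 33-test comparison family, and the
# fold-change ranking. Prints the headline counts and top movers.

library(mirpanel)

norm_df <- read_result_table("results/normalized_dct.tsv")
norm <- as.matrix(norm_df[, -1])
rownames(norm) <- norm_df$sample_id
sheet <- read_sample_sheet("results/cohort_samples.csv")

de <- build_de_table(norm, sheet,
                     comparisons = list(c("RA", "HC"), c("FDR", "HC"),
                                        c("FDR", "RA")),
                     alpha = 0.05, q_threshold = 0.04)
write_result_table(de, "results/de_table.tsv")

for (cc in unique(de$comparison)) {
  sub <- de[de$comparison == cc, ]
  cat(sprintf("%s: %d of %d miRNAs at P < 0.05 (%d at Q < 0.04)\n",
              cc, sum(sub$sig_p, na.rm = TRUE), nrow(sub),
              sum(sub$sig_q, na.rm = TRUE)))
  top <- sub[sub$rank == 1, ][1, ]
  bot <- sub[which.min(sub$fold), ]
  cat(sprintf("  top fold: %s (%+.2f, P = %.4g); most down: %s (%+.2f, P = %.4g)\n",
              top$assay, top$fold, top$P, bot$assay, bot$fold, bot$P))
}
cat("Wrote results/de_table.tsv\n")
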
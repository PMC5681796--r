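#!/usr/bin/env Rscript
# Summary structure of the differential-expression results: the log2
# fold-change matrix across the two "vs HC" comparisons, its
# unsupervised hierarchical row ordering (Euclidean distance, average
# linkage), and volcano-plot coordinates. Outputs are plot-ready data;
# rendering is left to the reader's tool of choice.

library(mirpanel)

de <- read_result_table("results/de_table.tsv")

fm <- build_fold_matrix(de, comparisons = c("RA_vs_HC", "FDR_vs_HC"))
ord <- hierarchical_order(fm, metric = "euclidean", linkage = "average")
vc <- volcano_coords(de)

fm_df <- data.frame(assay = rownames(fm), fm, check.names = FALSE)
write_result_table(fm_df[ord$order, ], "results/fold_matrix_clustered.tsv")
write_result_table(vc, "results/volcano.tsv")
writeLines(ord$labels, "results/leaf_order.txt")

cat("Leaf order (top 5):", paste(head(ord$labels, 5), collapse = ", "), "...\n")
cat(sprintf("Volcano guide line at -log10(0.05) = %.4f\n", attr(vc, "guide")))
up <- vc[vc$comparison == "RA_vs_HC", ]
cat(sprintf("RA vs HC extremes: %s (x = %+.2f), %s (x = %+.2f)\n",
            up$assay[which.max(up$log2_fold)], max(up$log2_fold),
            up$assay[which.min(up$log2_fold)], min(up$log2_fold)))
cat("Wrote results/fold_matrix_clustered.tsv, results/volcano.tsv, results/leaf_order.txt\n")
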
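#!/usr/bin/env Rscript
# Rank the five candidate endogenous controls (RNU48, RNU6B, RNU44, U6,
# miR-16) by the four stability methods (geNorm, comparative delta-Ct,
# BestKeeper, NormFinder) and aggregate the ranks geometrically. The
# analysis itself proceeds with the forced pair RNU48 + RNU6B; this step
# documents how the stability evidence relates to that choice on the
# simulated cohort.

library(mirpanel)

panel <- default_panel()
roles <- setNames(panel$role, panel$assay)
ct <- read_ct_table("results/cohort_ct.csv", assay_roles = roles)
sheet <- read_sample_sheet("results/cohort_samples.csv")

st <- reference_stability(ct, sheet)
write_result_table(as.data.frame(st), "results/stability.tsv")

cat("Candidate stability (lower aggregate rank = more stable):\n")
print(as.data.frame(st)[, c("candidate", "genorm_m", "comparative_dct_sd",
                            "bestkeeper_sd", "normfinder_stability",
                            "aggregate_rank")], digits = 3)
cat("\nChosen pair by aggregate rank:",
    paste(attr(st, "chosen_pair"), collapse = " + "), "\n")
cat("Pair used downstream (study choice): RNU48 + RNU6B\n")
cat("Wrote results/stability.tsv\n")
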
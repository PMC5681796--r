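#' Packaged differential-expression table for the whole-blood panel
#'
#' Loads the packaged per-miRNA summary of the three clinical
#' comparisons (RA vs HC, FDR vs HC, FDR vs RA): Mann-Whitney P value
#' and median-based signed fold change for each of the 33 detectable
#' miRNAs of the 35-assay panel, plus the printed RA-vs-HC fold-change
#' rank. `hsa-miR-34a*` carries the alias `hsa-miR-34a-3p` in the
#' `alias` column; all other aliases equal the printed name.
#'
#' Signed fold changes follow the reciprocal convention: ratios below 1
#' are reported as negative reciprocals (0.5 -> -2), so no value lies in
#' the open interval (-1, 1).
#'
#' @return A data frame with 33 rows and columns `mirna`, `alias`,
#'   `p_ra_hc`, `fold_ra_hc`, `rank_ra_hc`, `p_fdr_hc`, `fold_fdr_hc`,
#'   `p_fdr_ra`, `fold_fdr_ra`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_fold_changes.csv",
                      package = "mirpanel", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 33) stop("fixture corrupt: expected 33 miRNA rows, got ", nrow(df))
  p <- unlist(df[, c("p_ra_hc", "p_fdr_hc", "p_fdr_ra")])
  if (any(p <= 0 | p > 1)) stop("fixture corrupt: P values must lie in (0, 1]")
  f <- unlist(df[, c("fold_ra_hc", "fold_fdr_hc", "fold_fdr_ra")])
  if (any(abs(f) < 1)) stop("fixture corrupt: signed folds must not lie in (-1, 1)")
  if (anyDuplicated(df$mirna)) stop("fixture corrupt: duplicate miRNA names")
  df
}

#' Comparisons covered by the packaged fixture
#'
#' @return Named list mapping comparison label to the fixture's P and
#'   fold column names.
#' @export
fixture_comparisons <- function() {
  list(
    RA_vs_HC  = c(p = "p_ra_hc",  fold = "fold_ra_hc"),
    FDR_vs_HC = c(p = "p_fdr_hc", fold = "fold_fdr_hc"),
    FDR_vs_RA = c(p = "p_fdr_ra", fold = "fold_fdr_ra")
  )
}
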
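# Fold-change matrix assembly, hierarchical leaf ordering, and volcano
# coordinates (plot-ready data; rendering is left to the caller).

#' Assemble a log2 fold-change matrix across comparisons
#'
#' Rows are miRNAs, columns the requested comparisons, entries the
#' signed fold changes converted to log2 ratios (signed +4 becomes +2,
#' signed -4 becomes -2). All comparisons must cover the same miRNA
#' set.
#'
#' @param de Differential-expression table from [build_de_table()].
#' @param comparisons Comparison labels to include; default the first
#'   two present (the "vs HC" pair in the standard run).
#' @return Numeric matrix of log2 fold changes.
#' @export
build_fold_matrix <- function(de, comparisons = NULL) {
  if (is.null(comparisons)) comparisons <- unique(de$comparison)
  sets <- lapply(comparisons, function(cc) sort(de$assay[de$comparison == cc]))
  ref <- sets[[1]]
  for (i in seq_along(sets)) {
    if (!identical(sets[[i]], ref)) {
      diffs <- c(setdiff(ref, sets[[i]]), setdiff(sets[[i]], ref))
      stop("comparisons cover different miRNA sets; difference: ",
           paste(unique(diffs), collapse = ", "))
    }
  }
  m <- sapply(comparisons, function(cc) {
    sub <- de[de$comparison == cc, ]
    stats::setNames(signed_to_log2(sub$fold), sub$assay)[ref]
  })
  m <- matrix(m, nrow = length(ref),
              dimnames = list(ref, comparisons))
  m
}

#' Agglomerative leaf ordering of a fold-change matrix
#'
#' Hierarchical clustering of the rows with a configurable distance and
#' linkage (defaults: Euclidean distance, average linkage). The merge
#' tree and leaf order are deterministic for a given input (ties merge
#' the lower-index cluster first, the `stats::hclust` convention).
#'
#' @param fm Numeric matrix (e.g. from [build_fold_matrix()]); all
#'   entries must be finite.
#' @param metric Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `order` (leaf order, row indices), `labels`
#'   (rownames in leaf order), and `hclust` (the full tree).
#' @export
hierarchical_order <- function(fm, metric = "euclidean",
                               linkage = "average") {
  stopifnot(is.matrix(fm))
  if (nrow(fm) < 2) {
    return(list(order = 1L, labels = rownames(fm), hclust = NULL))
  }
  if (any(!is.finite(fm))) stop("fold matrix contains non-finite entries")
  hc <- stats::hclust(stats::dist(fm, method = metric), method = linkage)
  list(order = hc$order, labels = rownames(fm)[hc$order], hclust = hc)
}

#' Volcano-plot coordinates
#'
#' Per miRNA: x = log2 signed fold, y = -log10 P, plus the customary
#' P = 0.05 guide line as attribute `guide`.
#'
#' @param de Differential-expression table (one or more comparisons).
#' @return Data frame with `assay`, `comparison`, `log2_fold`,
#'   `neg_log10_p`; attribute `guide` = -log10(0.05).
#' @export
volcano_coords <- function(de) {
  if (any(!is.na(de$P) & de$P <= 0)) stop("P values must be > 0")
  out <- data.frame(assay = de$assay, comparison = de$comparison,
                    log2_fold = signed_to_log2(de$fold),
                    neg_log10_p = -log10(de$P), stringsAsFactors = FALSE)
  attr(out, "guide") <- -log10(0.05)
  out
}
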
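# Nonparametric differential expression and correlation statistics.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. With
#' `n_x + n_y <= 12` and no ties the P value comes from exact
#' enumeration of the permutation null; otherwise from the normal
#' approximation with tie and continuity corrections. Identical values
#' on both sides give P = 1 by convention. The U statistic counts pairs
#' in which an `x` exceeds a `y` (plus half-ties), i.e. W of `x`.
#'
#' @param x,y Numeric vectors, at least 2 non-missing values each.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("mann_whitney needs >= 2 values per side")
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values, monotone in sorted order and capped at 1.
#'
#' @param p P values in (0, 1]; `NA` passes through.
#' @return Adjusted values (Q) in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("P values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter significant P values
#'
#' @param p P values.
#' @param alpha Threshold; strict inequality `p < alpha`.
#' @return List with `significant` (logical, `NA`-safe) and `count`.
#' @export
filter_significant <- function(p, alpha = 0.05) {
  sig <- !is.na(p) & p < alpha
  list(significant = sig, count = sum(sig))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across three or more groups, followed
#' by Dunn's pairwise z statistics on the pooled ranks with
#' tie-corrected variance. Pairwise P values are two-sided and reported
#' unadjusted, with a Benjamini-Hochberg column alongside. Degenerate
#' input with every pooled value identical gives H = 0, P = 1.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, >= 2
#'   values each).
#' @return List with `H`, `p`, and `pairwise` (data frame of group
#'   pairs, `z`, `p`, `q`).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 3) {
    stop("kruskal_dunn needs >= 3 groups; use mann_whitney for two")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    pairs <- utils::combn(names(groups), 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p = 1, q = 1, stringsAsFactors = FALSE)
    return(list(H = 0, p = 1, pairwise = pw))
  }
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  mean_rank <- tapply(r, g, mean)
  tie <- table(x)
  tie_term <- sum(tie^3 - tie)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    n1 <- sum(g == pr[1]); n2 <- sum(g == pr[2])
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) /
      sqrt(sigma2 * (1 / n1 + 1 / n2))
  })
  p <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
                   q = bh_adjust(p), stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}

#' Spearman rank correlation
#'
#' Tie-safe rho (Pearson correlation of ranks) with the asymptotic t
#' approximation for the P value. Zero variance in either rank vector
#' leaves rho undefined (`NA`).
#'
#' @param x,y Paired numeric vectors, n >= 3 complete pairs.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("spearman_cor needs >= 3 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ctest <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ctest$estimate), p = ctest$p.value, n = length(x))
}

#' Differential-expression table over a normalized cohort
#'
#' For each target miRNA and each requested group comparison: the
#' Mann-Whitney test and the median-based signed fold change on
#' normalized delta-Ct values, with Benjamini-Hochberg adjustment across
#' the miRNA panel within each comparison (matching a per-comparison
#' multiple-testing family), and a fold-change rank within each
#' comparison (descending signed fold; ties share the minimum rank and
#' are then ordered by name). Missing values are handled by pairwise
#' deletion; a comparison needs at least 2 observations per side, else
#' its statistics are `NA`. Both significance flags are reported: raw
#' `P < alpha` and adjusted `Q < q_threshold`.
#'
#' @param norm Normalized delta-Ct matrix ([global_mean_normalize()] or
#'   the `normalized` element of [normalize_cohort()]).
#' @param sheet Sample sheet covering the matrix samples.
#' @param comparisons List of `c(case, control)` group pairs.
#' @param alpha Raw significance threshold.
#' @param q_threshold Adjusted (Q) significance threshold.
#' @return Data frame with one row per miRNA per comparison: `assay`,
#'   `case`, `control`, `comparison`, `n_case`, `n_control`, `U`, `P`,
#'   `Q`, `ddct`, `fold` (signed), `rank`, `sig_p`, `sig_q`.
#' @export
build_de_table <- function(norm, sheet,
                           comparisons = list(c("RA", "HC"), c("FDR", "HC"),
                                              c("FDR", "RA")),
                           alpha = 0.05, q_threshold = 0.04) {
  m <- unclass(norm)
  stopifnot(is.matrix(m))
  sheet <- sheet[match(rownames(m), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sample(s) missing from sample sheet")
  out <- list()
  for (cmp in comparisons) {
    case <- cmp[1]; control <- cmp[2]
    for (gname in c(case, control)) {
      if (!gname %in% sheet$group) stop("group absent from cohort: ", gname)
    }
    label <- paste0(case, "_vs_", control)
    ci <- sheet$group == case
    ki <- sheet$group == control
    rows <- lapply(colnames(m), function(a) {
      xc <- m[ci, a]; xk <- m[ki, a]
      if (sum(!is.na(xc)) < 2 || sum(!is.na(xk)) < 2) {
        return(data.frame(assay = a, case = case, control = control,
                          comparison = label, n_case = sum(!is.na(xc)),
                          n_control = sum(!is.na(xk)), U = NA_real_,
                          P = NA_real_, ddct = NA_real_, fold = NA_real_,
                          stringsAsFactors = FALSE))
      }
      mw <- mann_whitney(xc, xk)
      fc <- signed_fold_change(xc, xk)
      data.frame(assay = a, case = case, control = control,
                 comparison = label, n_case = fc$n_case,
                 n_control = fc$n_control, U = mw$U, P = mw$p,
                 ddct = fc$ddct, fold = fc$signed, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$Q <- bh_adjust(tab$P)
    fold_key <- ifelse(is.na(tab$fold), -Inf, tab$fold)
    tab$rank <- rank(-fold_key, ties.method = "min")
    tab <- tab[order(tab$rank, tab$assay), ]
    tab$sig_p <- filter_significant(tab$P, alpha)$significant
    tab$sig_q <- filter_significant(tab$Q, q_threshold)$significant
    out[[label]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("assay", "case", "control", "comparison", "n_case", "n_control",
          "U", "P", "Q", "ddct", "fold", "rank", "sig_p", "sig_q")]
}
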
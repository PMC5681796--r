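# Reference-gene stability ranking: geNorm, comparative delta-Ct,
# BestKeeper, NormFinder, and geometric-mean rank aggregation.
# All methods operate directly on Ct, which is already a log2-scale
# quantity (one PCR cycle = one log2 unit of template), so pairwise Ct
# differences are log ratios and no linearization is needed.

# Extract the candidate submatrix, enforcing shared preconditions.
.candidate_ct <- function(ct, candidates, min_candidates = 2L) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (is.null(candidates)) candidates <- candidate_references(ct)
  miss <- setdiff(candidates, assay_ids(ct))
  if (length(miss)) stop("candidate assay(s) not in matrix: ", paste(miss, collapse = ", "))
  if (length(candidates) < min_candidates) {
    stop("need at least ", min_candidates, " candidate reference assays")
  }
  m <- ct$values[, candidates, drop = FALSE]
  if (nrow(m) < 4) stop("stability methods refuse to run with fewer than 4 samples")
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    stop("nondetect among candidate reference assay(s) ",
         paste(bad, collapse = ", "),
         "; impute or exclude the affected samples upstream")
  }
  m
}

# SD of pairwise Ct differences, the shared kernel of geNorm and the
# comparative delta-Ct method.
.pairwise_sd <- function(m) {
  k <- ncol(m)
  v <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v[i, j] <- v[j, i] <- stats::sd(m[, i] - m[, j])
    }
  }
  v
}

#' geNorm expression-stability measure M
#'
#' For each candidate j, `M(j)` is the mean over partners k of the
#' sample standard deviation of the pairwise Ct difference
#' `Ct_j - Ct_k`. Lower M means more stable. Candidates are then
#' eliminated iteratively: the highest-M candidate is dropped and M
#' recomputed until two remain (ties broken toward the lexicographically
#' later name so elimination is deterministic).
#'
#' @param ct A [ct_matrix()].
#' @param candidates Candidate assay ids; defaults to the matrix's
#'   `candidate_reference` assays. Nondetects among candidates are a
#'   hard error.
#' @return List with `m` (named M values for the full candidate set),
#'   `elimination` (assays in drop order), and `final_pair`.
#' @export
genorm_m <- function(ct, candidates = NULL) {
  m <- .candidate_ct(ct, candidates, min_candidates = 3L)
  m_of <- function(mat) {
    v <- .pairwise_sd(mat)
    rowMeans(v) * ncol(v) / (ncol(v) - 1)  # mean over k != j
  }
  first <- m_of(m)
  cur <- m
  dropped <- character()
  while (ncol(cur) > 2) {
    mm <- m_of(cur)
    worst <- names(mm)[mm == max(mm)]
    worst <- sort(worst, decreasing = TRUE)[1]
    dropped <- c(dropped, worst)
    cur <- cur[, setdiff(colnames(cur), worst), drop = FALSE]
  }
  list(m = first, elimination = dropped, final_pair = colnames(cur))
}

#' Comparative delta-Ct stability
#'
#' Mean, over all partners, of the sample SD of the pairwise Ct
#' difference — the geNorm kernel without iterative elimination.
#'
#' @inheritParams genorm_m
#' @return Named numeric vector, one value per candidate (lower =
#'   more stable).
#' @export
comparative_dct_stability <- function(ct, candidates = NULL) {
  m <- .candidate_ct(ct, candidates, min_candidates = 2L)
  v <- .pairwise_sd(m)
  if (ncol(m) == 2) {
    out <- c(v[1, 2], v[1, 2])
    names(out) <- colnames(m)
    return(out)
  }
  rowMeans(v) * ncol(v) / (ncol(v) - 1)
}

#' BestKeeper descriptors
#'
#' Per candidate: the sample SD of its Ct across samples and the Pearson
#' correlation with the BestKeeper index (the per-sample arithmetic mean
#' Ct over candidates — the log-scale equivalent of the geometric mean
#' of linear quantities). Ranking downstream uses `sd` ascending; `r` is
#' descriptive. A zero-variance candidate has undefined `r` (reported
#' `NA`) and is ranked best by its zero SD.
#'
#' @inheritParams genorm_m
#' @return Data frame with columns `candidate`, `sd`, `r`.
#' @export
bestkeeper_stats <- function(ct, candidates = NULL) {
  m <- .candidate_ct(ct, candidates, min_candidates = 2L)
  idx <- rowMeans(m)
  sds <- apply(m, 2, stats::sd)
  r <- vapply(seq_len(ncol(m)), function(j) {
    if (sds[j] == 0 || stats::sd(idx) == 0) return(NA_real_)
    stats::cor(m[, j], idx)
  }, numeric(1))
  data.frame(candidate = colnames(m), sd = unname(sds), r = r,
             stringsAsFactors = FALSE)
}

#' NormFinder model-based stability
#'
#' Variance-decomposition stability on Ct (log-scale) data following the
#' published two-level model: per candidate and group, an intragroup
#' variance is estimated from the two-way (gene x sample) residuals, and
#' an intergroup component from the group-wise deviations of gene means
#' around the panel average, shrunk by its sampling variance. The
#' stability value combines the absolute (shrunk) intergroup deviation
#' with the intragroup standard error; smaller is more stable. With
#' unequal group sizes, the cross-group averages are weighted by group
#' degrees of freedom. With a single group the function falls back to an
#' intragroup-only variant (residual SD) and flags it.
#'
#' @inheritParams genorm_m
#' @param sheet Sample sheet aligned to `ct` (see [align_sheet()]).
#' @return List with `stability` (named vector, lower = better) and
#'   `single_group` flag.
#' @export
normfinder_stability <- function(ct, sheet, candidates = NULL) {
  m <- .candidate_ct(ct, candidates, min_candidates = 3L)
  sheet <- align_sheet(ct, sheet)
  grp <- sheet$group
  groups <- unique(grp)
  G <- ncol(m)

  if (length(groups) < 2) {
    resid_sd <- apply(m, 2, function(x) stats::sd(x - rowMeans(m)))
    return(list(stability = resid_sd, single_group = TRUE))
  }
  sizes <- table(grp)
  if (any(sizes < 2)) stop("each group needs at least 2 samples")

  K <- length(groups)
  s2 <- z <- matrix(NA_real_, nrow = K, ncol = G,
                    dimnames = list(groups, colnames(m)))
  for (g in groups) {
    xg <- m[grp == g, , drop = FALSE]
    ng <- nrow(xg)
    gene_mean <- colMeans(xg)
    samp_mean <- rowMeans(xg)
    grand <- mean(xg)
    r <- xg - outer(samp_mean, rep(1, G)) -
      outer(rep(1, ng), gene_mean) + grand
    # two-way residual variance with the published G/(G-2) inflation
    s2[g, ] <- colSums(r^2) / (ng - 1) * G / (G - 2)
    z[g, ] <- gene_mean - grand
  }
  w <- (sizes[groups] - 1) / sum(sizes[groups] - 1)  # df weights
  d <- z - matrix(colSums(z * as.numeric(w)), nrow = K, ncol = G, byrow = TRUE)
  n_g <- as.numeric(sizes[groups])
  samp_var <- s2 / n_g
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (K - 1)) - mean(samp_var))
  denom <- gamma2 + samp_var
  d_hat <- ifelse(denom > 0, d * gamma2 / denom, 0)
  se2 <- ifelse(denom > 0, gamma2 * samp_var / denom, 0)
  rho <- abs(d_hat) + sqrt(se2)
  stability <- colSums(rho * as.numeric(w))
  list(stability = stability, single_group = FALSE)
}

#' Aggregate per-method stability ranks
#'
#' Geometric mean of the four per-method ranks (geNorm M, comparative
#' delta-Ct, BestKeeper SD, NormFinder stability), with ties in the
#' aggregate broken by geNorm M and then by name. The chosen reference
#' pair is the two candidates with the lowest aggregate.
#'
#' @param ranks Numeric matrix, candidates x methods (4 columns), each
#'   column a rank vector over the same candidate set.
#' @param genorm Named geNorm M values used for tie-breaking; optional.
#' @return List with `aggregate_rank` (named, geometric-mean scale) and
#'   `chosen_pair`.
#' @export
aggregate_ranks <- function(ranks, genorm = NULL) {
  stopifnot(is.matrix(ranks), ncol(ranks) == 4)
  if (is.null(rownames(ranks))) stop("ranks must carry candidate rownames")
  agg <- exp(rowMeans(log(ranks)))
  tie1 <- if (is.null(genorm)) rep(0, nrow(ranks)) else genorm[rownames(ranks)]
  ord <- order(agg, tie1, rownames(ranks))
  list(aggregate_rank = agg, chosen_pair = rownames(ranks)[ord[1:2]])
}

#' Full candidate-reference stability table
#'
#' Runs the four stability methods on the candidate assays and
#' aggregates their ranks (geometric mean). Per-method ranks use
#' shared-minimum ties.
#'
#' @inheritParams normfinder_stability
#' @return A data frame (class `stability_table`) with one row per
#'   candidate: the four method values, their ranks, and
#'   `aggregate_rank`, ordered by aggregate; the chosen reference pair
#'   is attached as attribute `chosen_pair`.
#' @export
reference_stability <- function(ct, sheet, candidates = NULL) {
  if (is.null(candidates)) candidates <- candidate_references(ct)
  gn <- genorm_m(ct, candidates)
  cd <- comparative_dct_stability(ct, candidates)
  bk <- bestkeeper_stats(ct, candidates)
  nf <- normfinder_stability(ct, sheet, candidates)

  bk_sd <- stats::setNames(bk$sd, bk$candidate)[candidates]
  rk <- cbind(genorm = rank(gn$m[candidates], ties.method = "min"),
              comparative_dct = rank(cd[candidates], ties.method = "min"),
              bestkeeper = rank(bk_sd, ties.method = "min"),
              normfinder = rank(nf$stability[candidates], ties.method = "min"))
  rownames(rk) <- candidates
  agg <- aggregate_ranks(rk, genorm = gn$m)

  out <- data.frame(candidate = candidates,
                    genorm_m = unname(gn$m[candidates]),
                    comparative_dct_sd = unname(cd[candidates]),
                    bestkeeper_sd = unname(bk_sd),
                    bestkeeper_r = bk$r[match(candidates, bk$candidate)],
                    normfinder_stability = unname(nf$stability[candidates]),
                    rank_genorm = rk[, "genorm"],
                    rank_comparative_dct = rk[, "comparative_dct"],
                    rank_bestkeeper = rk[, "bestkeeper"],
                    rank_normfinder = rk[, "normfinder"],
                    aggregate_rank = unname(agg$aggregate_rank[candidates]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aggregate_rank, out$genorm_m, out$candidate), ]
  rownames(out) <- NULL
  attr(out, "chosen_pair") <- agg$chosen_pair
  attr(out, "normfinder_single_group") <- nf$single_group
  class(out) <- c("stability_table", "data.frame")
  out
}
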
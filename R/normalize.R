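# The normalization cascade: detectability filter -> reference Ct ->
# delta-Ct -> global-mean-centered delta-Ct -> signed fold change.

#' Detectability filter
#'
#' Censors undetectable reactions and drops assays that fail panel-wide.
#' A reaction is detectable when its Ct is at most `limit` (inclusive:
#' Ct = 35.0 exactly is retained at the default limit). Ct above the
#' limit and nondetects become missing; an assay missing in more than
#' `max_nondetect_frac` of samples is dropped panel-wide.
#'
#' @param ct A [ct_matrix()].
#' @param limit Detectability limit in Ct units.
#' @param max_nondetect_frac Maximum tolerated fraction of missing
#'   reactions per assay before the assay is dropped.
#' @return List with `ct` (filtered matrix), `dropped_assays`,
#'   `n_censored` (reactions newly set missing), and `report` (per-assay
#'   missing fraction and kept flag).
#' @export
detectability_filter <- function(ct, limit = 35, max_nondetect_frac = 0.5) {
  stopifnot(inherits(ct, "ct_matrix"))
  m <- ct$values
  censor <- !is.na(m) & m > limit
  m[censor] <- NA_real_
  frac <- colMeans(is.na(m))
  keep <- frac <= max_nondetect_frac
  if (!any(keep)) stop("detectability filter dropped every assay (limit = ", limit, ")")
  report <- data.frame(assay = colnames(m), missing_frac = unname(frac),
                       kept = unname(keep), stringsAsFactors = FALSE)
  out <- ct_matrix(m[, keep, drop = FALSE],
                   assay_roles = ct$assay_roles[colnames(m)[keep]])
  list(ct = out, dropped_assays = colnames(m)[!keep],
       n_censored = sum(censor), report = report)
}

#' Per-sample reference Ct
#'
#' The arithmetic mean of the chosen reference assays' Ct values within
#' each sample (for the study pair RNU48 and RNU6B, the average of the
#' two). Samples in which any reference is undetected cannot be
#' normalized and come back as `NA` with a warning; callers drop them.
#'
#' @param ct A [ct_matrix()].
#' @param refs Reference assay ids (typically two).
#' @return Named numeric vector, one reference Ct per sample (`NA` =
#'   sample excluded).
#' @export
reference_ct <- function(ct, refs = c("RNU48", "RNU6B")) {
  stopifnot(inherits(ct, "ct_matrix"))
  miss <- setdiff(refs, assay_ids(ct))
  if (length(miss)) stop("reference assay(s) not in matrix: ", paste(miss, collapse = ", "))
  rm_ <- ct$values[, refs, drop = FALSE]
  bad <- rowSums(is.na(rm_)) > 0
  out <- rowMeans(rm_)
  out[bad] <- NA_real_
  if (any(bad)) {
    warning("reference nondetect; excluding sample(s): ",
            paste(rownames(rm_)[bad], collapse = ", "))
  }
  out
}

#' Delta-Ct: subtract the per-sample reference Ct
#'
#' `dCt(sample, assay) = Ct(sample, assay) - reference_ct(sample)`.
#' Missing Ct stays missing; samples with a missing reference are
#' removed. Adding any constant to all assays of a sample (references
#' included) leaves that sample's delta-Ct unchanged — this is what
#' makes the cascade immune to loading offsets.
#'
#' @param ct A [ct_matrix()].
#' @param ref Per-sample reference values from [reference_ct()] (or a
#'   single assay's Ct in single-reference mode).
#' @return Numeric matrix of delta-Ct values (samples with a defined
#'   reference only).
#' @export
delta_ct <- function(ct, ref) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (is.null(names(ref))) stop("`ref` must be named by sample id")
  miss <- setdiff(sample_ids(ct), names(ref))
  if (length(miss)) stop("reference value missing for sample(s): ", paste(miss, collapse = ", "))
  ref <- ref[sample_ids(ct)]
  keep <- !is.na(ref)
  ct$values[keep, , drop = FALSE] - ref[keep]
}

#' Global-mean centering of delta-Ct values
#'
#' Subtracts, per sample, the mean delta-Ct over the `mean_set` assays
#' (by default every assay of the matrix) from all of that sample's
#' values, so each sample's mean over the mean set is zero. Samples with
#' fewer than `min_frac` of the mean set observed are excluded with a
#' warning rather than centered on too little information.
#'
#' @param dct Delta-Ct matrix from [delta_ct()].
#' @param mean_set Assays defining the per-sample mean; default all
#'   columns of `dct`.
#' @param min_frac Minimum observed fraction of the mean set per sample.
#' @return Object of class `normalized_matrix`: the centered matrix with
#'   attributes `mean_set` and `excluded_samples`.
#' @export
global_mean_normalize <- function(dct, mean_set = NULL, min_frac = 0.8) {
  stopifnot(is.matrix(dct))
  if (is.null(mean_set)) mean_set <- colnames(dct)
  miss <- setdiff(mean_set, colnames(dct))
  if (length(miss)) stop("mean_set assay(s) not present: ", paste(miss, collapse = ", "))
  sub <- dct[, mean_set, drop = FALSE]
  frac <- rowMeans(!is.na(sub))
  keep <- frac >= min_frac
  if (any(!keep)) {
    warning("fewer than ", round(100 * min_frac),
            "% of the global-mean set observed; excluding sample(s): ",
            paste(rownames(dct)[!keep], collapse = ", "))
  }
  centered <- dct[keep, , drop = FALSE] -
    rowMeans(sub[keep, , drop = FALSE], na.rm = TRUE)
  structure(centered, mean_set = mean_set,
            excluded_samples = rownames(dct)[!keep],
            class = c("normalized_matrix", class(centered)))
}

#' Median-based signed fold change between two groups
#'
#' The delta-delta-Ct statistic on (normalized) delta-Ct values:
#' `ddCt = median(case) - median(control)`, `ratio = 2^(-ddCt)`, and the
#' signed fold follows the reciprocal convention (`ratio` if at least 1,
#' otherwise `-1/ratio`), so downregulation is printed as a negative
#' reciprocal (a ratio of 1/8.70 prints as -8.70). Group medians rather
#' than means are used throughout.
#'
#' @param case,control Numeric vectors of (normalized) delta-Ct values
#'   for one miRNA; at least 2 non-missing values per side.
#' @return List with `ddct`, `ratio`, `signed`, `n_case`, `n_control`.
#' @export
signed_fold_change <- function(case, control) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) < 2 || length(control) < 2) {
    stop("signed_fold_change needs >= 2 observations per side")
  }
  ddct <- stats::median(case) - stats::median(control)
  ratio <- 2^(-ddct)
  list(ddct = ddct, ratio = ratio,
       signed = if (ratio >= 1) ratio else -1 / ratio,
       n_case = length(case), n_control = length(control))
}

#' Single-reference delta-Ct mode
#'
#' Normalization against one endogenous control (as for the mRNA branch
#' against 18S ribosomal RNA): `dCt = Ct(target) - Ct(ref)` with no
#' global-mean step. Samples where the reference is undetected are
#' excluded with a warning.
#'
#' @param ct A [ct_matrix()].
#' @param ref Single reference assay id.
#' @return Delta-Ct matrix over the remaining (target) assays.
#' @export
single_reference_mode <- function(ct, ref) {
  stopifnot(length(ref) == 1)
  d <- delta_ct(ct, reference_ct(ct, ref))
  d[, setdiff(colnames(d), ref), drop = FALSE]
}

#' Run the full normalization cascade
#'
#' Detectability filter, reference averaging over the chosen pair,
#' delta-Ct, then global-mean centering over all retained target assays
#' (every retained assay except the chosen references — candidate
#' controls that were not chosen are analyzed as targets).
#'
#' @param ct A [ct_matrix()].
#' @param refs Chosen reference pair.
#' @param limit,max_nondetect_frac Passed to [detectability_filter()].
#' @param mean_set Global-mean set; default all retained targets.
#' @param min_frac Passed to [global_mean_normalize()].
#' @return List with `normalized` (a `normalized_matrix`, reference
#'   assays removed), `filter` (the filter report list), `reference_ct`,
#'   and `refs`.
#' @export
normalize_cohort <- function(ct, refs = c("RNU48", "RNU6B"), limit = 35,
                             max_nondetect_frac = 0.5, mean_set = NULL,
                             min_frac = 0.8) {
  filt <- detectability_filter(ct, limit = limit,
                               max_nondetect_frac = max_nondetect_frac)
  gone <- intersect(refs, filt$dropped_assays)
  if (length(gone)) {
    stop("chosen reference assay(s) failed the detectability filter: ",
         paste(gone, collapse = ", "))
  }
  rc <- reference_ct(filt$ct, refs)
  dct <- delta_ct(filt$ct, rc)
  targets <- setdiff(colnames(dct), refs)
  dct <- dct[, targets, drop = FALSE]
  if (is.null(mean_set)) mean_set <- targets
  norm <- global_mean_normalize(dct, mean_set = mean_set, min_frac = min_frac)
  list(normalized = norm, filter = filt, reference_ct = rc, refs = refs)
}
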
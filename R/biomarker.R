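# ECDF / Kolmogorov-Smirnov-distance cutoff selection and ROC/AUC
# evaluation of a single marker between two groups.

#' Signed KS distance and cutoff between two samples
#'
#' Evaluates `diff(t) = F_case(t) - F_control(t)` (ECDFs, right-
#' continuous, `F(t)` = fraction of values <= t) at every pooled
#' observed value and returns the signed difference of maximum
#' magnitude together with the observed value attaining it (ties in
#' |diff| broken toward the smallest t). D is positive when the case
#' ECDF lies above the control ECDF at the optimum — for delta-Ct data
#' that means cases shifted toward LOWER delta-Ct, i.e. higher
#' expression — giving a score in [-1, 1]. Swapping case and control
#' negates D.
#'
#' @param case,control Numeric vectors, >= 2 non-missing values each.
#' @return List with `D` (signed) and `cutoff` (observed-scale value).
#' @export
ks_cutoff <- function(case, control) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) < 2 || length(control) < 2) {
    stop("ks_cutoff needs >= 2 values per side")
  }
  t <- sort(unique(c(case, control)))
  d <- vapply(t, function(tt) mean(case <= tt) - mean(control <= tt),
              numeric(1))
  i <- which.max(abs(d))  # first index = smallest t on ties
  list(D = d[i], cutoff = t[i])
}

#' Sensitivity and specificity at a cutoff
#'
#' With direction `lower_is_positive` (an upregulated marker has lower
#' delta-Ct in cases): sensitivity is the fraction of case values at or
#' below the cutoff (inclusive on the case side) and specificity the
#' fraction of control values above it. `higher_is_positive` mirrors
#' both comparisons.
#'
#' @param case,control Numeric vectors.
#' @param cutoff Finite classification threshold.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @return List with `sensitivity` and `specificity`.
#' @export
confusion_at_cutoff <- function(case, control, cutoff,
                                direction = c("lower_is_positive",
                                              "higher_is_positive")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(cutoff))
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (direction == "lower_is_positive") {
    list(sensitivity = mean(case <= cutoff),
         specificity = mean(control > cutoff))
  } else {
    list(sensitivity = mean(case >= cutoff),
         specificity = mean(control < cutoff))
  }
}

#' ROC curve and AUC for a single marker
#'
#' Sweeps the classification threshold over all pooled observed values,
#' collecting (1 - specificity, sensitivity) points from (0, 0) to
#' (1, 1), and integrates by the trapezoid rule. The result equals the
#' probability that a random case is more "positive" than a random
#' control plus half the tie probability, i.e. U/(n_case * n_control).
#'
#' @inheritParams confusion_at_cutoff
#' @return List with `auc` and `roc_points` (data frame with columns
#'   `fpr`, `tpr`, `threshold`).
#' @export
auc_eval <- function(case, control,
                     direction = c("lower_is_positive",
                                   "higher_is_positive")) {
  direction <- match.arg(direction)
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) < 1 || length(control) < 1) {
    stop("auc_eval needs >= 1 value per side")
  }
  # orient scores so that larger = more positive
  s_case <- if (direction == "lower_is_positive") -case else case
  s_control <- if (direction == "lower_is_positive") -control else control
  thr <- c(Inf, sort(unique(c(s_case, s_control)), decreasing = TRUE))
  tpr <- vapply(thr, function(tt) mean(s_case >= tt), numeric(1))
  fpr <- vapply(thr, function(tt) mean(s_control >= tt), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  pts <- data.frame(fpr = fpr, tpr = tpr, threshold = thr)
  list(auc = auc, roc_points = pts)
}

#' KS-cutoff biomarker evaluation of one marker
#'
#' Composes [ks_cutoff()], [confusion_at_cutoff()] and [auc_eval()] for
#' one marker between a case and a control group of a normalized
#' cohort. The classification direction is inferred from the sign of
#' the median difference (case median at or below control median means
#' the marker is upregulated in cases and lower delta-Ct is positive).
#' The evaluation is declared significant when |D| > 0.5.
#'
#' @param norm Normalized delta-Ct matrix.
#' @param sheet Sample sheet covering the matrix samples.
#' @param marker Assay id.
#' @param case_group,control_group Group labels.
#' @param direction Optional override of the inferred direction.
#' @return Object of class `ks_evaluation`: a list with `marker`,
#'   `case`, `control`, `direction`, `D`, `cutoff`, `sensitivity`,
#'   `specificity`, `auc`, `roc_points`, `significant`.
#' @export
evaluate_marker <- function(norm, sheet, marker, case_group, control_group,
                            direction = NULL) {
  m <- unclass(norm)
  stopifnot(is.matrix(m))
  if (!marker %in% colnames(m)) stop("marker not in matrix: ", marker)
  sheet <- sheet[match(rownames(m), sheet$sample_id), , drop = FALSE]
  for (gname in c(case_group, control_group)) {
    if (!gname %in% sheet$group) stop("group absent from cohort: ", gname)
  }
  case <- m[sheet$group == case_group, marker]
  control <- m[sheet$group == control_group, marker]
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (!length(case) || !length(control)) {
    stop("marker '", marker, "' has no detected values in one group")
  }
  if (is.null(direction)) {
    direction <- if (stats::median(case) <= stats::median(control)) {
      "lower_is_positive"
    } else {
      "higher_is_positive"
    }
  }
  ks <- ks_cutoff(case, control)
  cf <- confusion_at_cutoff(case, control, ks$cutoff, direction)
  au <- auc_eval(case, control, direction)
  structure(list(marker = marker, case = case_group,
                 control = control_group, direction = direction,
                 D = ks$D, cutoff = ks$cutoff,
                 sensitivity = cf$sensitivity,
                 specificity = cf$specificity,
                 auc = au$auc, roc_points = au$roc_points,
                 significant = abs(ks$D) > 0.5),
            class = "ks_evaluation")
}

#' @export
print.ks_evaluation <- function(x, ...) {
  cat(sprintf(
    "%s, %s vs %s: KS D = %.3f at cutoff %.3f (%s)\n  sensitivity %.3f, specificity %.3f, AUC %.4f, significant (|D| > 0.5): %s\n",
    x$marker, x$case, x$control, x$D, x$cutoff, x$direction,
    x$sensitivity, x$specificity, x$auc, x$significant))
  invisible(x)
}
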
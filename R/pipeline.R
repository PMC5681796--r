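# One-call end-to-end pipeline and the packaged-table reproduction
# report.

.stage <- function(name, expr, log) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full panel analysis end to end
#'
#' Stages, in order: detectability filter, reference selection (the
#' forced pair by default, mirroring the study's final choice of RNU48
#' and RNU6B; stability-driven with `auto_refs = TRUE`), normalization
#' cascade, differential expression, KS/ROC biomarker evaluation,
#' fold-change matrix with hierarchical ordering, and volcano
#' coordinates. Every decision taken (dropped assay, excluded sample,
#' chosen references) is recorded as a machine-parsable `key=value` log
#' line. Given the same inputs the run is deterministic.
#'
#' @param ct A [ct_matrix()].
#' @param sheet Sample sheet data frame.
#' @param refs Forced reference pair (must be in the panel).
#' @param auto_refs When `TRUE`, choose the pair by aggregated
#'   stability rank instead of `refs`.
#' @param limit,max_nondetect_frac Detectability settings.
#' @param comparisons List of `c(case, control)` pairs.
#' @param alpha,q_threshold Significance thresholds.
#' @param markers Assay ids to evaluate as biomarkers (those present
#'   after filtering; each is evaluated for every comparison).
#' @param out_dir Optional directory; when given, result tables are
#'   written there as TSV plus a `run.log`.
#' @return List bundle: `stability` (or `NULL`), `refs`, `filter`,
#'   `normalized`, `de`, `ks` (list of `ks_evaluation`), `fold_matrix`,
#'   `clustering`, `volcano`, `log`.
#' @export
run_pipeline <- function(ct, sheet, refs = c("RNU48", "RNU6B"),
                         auto_refs = FALSE, limit = 35,
                         max_nondetect_frac = 0.5,
                         comparisons = list(c("RA", "HC"), c("FDR", "HC"),
                                            c("FDR", "RA")),
                         alpha = 0.05, q_threshold = 0.04,
                         markers = "hsa-miR-103a-3p", out_dir = NULL) {
  log <- character()
  push <- function(...) log <<- c(log, paste0(...))

  sheet <- .stage("input", align_sheet(ct, sheet))
  for (cmp in comparisons) {
    bad <- setdiff(cmp, unique(sheet$group))
    if (length(bad)) {
      stop("stage 'input' failed: unknown comparison group: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  stability <- NULL
  if (auto_refs) {
    stability <- .stage("stability", reference_stability(ct, sheet))
    refs <- attr(stability, "chosen_pair")
    push("reference_policy=auto")
  } else {
    push("reference_policy=forced")
  }
  push("refs=", paste(refs, collapse = ","))
  bad <- setdiff(refs, assay_ids(ct))
  if (length(bad)) {
    stop("stage 'stability' failed: forced reference pair not in panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  nc <- .stage("normalize",
               normalize_cohort(ct, refs = refs, limit = limit,
                                max_nondetect_frac = max_nondetect_frac))
  for (a in nc$filter$dropped_assays) push("dropped_assay=", a)
  for (s in attr(nc$normalized, "excluded_samples")) push("excluded_sample=", s)
  push("n_censored=", nc$filter$n_censored)
  push("n_targets=", ncol(nc$normalized))

  de <- .stage("de", build_de_table(nc$normalized, sheet,
                                    comparisons = comparisons,
                                    alpha = alpha, q_threshold = q_threshold))

  ks <- list()
  for (mk in markers) {
    if (!mk %in% colnames(nc$normalized)) {
      push("skipped_marker=", mk)
      next
    }
    for (cmp in comparisons) {
      key <- paste0(mk, ":", cmp[1], "_vs_", cmp[2])
      ks[[key]] <- .stage("biomarker",
                          evaluate_marker(nc$normalized, sheet, mk,
                                          cmp[1], cmp[2]))
    }
  }

  fm <- .stage("summarize", build_fold_matrix(de))
  cl <- .stage("summarize", hierarchical_order(fm))
  vc <- .stage("summarize", volcano_coords(de))

  bundle <- list(stability = stability, refs = refs, filter = nc$filter,
                 normalized = nc$normalized, de = de, ks = ks,
                 fold_matrix = fm, clustering = cl, volcano = vc, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(de, file.path(out_dir, "de_table.tsv"))
    nm <- data.frame(sample_id = rownames(nc$normalized),
                     unclass(nc$normalized), check.names = FALSE)
    write_result_table(nm, file.path(out_dir, "normalized_dct.tsv"))
    fmdf <- data.frame(assay = rownames(fm), fm, check.names = FALSE)
    write_result_table(fmdf, file.path(out_dir, "fold_matrix.tsv"))
    write_result_table(vc, file.path(out_dir, "volcano.tsv"))
    if (length(ks)) {
      kdf <- do.call(rbind, lapply(ks, function(k) {
        data.frame(marker = k$marker, case = k$case, control = k$control,
                   direction = k$direction, D = k$D, cutoff = k$cutoff,
                   sensitivity = k$sensitivity, specificity = k$specificity,
                   auc = k$auc, significant = k$significant,
                   stringsAsFactors = FALSE)
      }))
      write_result_table(kdf, file.path(out_dir, "ks_evaluations.tsv"))
    }
    if (!is.null(stability)) {
      write_result_table(as.data.frame(stability),
                         file.path(out_dir, "stability.tsv"))
    }
    writeLines(log, file.path(out_dir, "run.log"))
  }
  bundle
}

#' Reproduction report for the packaged comparison table
#'
#' Recomputes, from the packaged per-miRNA P/fold table: the number of
#' significant miRNAs per comparison at the raw `P < alpha` threshold,
#' the top-ranked (largest signed fold) and most downregulated (most
#' negative signed fold) miRNA per comparison, and a consistency check
#' that no signed fold lies in (-1, 1).
#'
#' @param fixture Data frame from [load_table2_fixture()].
#' @param alpha Raw significance threshold.
#' @return List with `counts` (named per comparison), `top_by_fold`,
#'   `most_downregulated`, `fold_convention_ok`, `n_mirnas`.
#' @export
reproduce_table2 <- function(fixture = load_table2_fixture(), alpha = 0.05) {
  cmps <- fixture_comparisons()
  counts <- vapply(cmps, function(cols) {
    filter_significant(fixture[[cols["p"]]], alpha)$count
  }, numeric(1))
  top <- vapply(cmps, function(cols) {
    fixture$mirna[which.max(fixture[[cols["fold"]]])]
  }, character(1))
  down <- vapply(cmps, function(cols) {
    fixture$mirna[which.min(fixture[[cols["fold"]]])]
  }, character(1))
  folds <- unlist(fixture[, vapply(cmps, `[[`, "", "fold")])
  list(counts = counts, top_by_fold = top, most_downregulated = down,
       fold_convention_ok = all(abs(folds) >= 1), n_mirnas = nrow(fixture))
}
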
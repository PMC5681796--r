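#' Construct a Ct matrix
#'
#' A `ct_matrix` holds raw qRT-PCR cycle-threshold values as a numeric
#' samples-by-assays matrix. Nondetects (reactions that never crossed the
#' fluorescence threshold, reported as "Undetermined" by the instrument)
#' are stored as `NA`; every numeric entry must be a finite, positive
#' cycle number. Each assay carries a role: `"target"` or
#' `"candidate_reference"` (a small RNA evaluated as endogenous control).
#'
#' @param values Numeric matrix, rows = samples, columns = assays; both
#'   dimnames required and unique. `NA` marks a nondetect.
#' @param assay_roles Named character vector mapping assay id to
#'   `"target"` or `"candidate_reference"`. Assays not named default to
#'   `"target"`.
#' @return An object of class `ct_matrix`: a list with elements `values`
#'   and `assay_roles`.
#' @export
ct_matrix <- function(values, assay_roles = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x assays)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample ids as rownames and assay ids as colnames")
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s)) stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  dup_a <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_a)) stop("duplicate assay id(s): ", paste(unique(dup_a), collapse = ", "))
  v <- values[!is.na(values)]
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all numeric Ct values must be finite and > 0 (use NA for nondetects)")
  }
  roles <- rep("target", ncol(values))
  names(roles) <- colnames(values)
  if (!is.null(assay_roles)) {
    bad <- setdiff(names(assay_roles), colnames(values))
    if (length(bad)) stop("assay_roles names not in matrix: ", paste(bad, collapse = ", "))
    ok <- assay_roles %in% c("target", "candidate_reference")
    if (!all(ok)) stop("assay roles must be 'target' or 'candidate_reference'")
    roles[names(assay_roles)] <- assay_roles
  }
  structure(list(values = values, assay_roles = roles), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf(
    "ct_matrix: %d samples x %d assays (%d candidate reference(s), %d nondetect(s))\n",
    nrow(x$values), ncol(x$values),
    sum(x$assay_roles == "candidate_reference"), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
as.matrix.ct_matrix <- function(x, ...) x$values

#' Sample and assay ids of a Ct matrix
#' @param x A `ct_matrix`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
assay_ids <- function(x) colnames(x$values)

#' Candidate reference assays of a Ct matrix
#' @param x A `ct_matrix`.
#' @return Character vector of assay ids with role `candidate_reference`.
#' @export
candidate_references <- function(x) {
  names(x$assay_roles)[x$assay_roles == "candidate_reference"]
}

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.nondetect_sentinels <- c("Undetermined", "undetermined", "NA", "")

#' Read a wide-format Ct table
#'
#' Expects a UTF-8 CSV (`.csv`) or TSV (any other extension) with assay
#' ids in the header row, one row per sample, and sample ids in the first
#' column. Cells reading "Undetermined", "NA", or empty map to nondetect
#' (`NA`); any other non-numeric cell is a hard error reporting its
#' position. Values above the detectability limit are kept numeric:
#' censoring is a pipeline stage (see [detectability_filter()]), not an
#' I/O concern.
#'
#' @param path File path.
#' @param assay_roles Optional role map passed to [ct_matrix()].
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, assay_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("Ct table needs a sample id column plus at least one assay")
  samples <- raw[[1]]
  assays <- colnames(raw)[-1]
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  dup <- assays[duplicated(assays)]
  if (length(dup)) stop("duplicate assay id(s): ", paste(unique(dup), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(assays),
              dimnames = list(samples, assays))
  for (j in seq_along(assays)) {
    cell <- trimws(raw[[j + 1L]])
    nondetect <- cell %in% .nondetect_sentinels
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!nondetect & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric Ct cell '%s' at row %d (sample '%s'), column '%s'",
                   cell[bad[1]], bad[1], samples[bad[1]], assays[j]))
    }
    num[nondetect] <- NA_real_
    m[, j] <- num
  }
  ct_matrix(m, assay_roles = assay_roles)
}

#' Write a Ct table
#'
#' Inverse of [read_ct_table()]: nondetects are written as
#' "Undetermined" and numeric values with 17 significant digits so that a
#' write/read round trip is value-identical.
#'
#' @param x A `ct_matrix`.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  m <- x$values
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m))
  chr[is.na(m)] <- "Undetermined"
  df <- data.frame(sample_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(m))
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with header `sample_id,group[,timepoint]`. Groups are restricted
#' to `groups`; an unknown label or an empty sheet is a hard error.
#'
#' @param path File path.
#' @param groups Allowed group labels.
#' @return A data frame with columns `sample_id`, `group`, and
#'   `timepoint` (NA when absent), in file order.
#' @export
read_sample_sheet <- function(path, groups = c("HC", "RA", "FDR")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("sample_id", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no samples in sample sheet")
  if (!"timepoint" %in% colnames(df)) df$timepoint <- NA_character_
  df <- df[, c("sample_id", "group", "timepoint")]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id(s) in sheet: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$group), groups)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(groups, collapse = ", "), ")")
  }
  df
}

#' Align a sample sheet to a Ct matrix
#'
#' Every sample of the Ct matrix must appear exactly once in the sheet.
#'
#' @param ct A `ct_matrix`.
#' @param sheet Sample sheet data frame.
#' @return The sheet subset to, and ordered as, the Ct matrix samples.
#' @export
align_sheet <- function(ct, sheet) {
  miss <- setdiff(sample_ids(ct), sheet$sample_id)
  if (length(miss)) {
    stop("sample(s) in Ct table missing from sample sheet: ",
         paste(miss, collapse = ", "))
  }
  sheet[match(sample_ids(ct), sheet$sample_id), , drop = FALSE]
}

#' Write / read a result table
#'
#' Tab-separated result tables with value-identical round trip (numeric
#' columns are written with 17 significant digits).
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}
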
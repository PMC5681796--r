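#' Default 35-assay panel
#'
#' The study panel: the 33 detectable miRNAs of the packaged comparison
#' table plus the two small RNAs used as the chosen reference pair
#' (RNU48, RNU6B). Five assays are flagged as candidate endogenous
#' controls (RNU48, RNU6B, RNU44, U6, miR-16); RNU44, U6, and miR-16 are
#' nevertheless analyzed as targets downstream whenever they are not the
#' chosen reference pair, mirroring their presence in the comparison
#' table.
#'
#' @return Data frame with columns `assay` and `role`.
#' @export
default_panel <- function() {
  fix <- load_table2_fixture()
  assay <- c("RNU48", "RNU6B", fix$mirna)
  role <- ifelse(assay %in% c("RNU48", "RNU6B", "RNU44", "U6", "hsa-miR-16"),
                 "candidate_reference", "target")
  data.frame(assay = assay, role = role, stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defines the generative model for a synthetic Ct cohort that emulates
#' the study design: three groups (12 HC, 18 RA, 12 FDR), a 35-assay
#' panel, a per-sample loading offset shared across all assays of a
#' sample (modeling RNA input / RT-efficiency variation, which reference
#' subtraction and global-mean centering are designed to remove), and
#' Gaussian technical noise per reaction.
#'
#' The observation model for sample s in group g and assay a is
#' `Ct = baseline_ct(a) - group_effects(a, g) + offset(s) + noise`,
#' with `offset ~ N(0, sample_offset_sd)` and `noise ~ N(0, noise_sd)`.
#' Group effects are log2 expression shifts relative to HC; one PCR
#' cycle equals one log2 unit, and Ct moves opposite to expression, so a
#' positive shift (higher expression) lowers Ct.
#'
#' @param group_sizes Named integer vector of samples per group.
#' @param panel Data frame with columns `assay`, `role` ([default_panel()]).
#' @param baseline_ct Optional named numeric vector of per-assay mean Ct
#'   in HC; when `NULL`, drawn once from Uniform(18, 32) under the seed.
#' @param group_effects Optional assays-by-groups numeric matrix of log2
#'   expression shifts relative to HC (see [effects_from_fixture()]);
#'   missing assays or groups default to 0. Reference assays are assumed
#'   stable: leave their rows at 0 unless deliberately overridden.
#' @param sample_offset_sd SD of the per-sample loading offset, Ct units.
#' @param noise_sd SD of per-reaction technical noise, Ct units.
#' @param nondetect_ct Detectability limit in Ct units; the generator
#'   emits values above it as numeric (censoring is applied downstream by
#'   [detectability_filter()] so tests can toggle it independently).
#' @param undetectable_assays Assays forced above the detectability
#'   limit in every sample (emulating panel members that never amplify).
#' @param seed Integer seed; identical configuration and seed give an
#'   identical cohort.
#' @return A `synth_config` list.
#' @export
synth_config <- function(group_sizes = c(HC = 12L, RA = 18L, FDR = 12L),
                         panel = default_panel(),
                         baseline_ct = NULL,
                         group_effects = NULL,
                         sample_offset_sd = 0.8,
                         noise_sd = 0.25,
                         nondetect_ct = 35,
                         undetectable_assays = character(),
                         seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector")
  }
  if (any(group_sizes < 2)) stop("each group needs at least 2 samples")
  if (sample_offset_sd < 0 || noise_sd < 0) stop("SDs must be >= 0")
  stopifnot(all(c("assay", "role") %in% colnames(panel)))
  if (anyDuplicated(panel$assay)) stop("duplicate assay in panel")
  if (!is.null(group_effects)) {
    if (is.null(rownames(group_effects)) || is.null(colnames(group_effects))) {
      stop("group_effects must have assay rownames and group colnames")
    }
    bad <- setdiff(colnames(group_effects), names(group_sizes))
    if (length(bad)) stop("unknown group(s) in group_effects: ", paste(bad, collapse = ", "))
    bad <- setdiff(rownames(group_effects), panel$assay)
    if (length(bad)) stop("unknown assay(s) in group_effects: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(undetectable_assays, panel$assay)
  if (length(bad)) stop("undetectable_assays not in panel: ", paste(bad, collapse = ", "))
  structure(list(group_sizes = group_sizes, panel = panel,
                 baseline_ct = baseline_ct, group_effects = group_effects,
                 sample_offset_sd = sample_offset_sd, noise_sd = noise_sd,
                 nondetect_ct = nondetect_ct,
                 undetectable_assays = undetectable_assays,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic Ct cohort
#'
#' Draws a cohort under the model described in [synth_config()]. Values
#' above the detectability limit are emitted as numeric Ct; downstream
#' censoring is the job of [detectability_filter()].
#'
#' @param config A [synth_config()].
#' @return List with elements `ct` (a [ct_matrix()]) and `sheet` (a
#'   sample sheet data frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    assays <- config$panel$assay
    groups <- names(config$group_sizes)
    n <- sum(config$group_sizes)

    baseline <- config$baseline_ct
    if (is.null(baseline)) {
      baseline <- stats::runif(length(assays), 18, 32)
      names(baseline) <- assays
    } else {
      miss <- setdiff(assays, names(baseline))
      if (length(miss)) stop("baseline_ct missing assay(s): ", paste(miss, collapse = ", "))
      baseline <- baseline[assays]
    }
    # park non-amplifying assays just above the censoring threshold
    if (length(config$undetectable_assays)) {
      k <- length(config$undetectable_assays)
      baseline[config$undetectable_assays] <-
        config$nondetect_ct + stats::runif(k, 1, 3)
    }

    eff <- matrix(0, nrow = length(assays), ncol = length(groups),
                  dimnames = list(assays, groups))
    if (!is.null(config$group_effects)) {
      ge <- config$group_effects
      eff[rownames(ge), colnames(ge)] <- ge
    }

    sample_id <- unlist(lapply(groups, function(g) {
      sprintf("%s%02d", g, seq_len(config$group_sizes[[g]]))
    }))
    group <- rep(groups, times = config$group_sizes)
    offset <- stats::rnorm(n, 0, config$sample_offset_sd)
    noise <- matrix(stats::rnorm(n * length(assays), 0, config$noise_sd),
                    nrow = n)

    m <- matrix(baseline, nrow = n, ncol = length(assays), byrow = TRUE) -
      t(eff[, group, drop = FALSE]) + offset + noise
    dimnames(m) <- list(sample_id, assays)

    roles <- config$panel$role
    names(roles) <- assays
    list(ct = ct_matrix(m, assay_roles = roles),
         sheet = data.frame(sample_id = sample_id, group = group,
                            timepoint = NA_character_,
                            stringsAsFactors = FALSE))
  })
}

#' Convert printed signed folds to log2 group effects
#'
#' Each signed fold f of the packaged comparison table becomes the log2
#' expression shift `log2(f)` when `f >= 1` and `-log2(-f)` when
#' `f <= -1`, applied to the RA and FDR groups relative to HC (the
#' respective "vs HC" columns). A fold in the open interval (-1, 1)
#' violates the reciprocal sign convention and is a hard error.
#'
#' @param fixture Data frame from [load_table2_fixture()].
#' @return Numeric matrix, rows = the fixture's miRNAs (printed names),
#'   columns `RA` and `FDR`, entries in log2 units.
#' @export
effects_from_fixture <- function(fixture = load_table2_fixture()) {
  eff <- cbind(RA = signed_to_log2(fixture$fold_ra_hc),
               FDR = signed_to_log2(fixture$fold_fdr_hc))
  rownames(eff) <- fixture$mirna
  eff
}

#' Convert between signed folds and log2 ratios
#'
#' `signed_to_log2()` maps a signed fold (reciprocal convention) to a
#' log2 ratio; `log2_to_signed()` is its inverse.
#'
#' @param f Signed fold values (no entry in (-1, 1)).
#' @param x Log2 ratios.
#' @return Numeric vector.
#' @export
signed_to_log2 <- function(f) {
  if (any(abs(f) < 1, na.rm = TRUE)) {
    stop("signed fold in (-1, 1) violates the reciprocal convention")
  }
  ifelse(f >= 1, log2(pmax(f, 1)), -log2(pmax(-f, 1)))
}

#' @rdname signed_to_log2
#' @export
log2_to_signed <- function(x) {
  r <- 2^x
  ifelse(r >= 1, r, -1 / r)
}
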
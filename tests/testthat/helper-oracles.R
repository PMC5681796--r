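# Independent oracles and small fixture builders used across tests.
# The oracles are deliberately brute-force re-derivations of the
# definitions; they never call the implementation paths they check.

# Two-sided Mann-Whitney P by full enumeration of all C(m+n, m)
# assignments of the pooled values to the first sample, using the
# symmetric "at least as extreme |U - mn/2|" criterion.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  n <- length(y)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  mu <- m * n / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Benjamini-Hochberg step-up from the definition: sort ascending,
# q_(i) = min_{j >= i} p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Classical two-sample KS statistic: brute-force max |F1 - F2| over all
# pooled observed values.
ks_oracle <- function(a, b) {
  t <- sort(unique(c(a, b)))
  max(abs(vapply(t, function(tt) mean(a <= tt) - mean(b <= tt), numeric(1))))
}

# Tiny Ct matrix builder: `...` are named per-assay value vectors.
make_ct <- function(..., roles = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  ct_matrix(m, assay_roles = roles)
}

# Two-group sheet helper.
make_sheet <- function(ids, groups) {
  data.frame(sample_id = ids, group = groups, timepoint = NA_character_,
             stringsAsFactors = FALSE)
}

# Small balanced-effect configuration: log2 shifts that sum to zero
# across the 33-target mean set, so global-mean centering does not bias
# the recovered folds (the regime global-mean normalization assumes).
balanced_effects <- function() {
  eff <- matrix(0, nrow = 6, ncol = 2,
                dimnames = list(c("hsa-miR-103a-3p", "hsa-miR-155",
                                  "hsa-miR-132", "hsa-miR-346",
                                  "hsa-miR-16", "hsa-miR-21"),
                                c("RA", "FDR")))
  eff[, "RA"] <- c(3, 2, 1, -3, -2, -1)
  eff[, "FDR"] <- c(2, 1, 3, -2, -3, -1)
  eff
}
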
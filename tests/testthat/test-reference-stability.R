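# Toy candidates used throughout: A and B differ by a constant (their
# pairwise difference has zero SD); C breaks the pattern.
toy_ct <- function() {
  make_ct(A = c(20, 21, 22, 23),
          B = c(20.5, 21.5, 22.5, 23.5),
          C = c(20, 22, 21, 23),
          roles = c(A = "candidate_reference", B = "candidate_reference",
                    C = "candidate_reference"))
}

test_that("geNorm M matches the pairwise-difference definition and eliminates the outlier", {
  gn <- genorm_m(toy_ct())
  sd_ac <- sd(c(0, -1, 1, 0))  # 0.8165
  expect_equal(unname(gn$m["A"]), sd_ac / 2, tolerance = 1e-12)
  expect_equal(unname(gn$m["B"]), sd_ac / 2, tolerance = 1e-12)
  expect_equal(unname(gn$m["C"]), sd_ac, tolerance = 1e-12)
  expect_identical(gn$elimination, "C")
  expect_setequal(gn$final_pair, c("A", "B"))
})

test_that("geNorm M equals a brute-force recomputation on random candidate sets", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    n <- sample(4:10, 1)
    m <- matrix(rnorm(n * k, 25, 2), nrow = n,
                dimnames = list(paste0("S", 1:n), paste0("G", 1:k)))
    ct <- ct_matrix(m, assay_roles = setNames(rep("candidate_reference", k),
                                              colnames(m)))
    gn <- genorm_m(ct)
    brute <- sapply(colnames(m), function(j) {
      mean(sapply(setdiff(colnames(m), j),
                  function(kk) sd(m[, j] - m[, kk])))
    })
    expect_equal(gn$m, brute, tolerance = 1e-12)
  }
})

test_that("an identical pair survives geNorm elimination", {
  ct <- make_ct(A = c(20, 21, 22, 23), A2 = c(20, 21, 22, 23),
                C = c(19, 23, 20, 24))
  gn <- genorm_m(ct, candidates = c("A", "A2", "C"))
  expect_setequal(gn$final_pair, c("A", "A2"))
})

test_that("comparative delta-Ct stability is the mean pairwise difference SD", {
  cd <- comparative_dct_stability(toy_ct())
  expect_equal(unname(cd["A"]), sd(c(0, -1, 1, 0)) / 2, tolerance = 1e-12)

  # all candidates identical up to a constant: all values zero
  ct <- make_ct(A = c(20, 21, 22, 23), B = c(21, 22, 23, 24),
                C = c(19, 20, 21, 22))
  expect_equal(unname(comparative_dct_stability(ct, c("A", "B", "C"))),
               rep(0, 3), tolerance = 1e-12)

  # with exactly two candidates each value is the SD of their difference
  ct2 <- make_ct(A = c(20, 21, 22, 23), B = c(20, 23, 21, 25))
  cd2 <- comparative_dct_stability(ct2, c("A", "B"))
  expect_equal(unname(cd2), rep(sd(c(0, -2, 1, -2)), 2), tolerance = 1e-12)
})

test_that("BestKeeper descriptors: SD, index correlation, degenerate candidate", {
  bk <- bestkeeper_stats(toy_ct())
  expect_equal(bk$sd[bk$candidate == "A"], sd(20:23), tolerance = 1e-12)

  # candidate equal to the index correlates perfectly
  ct <- make_ct(A = c(20, 21, 22, 23), B = c(19, 20, 21, 22),
                C = c(21, 22, 23, 24))
  bk <- bestkeeper_stats(ct, c("A", "B", "C"))
  expect_equal(bk$r, rep(1, 3), tolerance = 1e-12)

  # constant candidate: sd 0, r missing, ranked best by sd
  ct <- make_ct(A = rep(21, 4), B = c(19, 20, 21, 22), C = c(21, 23, 22, 25))
  bk <- bestkeeper_stats(ct, c("A", "B", "C"))
  expect_identical(bk$sd[bk$candidate == "A"], 0)
  expect_true(is.na(bk$r[bk$candidate == "A"]))
})

test_that("NormFinder: degenerate and shifted candidates behave as the model predicts", {
  sheet <- make_sheet(paste0("S", 1:8), rep(c("g1", "g2"), each = 4))

  # all-constant panel: perfect stability for everyone
  ct <- make_ct(A = rep(20, 8), B = rep(22, 8), C = rep(25, 8))
  nf <- normfinder_stability(ct, sheet, c("A", "B", "C"))
  expect_equal(unname(nf$stability), rep(0, 3), tolerance = 1e-12)
  expect_false(nf$single_group)

  # one candidate given a +1 Ct group shift ranks worst
  set.seed(7)
  base <- matrix(rnorm(8 * 3, 25, 0.1), nrow = 8,
                 dimnames = list(paste0("S", 1:8), c("A", "B", "C")))
  base[5:8, "C"] <- base[5:8, "C"] + 1
  ct <- ct_matrix(base, assay_roles = setNames(rep("candidate_reference", 3),
                                               colnames(base)))
  nf <- normfinder_stability(ct, sheet, c("A", "B", "C"))
  expect_identical(names(which.max(nf$stability)), "C")

  # relabeling the groups leaves the stability values unchanged
  sheet2 <- make_sheet(paste0("S", 1:8), rep(c("g2", "g1"), each = 4))
  nf2 <- normfinder_stability(ct, sheet2, c("A", "B", "C"))
  expect_equal(unname(nf$stability), unname(nf2$stability), tolerance = 1e-12)

  # single group falls back to the intragroup-only variant, flagged
  one <- make_sheet(paste0("S", 1:8), rep("g1", 8))
  nf1 <- normfinder_stability(ct, one, c("A", "B", "C"))
  expect_true(nf1$single_group)
  expect_identical(names(which.max(nf1$stability)), "C")
})

test_that("rank aggregation is the geometric mean with documented tie-breaking", {
  rk <- rbind(W = c(1, 2, 1, 4), X = c(2, 1, 2, 1), Y = c(3, 3, 3, 2),
              Z = c(4, 4, 4, 3))
  agg <- aggregate_ranks(rk)
  expect_equal(unname(agg$aggregate_rank["W"]), 8^(1 / 4), tolerance = 1e-12)
  expect_setequal(agg$chosen_pair, c("W", "X"))

  # unanimous winner aggregates to exactly 1
  rk["X", ] <- c(1, 1, 1, 1)
  expect_equal(unname(aggregate_ranks(rk)$aggregate_rank["X"]), 1)

  # aggregate ties break by geNorm M, then name
  rk2 <- rbind(P = c(1, 2, 1, 2), Q = c(2, 1, 2, 1), R = c(3, 3, 3, 3))
  agg2 <- aggregate_ranks(rk2, genorm = c(P = 0.5, Q = 0.2, R = 0.9))
  expect_identical(agg2$chosen_pair, c("Q", "P"))
})

test_that("stability values are invariant to per-sample constants and preconditions hold", {
  ct <- toy_ct()
  shift <- c(1.3, -0.7, 2.1, 0.4)
  ct2 <- ct_matrix(ct$values + shift, assay_roles = ct$assay_roles)
  expect_equal(genorm_m(ct2)$m, genorm_m(ct)$m, tolerance = 1e-12)
  expect_equal(comparative_dct_stability(ct2), comparative_dct_stability(ct),
               tolerance = 1e-12)

  # nondetect among candidates is a hard error pointing upstream
  v <- ct$values; v[1, "A"] <- NA
  ctna <- ct_matrix(v, assay_roles = ct$assay_roles)
  expect_error(genorm_m(ctna), "nondetect.*upstream|impute")

  # fewer than 4 samples refused
  small <- make_ct(A = c(20, 21, 22), B = c(21, 22, 23), C = c(19, 25, 21))
  expect_error(genorm_m(small, c("A", "B", "C")), "fewer than 4")
})

test_that("a group-shifted candidate gets the worst aggregate rank on synthetic cohorts", {
  # RNU44 given a strong FDR shift while true references stay flat
  eff <- matrix(2.5, 1, 1, dimnames = list("RNU44", "FDR"))
  worst <- character(10)
  for (seed in 1:10) {
    coh <- generate_cohort(synth_config(group_effects = eff, seed = seed))
    st <- reference_stability(coh$ct, coh$sheet)
    worst[seed] <- st$candidate[which.max(st$aggregate_rank)]
  }
  expect_gte(mean(worst == "RNU44"), 0.9)
})
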
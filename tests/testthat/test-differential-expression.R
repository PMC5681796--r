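test_that("Mann-Whitney exact branch matches the enumeration oracle on worked cases", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  expect_equal(mw$p, mw_enum_oracle(c(1, 2), c(3, 4)), tolerance = 1e-12)

  mw <- mann_whitney(c(1, 3), c(2, 4))
  expect_equal(mw$p, 4 / 6, tolerance = 1e-12)
  expect_equal(mw$p, mw_enum_oracle(c(1, 3), c(2, 4)), tolerance = 1e-12)

  # identical multisets: P = 1 by convention
  expect_identical(mann_whitney(c(5, 5, 7), c(5, 7, 5))$p, 1)
  expect_error(mann_whitney(1, c(2, 3)), ">= 2")
})

test_that("Mann-Whitney exact P equals full enumeration for all sizes up to 6", {
  set.seed(101)
  for (rep in 1:200) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    x <- round(rnorm(nx), 3)
    y <- round(rnorm(ny, 0.5), 3)
    if (anyDuplicated(c(x, y))) next  # ties route to the approximate branch
    expect_equal(mann_whitney(x, y)$p, mw_enum_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05),
               tolerance = 1e-12)
  expect_identical(bh_adjust(0.123), 0.123)  # single P unchanged
  expect_error(bh_adjust(c(0, 0.5)), "\\(0, 1\\]")

  set.seed(7)
  for (rep in 1:50) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("significance filtering reproduces the printed per-comparison counts", {
  fix <- load_table2_fixture()
  expect_identical(filter_significant(fix$p_ra_hc, 0.05)$count, 13L)
  expect_identical(filter_significant(fix$p_fdr_hc, 0.05)$count, 10L)
  expect_identical(filter_significant(fix$p_fdr_ra, 0.05)$count, 3L)
  expect_identical(filter_significant(numeric(0), 0.05)$count, 0L)
})

test_that("Kruskal-Wallis H and Dunn's z follow the rank formulas", {
  kd <- kruskal_dunn(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(kd$H, 12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2),
               tolerance = 1e-6)
  expect_equal(kd$H, 4.5714, tolerance = 1e-4)
  expect_identical(nrow(kd$pairwise), 3L)

  # three identical groups: degenerate, H = 0
  kd0 <- kruskal_dunn(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_identical(kd0$H, 0)
  expect_identical(kd0$p, 1)

  # Dunn z against the direct pooled-rank formula (no ties)
  g <- list(a = c(1, 4, 9), b = c(2, 6, 8), c = c(3, 5, 7))
  kd <- kruskal_dunn(g)
  r <- rank(unlist(g))
  mr <- tapply(r, rep(names(g), lengths(g)), mean)
  z_ab <- (mr[["a"]] - mr[["b"]]) / sqrt((9 * 10 / 12) * (1 / 3 + 1 / 3))
  row_ab <- kd$pairwise[kd$pairwise$group1 == "a" & kd$pairwise$group2 == "b", ]
  expect_equal(row_ab$z, z_ab, tolerance = 1e-12)
  expect_equal(row_ab$p, 2 * pnorm(-abs(z_ab)), tolerance = 1e-12)

  expect_error(kruskal_dunn(list(a = 1:2, b = 3:4)), "mann_whitney")
})

test_that("Spearman correlation handles monotone, tied, and degenerate input", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1, tolerance = 1e-12)
  # classic d^2 formula: ranks (1,2,3,4) vs (2,1,4,3) -> 1 - 24/60
  expect_equal(spearman_cor(c(10, 20, 30, 40), c(15, 5, 40, 30))$rho, 0.6,
               tolerance = 1e-12)
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(2, 5, 3))$rho))
  expect_error(spearman_cor(1:2, 1:2), ">= 3")
})

test_that("the DE table composes tests, BH family per comparison, and fold ranks", {
  eff <- balanced_effects()
  coh <- generate_cohort(synth_config(group_effects = eff, seed = 31L))
  nc <- normalize_cohort(coh$ct)
  de <- build_de_table(nc$normalized, coh$sheet)

  expect_identical(nrow(de), 33L * 3L)
  # Q is BH within each comparison's 33-test family
  for (cc in unique(de$comparison)) {
    sub <- de[de$comparison == cc, ]
    expect_equal(sub$Q, bh_oracle(sub$P), tolerance = 1e-12)
    expect_true(all(sub$Q >= sub$P - 1e-12))
    # ranks: shared-minimum permutation of 1..33 by descending fold
    expect_identical(sort(unique(sub$rank)), sort(unique(rank(-sub$fold,
                     ties.method = "min"))))
    expect_identical(sub$assay[sub$rank == 1],
                     sub$assay[which.max(sub$fold)])
  }
  # the strongest injected upregulation tops the RA-vs-HC fold ranking
  ra <- de[de$comparison == "RA_vs_HC", ]
  expect_identical(ra$assay[1], "hsa-miR-103a-3p")

  # row content is invariant to sample and assay order
  perm_s <- sample(nrow(coh$ct$values))
  perm_a <- sample(ncol(nc$normalized))
  norm2 <- unclass(nc$normalized)[perm_s, perm_a]
  de2 <- build_de_table(norm2, coh$sheet)
  key <- function(d) d[order(d$comparison, d$assay),
                       c("assay", "comparison", "U", "P", "Q", "fold", "rank")]
  expect_equal(key(de2), key(de), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(build_de_table(nc$normalized, coh$sheet,
                              comparisons = list(c("XX", "HC"))),
               "group absent.*XX")
})

test_that("a single-assay family has Q equal to P", {
  coh <- generate_cohort(synth_config(seed = 5L))
  nc <- normalize_cohort(coh$ct)
  one <- unclass(nc$normalized)[, "hsa-miR-155", drop = FALSE]
  de <- build_de_table(one, coh$sheet, comparisons = list(c("RA", "HC")))
  expect_identical(de$Q, de$P)
})

test_that("AUC equals the rescaled Mann-Whitney statistic across random samples", {
  set.seed(55)
  for (rep in 1:25) {
    case <- rnorm(sample(3:12, 1))
    control <- rnorm(sample(3:12, 1), 0.8)
    au <- auc_eval(case, control, "lower_is_positive")$auc
    u_control <- mann_whitney(control, case)$U  # pairs with control > case
    expect_equal(au, u_control / (length(case) * length(control)),
                 tolerance = 1e-12)
  }
})
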
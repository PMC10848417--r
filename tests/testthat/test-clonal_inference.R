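test_that("subclone strata follow the CCF/VAF definitions", {
  cls <- classify_subclone(vaf = c(0.40, 0.05, 0.20, 0.30),
                           ccf = c(0.96, 0.15, 0.40, 0.30),
                           called = c(TRUE, TRUE, TRUE, FALSE),
                           min_ccf = 0.02)
  expect_equal(cls$stratum, c("major", "rare", "minor", "undetected"))
  expect_equal(cls$min_ccf[4], 0.02)
  # VAF-based rare rule wins over the CCF-based major rule, flagged
  conf <- classify_subclone(0.08, 0.55, TRUE)
  expect_equal(conf$stratum, "rare")
  expect_true(conf$rare_major_conflict)
})

test_that("metastasis-specific detection excludes low coverage and
          attaches detection power", {
  met <- data.frame(mutation_id = c("m1", "m2", "m3", "m4"),
                    chrom = "chr1", pos = c(100, 200, 300, 400),
                    ref = "C", alt = "T", stringsAsFactors = FALSE)
  prim <- data.frame(
    patient_id = "P1", sample_id = "S", chrom = "chr1",
    pos = c(100, 200, 300), ref = "C", alt = "T",
    mt_alt = c(25, 0, 3), mt_total = c(1200, 2000, 80),
    called = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  prim$vaf <- prim$mt_alt / prim$mt_total
  out <- detect_metspec_in_primary(met, prim, purity = 0.7)
  pm <- out$per_mutation
  expect_equal(pm$stratum, c("rare", "undetected", "excluded", "excluded"))
  expect_match(pm$reason[3], "below floor")
  expect_match(pm$reason[4], "absent")
  expect_equal(pm$min_ccf[2], min_detectable_ccf(2000, 0.7, 2))
  expect_equal(out$summary$n_assayed, 2)
  expect_equal(out$summary$undetected_fraction, 0.5)
  # a primary call at VAF ~0.021 is a rare-subclone detection
  expect_equal(pm$vaf[1], 25 / 1200, tolerance = 1e-12)
})

test_that("pigeonhole test handles point masses and refuses ambiguity", {
  expect_equal(pigeonhole_sum_test(0.65, 0.81, n_draws = 1e4)$p, 0)
  expect_equal(pigeonhole_sum_test(0.3, 0.3, n_draws = 1e4)$p_mc, 1)
  amb <- ccf_estimate(100, 1000, 0.7, major_cn = 2, minor_cn = 1,
                      n_draws = 100)
  expect_error(pigeonhole_sum_test(amb, 0.5, n_draws = 100), "ambiguous")
})

test_that("Monte-Carlo tail matches the closed-form normal sum", {
  set.seed(4)
  a <- rnorm(2e5, 0.65, 0.05)
  b <- rnorm(2e5, 0.45, 0.05)
  res <- pigeonhole_sum_test(a, b, n_draws = 2e5, seed = 9)
  exact <- pnorm(1, 0.65 + 0.45, sqrt(2) * 0.05)
  se <- sqrt(exact * (1 - exact) / 2e5)
  expect_lt(abs(res$p_mc - exact), 3 * se + 2e-3)
  expect_equal(res$p_gaussian, exact, tolerance = 0.02)
})

test_that("pigeonhole p decreases as posterior means grow", {
  means <- c(0.3, 0.45, 0.55, 0.7)
  ps <- vapply(means, function(m) {
    set.seed(1)
    pigeonhole_sum_test(rnorm(5e4, m, 0.05), rnorm(5e4, 0.5, 0.05),
                        n_draws = 5e4, seed = 2)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("sequential lineage set collects CCF > 0.5 mutations", {
  s <- sequential_lineage_set(c(a = 0.9, b = 0.6, c = 0.3))
  expect_equal(s$ids, c("a", "b"))
  expect_equal(s$k, 2)
  expect_equal(sequential_lineage_set(c(0.2, 0.4))$k, 0)
})

test_that("nested-subclone bound is the min and idempotent", {
  b <- nested_subclone_upper_bound(0.19, c(0.05, 0.01, 0.03))
  expect_equal(b$bound, 0.01)            # detection-limited (printed 1%)
  expect_equal(b$limited_by, "detection")
  expect_equal(nested_subclone_upper_bound(0.005, c(0.01, 0.02))$bound,
               0.005)                    # ancestral-limited
  expect_equal(nested_subclone_upper_bound(b$bound, c(0.05, 0.01))$bound,
               b$bound)                  # idempotent
  expect_equal(nested_subclone_upper_bound(0.1, numeric(0))$limited_by,
               "ancestral_only")
})

test_that("metspec:truncal sequential ratio counts above threshold", {
  cls <- c(rep("metspec_driver", 4), rep("metspec_other", 3),
           rep("truncal", 3))
  ccf <- c(0.9, 0.8, 0.7, 0.3, 0.6, 0.55, 0.2, 1, 1, 0.4)
  r <- metspec_truncal_ratio(cls, ccf)
  expect_equal(r$ratio, 5 / 2)
  r0 <- metspec_truncal_ratio(c("metspec_other"), c(0.9))
  expect_true(r0$undefined)
})

test_that("clustered fraction matches trivial cases and Poisson spacing", {
  expect_equal(clustered_mutation_fraction(c("chr1", "chr1"),
                                           c(1000, 1500)), 1)
  expect_equal(clustered_mutation_fraction(c("chr1", "chr2"),
                                           c(1000, 1500)), 0)
  # uniform positions at low density: P(neighbor within w) ~
  # 1 - exp(-2 * density * w)
  set.seed(8)
  n <- 4000; L <- 2e8; w <- 1000
  frac <- clustered_mutation_fraction(rep("chr1", n),
                                      sample.int(L, n), w)
  expected <- 1 - exp(-2 * (n / L) * w)
  expect_equal(frac, expected, tolerance = 0.25)
})
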
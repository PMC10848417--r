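test_that("same seed gives identical cohorts", {
  a <- simulate_cohort(sim_config(n_patients = 3, seed = 5))
  b <- simulate_cohort(sim_config(n_patients = 3, seed = 5))
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sim_config(n_patients = 3, seed = 6))
  expect_false(identical(a$variants, c2$variants))
})

test_that("clonal heterozygous mutations sample around VAF 0.5", {
  cfg <- sim_config(n_patients = 6, purity_range = c(1, 1),
                    mean_metspec = 1, frac_predissemination = 0,
                    n_truncal = 8, artifact_ct_rate = 0,
                    background_rate = 0, seed = 9)
  co <- simulate_cohort(cfg)
  tr <- co$variants[co$variants$mutation_class == "truncal", ]
  expect_equal(ccf_to_vaf(1, 1, 2), 0.5)
  # binomial sampling noise around 0.5 at these depths
  se <- sqrt(sum(0.25 / tr$mt_total)) / nrow(tr)
  expect_lt(abs(mean(tr$vaf) - 0.5), 4 * se)
  expect_true(all(tr$called))
})

test_that("rare subclones near the detection limit behave as the power
          model predicts", {
  # a CCF-0.02 subclone (the smallest detected in practice) is reliably
  # called only when depth comfortably exceeds the implied minimum
  pur <- 0.8; ccf <- 0.02
  vaf <- ccf_to_vaf(ccf, pur, 2)
  depth_needed <- min(which(vapply(200:6000, function(n)
    !is.na(mv <- min_detectable_vaf(n, 8)) && mv <= vaf,
    logical(1)))) + 199
  set.seed(2)
  det_hi <- mean(rbinom(3000, depth_needed * 2, vaf) >= 8)
  det_lo <- mean(rbinom(3000, round(depth_needed / 4), vaf) >= 8)
  expect_gt(det_hi, 0.95)
  expect_lt(det_lo, 0.95)
})

test_that("ground truth joins losslessly and respects configured counts", {
  co <- shared_cohort()
  gt <- ground_truth_report(co)
  # every non-background variant row joins to exactly one truth row
  mut_rows <- co$variants[co$variants$mutation_class != "background", ]
  expect_true(all(mut_rows$mutation_id %in% gt$mutation_id))
  expect_equal(anyDuplicated(gt$mutation_id), 0)
  # per patient: truncal count as configured, >= 1 metspec
  tr_counts <- table(gt$patient_id[gt$mutation_class == "truncal"])
  expect_true(all(tr_counts == co$config$n_truncal))
  ms <- gt[startsWith(gt$mutation_class, "metspec"), ]
  expect_true(all(table(ms$patient_id) >= 1))
  # no artifact row is labeled as a somatic target mutation
  expect_true(all(gt$mutation_class[gt$artifact] == "background"))
  # post-dissemination mutations have true primary CCF zero
  expect_true(all(ms$true_ccf_primary[!ms$pre_dissemination] == 0))
  expect_true(all(ms$true_ccf_primary[ms$pre_dissemination] > 0))
})

test_that("UDG efficiency 1 leaves treated samples artifact-free and
          rate 0 injects nothing", {
  cfg1 <- sim_config(n_patients = 4, artifact_ct_rate = 0.05,
                     udg_efficiency = 1, background_rate = 0, seed = 3)
  co1 <- simulate_cohort(cfg1)
  gt1 <- ground_truth_report(co1)
  treated <- co1$samples$sample_id[co1$samples$udg_treated]
  art <- co1$variants$mutation_id[co1$variants$mutation_class ==
                                    "background"]
  art_samples <- co1$variants$sample_id[co1$variants$mutation_id %in%
                                          art]
  expect_false(any(art_samples %in% treated))
  expect_gt(sum(gt1$artifact), 0)        # untreated replicates got some
  cfg0 <- sim_config(n_patients = 4, artifact_ct_rate = 0,
                     background_rate = 0, seed = 3)
  co0 <- simulate_cohort(cfg0)
  expect_equal(sum(ground_truth_report(co0)$artifact), 0)
})

test_that("MT depth distribution echoes the stated panel scale", {
  co <- shared_cohort()
  d <- co$variants$mt_total
  expect_gt(median(d), 700)
  expect_lt(median(d), 1800)
  expect_true(all(d >= 100 & d <= 6000))
})

test_that("WES resampling of panel mutations runs at 50x", {
  co <- shared_cohort()
  w <- co$wes[[1]]$panel
  expect_true(all(w$wes_depth == 50))
  expect_true(all(w$wes_alt <= 50))
})
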
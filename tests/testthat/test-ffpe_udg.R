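test_that("rare-subclonal burden counts strictly below the VAF ceiling", {
  ctx_sites <- rep(c("ACA", "ACG"), 500)          # 1000 covered C sites
  v <- make_variants(3, vaf = 0.02,
                     context = canonical_context("ACA", "C", "T"))
  b <- rare_subclonal_burden(v, ctx_sites)
  expect_equal(b$n_rare, 3)
  expect_equal(b$panel_rate, 0.003)
  ct <- b$per_class[b$per_class$class == "A[C>T]A", ]
  expect_equal(ct$rate, 3 / 500)
  # boundary: vaf exactly at the ceiling is excluded
  v10 <- make_variants(1, vaf = 0.10, context = "A[C>T]A")
  expect_equal(rare_subclonal_burden(v10, ctx_sites)$n_rare, 0)
  # no rare variants -> all defined rates 0, empty classes NA not 0
  b0 <- rare_subclonal_burden(make_variants(0), ctx_sites)
  expect_equal(b0$panel_rate, 0)
  expect_true(all(is.na(b0$per_class$rate[b0$per_class$n_sites == 0])))
  expect_true(all(b0$per_class$rate[b0$per_class$n_sites > 0] == 0))
})

test_that("labeled target mutations are excluded from the background", {
  ctx_sites <- rep("ACA", 100)
  v <- make_variants(2, vaf = 0.02, context = "A[C>T]A",
                     mutation_class = c("metspec_driver", "background"))
  expect_equal(rare_subclonal_burden(v, ctx_sites)$n_rare, 1)
})

test_that("depletion is 0 for equal excess and invariant to site rescaling", {
  cnt <- c("C>T" = 20, "C>A" = 2, "C>G" = 2, "T>A" = 2, "T>C" = 2,
           "T>G" = 2)
  tr <- make_burden("t", 2000, 2000, cnt)
  un <- make_burden("u", 2000, 2000, cnt)
  d <- udg_depletion(tr, un, n_boot = 50)
  expect_equal(d$depletion, 0)
  # uniform rescaling of covered-site counts leaves depletion unchanged
  tr3 <- make_burden("t", 6000, 6000, cnt * 3)
  un3 <- make_burden("u", 6000, 6000, cnt * 3)
  d3 <- udg_depletion(tr3, un3, n_boot = 50)
  expect_equal(d3$depletion, d$depletion)
})

test_that("no demonstrable artifact burden yields an explicit signal", {
  flat <- c("C>T" = 2, "C>A" = 2, "C>G" = 2, "T>A" = 2, "T>C" = 2,
            "T>G" = 2)
  d <- udg_depletion(make_burden("t", 2000, 2000, flat),
                     make_burden("u", 2000, 2000, flat), n_boot = 10)
  expect_true(is.na(d$depletion))
  expect_match(d$reason, "untreated")
})

test_that("synthetic artifact injection at 10:1 recovers ~90% depletion", {
  # untreated carries a C>T excess of rate r; treated carries 0.1 r
  base <- c("C>A" = 4, "C>G" = 4, "T>A" = 4, "T>C" = 4, "T>G" = 4)
  un <- make_burden("u", 4000, 4000, c("C>T" = 204, base))  # excess .05
  tr <- make_burden("t", 4000, 4000, c("C>T" = 24, base))   # excess .005
  d <- udg_depletion(tr, un, n_boot = 500, seed = 3)
  expect_equal(d$depletion, 0.9, tolerance = 0.02)
  expect_true(d$ci[1] <= 0.9 && 0.9 <= d$ci[2])
})

test_that("context spectrum normalizes and flags emptiness", {
  v <- make_variants(5, vaf = 0.02, context = "A[C>T]A")
  sp <- context_spectrum(v, roi_contexts = rep(c("ACA", "ATA"), 50))
  expect_equal(sum(sp$prop_calls), 1)
  expect_equal(sp$prop_calls[sp$class == "A[C>T]A"], 1)  # point mass
  expect_equal(sum(sp$prop_sites_mutated), 1)
  expect_equal(nrow(context_spectrum(make_variants(0), vaf_ceiling = 0.1)),
               0)
})

test_that("untreated FFPE synthetic samples are C>T dominated", {
  cfg <- sim_config(n_patients = 5, artifact_ct_rate = 0.05,
                    udg_efficiency = 0.95, background_rate = 0.001,
                    seed = 11)
  co <- simulate_cohort(cfg)
  untreated <- co$samples$sample_id[!co$samples$udg_treated]
  v <- co$variants[co$variants$sample_id %in% untreated, ]
  sp <- context_spectrum(v)
  ct <- sum(sp$prop_calls[sp$substitution == "C>T"])
  expect_gt(ct, 0.5)
})
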
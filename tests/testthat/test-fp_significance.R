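test_that("artifact model takes rates from the burden profile", {
  ctx_sites <- rep(c("ACA", "ATA"), 60)
  v <- make_variants(2, vaf = 0.02, context = "A[C>T]A")
  am <- build_artifact_model(rare_subclonal_burden(v, ctx_sites))
  expect_equal(am$q_panel, 2 / 120)
  expect_equal(unname(am$q_context["A[C>T]A"]), 2 / 60)
  # classes with no covered sites fall back to the panel rate, flagged
  expect_true("A[C>T]G" %in% am$fallback)
  expect_equal(unname(am$q_context["A[C>T]G"]), am$q_panel)
  # zero burden -> all q zero
  am0 <- build_artifact_model(rare_subclonal_burden(make_variants(0),
                                                    ctx_sites))
  expect_equal(am0$q_panel, 0)
  expect_true(all(am0$q_context == 0))
})

test_that("panel-wide tail matches the exact binomial", {
  ctx <- rep("ACA", 2395)
  v5 <- make_variants(5, vaf = 0.02, context = "A[C>T]A")
  v5$pos <- 1:5 * 7L
  am <- build_artifact_model(rare_subclonal_burden(v5, ctx))
  expect_equal(am$q_panel, 5 / 2395, tolerance = 1e-12)  # ~0.00209
  am$q_panel <- 0.01
  # P(X >= 2), X ~ Bin(10, 0.01) = 1 - 0.99^10 - 10*.01*.99^9
  expect_equal(prob_false_detections(10, am, 2),
               1 - 0.99^10 - 10 * 0.01 * 0.99^9, tolerance = 1e-12)
  expect_equal(prob_false_detections(10, am, 0), 1)
  am$q_panel <- 0
  expect_equal(prob_false_detections(10, am, 1), 0)
})

test_that("Poisson-binomial DP equals the binomial when q is constant and
          is monotone in its arguments", {
  for (q in c(0.001, 0.01, 0.2)) for (k in c(1, 2, 5)) {
    expect_equal(poisson_binomial_tail(rep(q, 12), k),
                 pbinom(k - 1, 12, q, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  q <- c(0.01, 0.02, 0.005, 0.3)
  tails <- vapply(0:4, function(k) poisson_binomial_tail(q, k),
                  numeric(1))
  expect_true(all(diff(tails) <= 0))            # non-increasing in k
  expect_gte(poisson_binomial_tail(q * 2, 2),   # non-decreasing in q
             poisson_binomial_tail(q, 2))
})

test_that("Fisher combination behaves at the edges", {
  expect_equal(combined_significance(0.01)$p_fisher, 0.01)
  expect_equal(combined_significance(c(1, 1))$p_fisher, 1)
  z <- combined_significance(c(0, 0.5))
  expect_equal(z$p_fisher, 0)
  expect_true(z$zero)
})

test_that("Fisher combination is calibrated on uniform (randomized) tails", {
  # per-patient tails made exactly uniform by mid-p randomization of the
  # discrete binomial tail; 400 null cohorts of 6 patients
  set.seed(5)
  n_sim <- 400
  p_comb <- vapply(seq_len(n_sim), function(i) {
    p <- vapply(1:6, function(j) {
      x <- rbinom(1, 10, 0.05)
      pbinom(x, 10, 0.05, lower.tail = FALSE) +
        runif(1) * dbinom(x, 10, 0.05)
    }, numeric(1))
    combined_significance(p)$p_fisher
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p_comb, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation test: trivial cases and exhaustive agreement", {
  assayed <- list(P1 = c("a", "b"), P2 = c("c"), P3 = c("d", "e"))
  none <- list(P1 = character(0), P2 = character(0), P3 = character(0))
  r <- sample_permutation_test(assayed, none, n_perm = 50)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)
  expect_gte(r$p, 1 / 51)
  # own-primary detections only: exhaustive enumeration over 3! = 6
  det <- list(P1 = c("a"), P2 = c("c"), P3 = character(0))
  ex <- sample_permutation_test(assayed, det, exhaustive = TRUE)
  expect_equal(ex$n_perm, 6)
  expect_equal(ex$observed, 2)
  # brute-force oracle: count assignments with statistic >= 2
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stat <- vapply(perms, function(pp) {
    sum(vapply(1:3, function(i)
      sum(assayed[[i]] %in% det[[pp[i]]]), numeric(1)))
  }, numeric(1))
  expect_equal(ex$p, mean(stat >= 2))
  # random permutations approximate the exhaustive answer
  rr <- sample_permutation_test(assayed, det, n_perm = 4000, seed = 2)
  expect_equal(rr$p, mean(stat >= 2), tolerance = 0.05)
})

test_that("uncovered sites are unassayable in permuted primaries", {
  assayed <- list(P1 = c("a"), P2 = c("b"), P3 = c("c"))
  det <- list(P1 = c("a", "b", "c"), P2 = c("a", "b", "c"),
              P3 = c("a", "b", "c"))
  cov <- list(P1 = c("a"), P2 = c("b"), P3 = c("c"))
  r <- sample_permutation_test(assayed, det, cov, n_perm = 100, seed = 1)
  # permuted sites are uncovered, so permuted statistics fall below the
  # observed 3 whenever the permutation moves anything
  expect_equal(r$observed, 3)
  expect_gt(r$mean_unassayable, 0)
})
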
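test_that("degenerate cases match their closed forms", {
  mu <- 0.01; T <- 1000
  # d = 0: no driver term, independent of c
  p0a <- p_sequence(4, 0, mu, T, c = 0.1)$prob
  p0b <- p_sequence(4, 0, mu, T, c = 1)$prob
  expect_equal(p0a, p0b)
  expect_equal(p0a, mu^3 * (1 - (1 - mu)^T), tolerance = 1e-12)
  # k = 1, d = 0: just the first-mutation factor
  expect_equal(p_sequence(1, 0, mu, T)$prob, 1 - (1 - mu)^T,
               tolerance = 1e-12)
  expect_error(p_sequence(0.5, 0, mu, T), "k must be")
  expect_error(p_sequence(3, 3, mu, T), "d must")
})

test_that("small instance matches a per-cell Bernoulli-process simulation", {
  # independent oracle: simulate the acquisition chain event by event
  mu <- 0.01; T <- 1000; cc <- 1; k <- 3; d <- 1
  set.seed(6)
  n_sim <- 2e5
  success <- replicate(n_sim, {
    first <- rbinom(1, T, mu) >= 1            # some cell mutates
    driver <- rbinom(1, round(T * cc), mu) >= 1  # expanded clone remutates
    passenger <- runif(k - d - 1) < mu        # same cell, no expansion
    first && driver && all(passenger)
  })
  phat <- mean(success)
  p <- p_sequence(k, d, mu, T, cc)$prob
  se <- sqrt(phat * (1 - phat) / n_sim)
  expect_lt(abs(p - phat), 3 * se + 1e-6)
})

test_that("log-space evaluation survives extreme exponents and agrees with
          direct arithmetic where that does not underflow", {
  mu <- 10^-4.5
  # direct evaluation in ordinary arithmetic
  direct <- function(k, d, T, cc)
    (1 - (1 - mu)^(T * cc))^d * mu^(k - d - 1) * (1 - (1 - mu)^T)
  for (cs in list(c(5, 2), c(10, 4), c(20, 10))) {
    p <- p_sequence(cs[1], cs[2], mu, 1e9, 1)
    expect_equal(p$prob, direct(cs[1], cs[2], 1e9, 1), tolerance = 1e-10)
  }
  # far below double range: log10 stays finite
  p <- p_sequence(120, 0, mu, 1e9)
  expect_true(is.finite(p$log10))
  expect_lt(p$log10, -500)
  expect_equal(p$prob, 0)   # underflows as a bare double, by design
})

test_that("p_sequence is monotone in k and d", {
  mu <- 1e-5; T <- 1e8
  pk <- vapply(4:10, function(k) p_sequence(k, 2, mu, T)$log10,
               numeric(1))
  expect_true(all(diff(pk) < 0))       # decreasing in k
  pd <- vapply(0:5, function(d) p_sequence(8, d, mu, T)$log10,
               numeric(1))
  expect_true(all(diff(pd) > 0))       # increasing in d
})

test_that("bounded variant equals the capped-expansion evaluation", {
  mu <- 1e-9; T <- 1e9
  expect_equal(p_sequence_bounded(5, 4, mu, T, f = 1)$log10,
               p_sequence(5, 4, mu, T, c = 1)$log10)
  fs <- c(0.01, 0.03, 0.1, 0.5, 1)
  lps <- vapply(fs, function(f) p_sequence_bounded(6, 5, mu, T, f)$log10,
                numeric(1))
  expect_true(all(diff(lps) >= 0))     # non-decreasing in f
  # beneath a 3% detection floor, long undetected driver series are
  # exceedingly unlikely: < 1e-10 already at k = 8, < 1e-11 beyond
  expect_lt(p_sequence_bounded(8, 7, mu, T, 0.03)$log10, -10)
  for (k in 9:12)
    expect_lt(p_sequence_bounded(k, k - 1, mu, T, 0.03)$log10, -11)
})

test_that("passenger bound and cohort combination are exact arithmetic", {
  expect_equal(passenger_upper_bound(4, 0.1), 1e-3)
  expect_equal(passenger_upper_bound(5, 0.1), 1e-4)
  mu <- 0.1; T <- 100
  expect_lte(p_sequence(4, 0, mu, T)$prob,
             passenger_upper_bound(4, mu) * (1 + 1e-12))
  comb <- combine_patient_probabilities(c(1e-5, 1e-6))
  expect_equal(comb$log10, -11)
  expect_equal(combine_patient_probabilities(0.37)$prob, 0.37)
  # log-space product matches sequential summation of log10 values
  set.seed(3)
  lp <- -runif(30, 5, 40)
  expect_equal(combine_patient_probabilities(lp, log10 = TRUE)$log10,
               Reduce(`+`, lp), tolerance = 1e-9)
})

test_that("passenger-vs-driver ratio reduces to mu^d under saturation", {
  mu <- 10^-4.5
  r <- passenger_vs_driver_ratio(8, 7, mu, saturated = TRUE)
  expect_equal(r$log10_ratio, 7 * log10(mu))
  # non-saturated form approaches saturation for huge Tc
  r2 <- passenger_vs_driver_ratio(8, 7, mu, T = 1e12, c = 1)
  expect_equal(r2$log10_ratio, r$log10_ratio, tolerance = 1e-6)
  expect_equal(passenger_vs_driver_ratio(8, 0, mu,
                                         saturated = TRUE)$ratio, 1)
})
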
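# Could the metastasis-specific mutations "detected" in rare primary
# subclones be artifact sampling? Two complementary tests: a likelihood
# model parameterized on the background rare-subclonal burden
# (panel-wide or trinucleotide-specific), and a permutation test that
# reassigns each patient's assayed site list to unrelated primaries.

#' Build an artifact-sampling model from a background burden profile
#'
#' The per-assayed-site probability of observing an artifactual
#' rare-subclonal variant is taken from the background burden of the
#' same sample: panel-wide rate `q_panel`, and per-context rates
#' `q_context` (classes with no covered background sites fall back to
#' the panel-wide rate, flagged).
#'
#' @param burden a `burden_profile` from [rare_subclonal_burden()],
#'   computed on non-target (background) sites.
#' @return object of class `artifact_model`: list with `q_panel`,
#'   `q_context` (named over the 96 classes), `fallback` (classes using
#'   the panel-wide fallback).
#' @export
build_artifact_model <- function(burden) {
  stopifnot(inherits(burden, "burden_profile"))
  q <- burden$per_class$rate
  names(q) <- burden$per_class$class
  fallback <- names(q)[is.na(q)]
  q[is.na(q)] <- burden$panel_rate
  structure(list(q_panel = burden$panel_rate, q_context = q,
                 fallback = fallback, sample_id = burden$sample_id),
            class = "artifact_model")
}

#' Exact Poisson-binomial upper tail P(X >= k)
#'
#' X is a sum of independent Bernoulli(q_i); the distribution is built
#' by dynamic programming over sites, exact to floating precision.
#' Agrees with the binomial closed form when all q are equal.
#'
#' @param q per-site success probabilities.
#' @param k threshold count.
#' @return P(X >= k).
#' @export
poisson_binomial_tail <- function(q, k) {
  stopifnot(all(q >= 0), all(q <= 1))
  n <- length(q)
  if (k <= 0) return(1)
  if (k > n) return(0)
  pmf <- c(1, numeric(n))        # pmf[j+1] = P(X = j) after i sites
  for (i in seq_len(n)) {
    pmf <- c(pmf[1] * (1 - q[i]),
             pmf[2:(n + 1)] * (1 - q[i]) + pmf[1:n] * q[i])
  }
  sum(pmf[(k + 1):(n + 1)])
}

#' Tail probability that detections are artifact sampling
#'
#' P(X >= n_detected) where X is the number of assayed
#' metastasis-specific sites at which an artifactual rare-subclonal
#' variant would be sampled. Panel-wide mode uses
#' X ~ Binomial(n_assayed, q_panel); trinucleotide mode uses the exact
#' Poisson-binomial over the assayed sites' context-specific rates.
#'
#' @param n_assayed number of assayed metastasis-specific sites.
#' @param model an `artifact_model`.
#' @param n_detected observed number of rare-subclonal detections.
#' @param contexts canonical context classes of the assayed sites;
#'   required for `mode = "context"`.
#' @param mode "panel" or "context".
#' @return the tail probability.
#' @export
prob_false_detections <- function(n_assayed, model, n_detected,
                                  contexts = NULL,
                                  mode = c("panel", "context")) {
  mode <- match.arg(mode)
  stopifnot(n_detected <= n_assayed, n_detected >= 0)
  if (n_detected == 0) return(1)
  if (mode == "panel") {
    stats::pbinom(n_detected - 1, n_assayed, model$q_panel,
                  lower.tail = FALSE)
  } else {
    if (is.null(contexts) || length(contexts) != n_assayed)
      stop("context mode needs one context per assayed site",
           call. = FALSE)
    q <- model$q_context[contexts]
    q[is.na(q)] <- model$q_panel
    poisson_binomial_tail(unname(q), n_detected)
  }
}

#' Combine per-patient artifact tail probabilities
#'
#' Fisher's method (default, calibrated under the null) plus the raw
#' likelihood product for comparison.
#'
#' @param p per-patient tail probabilities.
#' @return list with `p_fisher`, `product`, `chisq`, `df`, and `zero`
#'   (TRUE when some tail was exactly 0, in which case the combined P is
#'   reported as 0).
#' @export
combined_significance <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  if (any(p == 0))
    return(list(p_fisher = 0, product = 0, chisq = Inf,
                df = 2 * length(p), zero = TRUE))
  chisq <- -2 * sum(log(p))
  list(p_fisher = stats::pchisq(chisq, df = 2 * length(p),
                                lower.tail = FALSE),
       product = prod(p), chisq = chisq, df = 2 * length(p), zero = FALSE)
}

#' Sample-permutation test of rare-subclonal detections
#'
#' Permutes the assignment of each patient's assayed metastasis-specific
#' site list to the cohort's primary tumors and recounts detections; an
#' observed count at or above the permutation distribution's upper tail
#' indicates patient-specific (bona fide) detections rather than
#' background shared across unrelated primaries. A site not covered in a
#' permuted primary is unassayable in that permutation (counted and
#' recorded).
#'
#' @param assayed_sites named list, one character vector of site keys
#'   per patient (the assayed metastasis-specific sites).
#' @param primary_detected named list, per patient the site keys at
#'   which the patient's primary had a rare-subclonal call.
#' @param primary_covered optional named list of site keys adequately
#'   covered in each primary; defaults to everything assayable.
#' @param n_perm number of random permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param seed RNG seed.
#' @param exhaustive enumerate all n! assignments (small cohorts only).
#' @param statistic "total" (total detections, default) or "patients"
#'   (number of patients with at least one detection).
#' @return list with `p` (add-one permutation estimate, or exact
#'   enumeration fraction), `observed`, `perm_stats`,
#'   `mean_unassayable`, `n_perm`.
#' @export
sample_permutation_test <- function(assayed_sites, primary_detected,
                                    primary_covered = NULL, n_perm = 10000,
                                    seed = 1, exhaustive = FALSE,
                                    statistic = c("total", "patients")) {
  statistic <- match.arg(statistic)
  patients <- names(assayed_sites)
  stopifnot(length(patients) >= 3,
            setequal(patients, names(primary_detected)))
  stat_for <- function(assignment) {
    # assignment[i]: index of the primary receiving patient i's sites
    det <- 0; unass <- 0; hit <- 0
    for (i in seq_along(patients)) {
      sites <- assayed_sites[[i]]
      prim <- patients[assignment[i]]
      if (!is.null(primary_covered)) {
        cov <- sites %in% primary_covered[[prim]]
        unass <- unass + sum(!cov)
        sites <- sites[cov]
      }
      d <- sum(sites %in% primary_detected[[prim]])
      det <- det + d
      hit <- hit + (d > 0)
    }
    c(stat = if (statistic == "total") det else hit, unass = unass)
  }
  obs <- stat_for(seq_along(patients))
  if (exhaustive) {
    perms <- all_permutations(length(patients))
    stats_mat <- vapply(perms, stat_for, numeric(2))
    p <- mean(stats_mat["stat", ] >= obs["stat"])
    return(list(p = p, observed = unname(obs["stat"]),
                perm_stats = unname(stats_mat["stat", ]),
                mean_unassayable = mean(stats_mat["unass", ]),
                n_perm = length(perms)))
  }
  set.seed(seed)
  stats_mat <- vapply(seq_len(n_perm), function(i)
    stat_for(sample.int(length(patients))), numeric(2))
  p <- (sum(stats_mat["stat", ] >= obs["stat"]) + 1) / (n_perm + 1)
  list(p = p, observed = unname(obs["stat"]),
       perm_stats = unname(stats_mat["stat", ]),
       mean_unassayable = mean(stats_mat["unass", ]), n_perm = n_perm)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (i in seq_len(n)) for (s in sub) {
    rest <- seq_len(n)[-i]
    out[[k]] <- c(i, rest[s])
    k <- k + 1L
  }
  out
}
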
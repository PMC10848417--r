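# VAF -> cancer cell fraction conversion with multiplicity uncertainty.
#
# At a locus with tumor total copy number C_t, normal copy number C_n,
# tumor cellularity (purity) p and s mutated allele copies, the expected
# VAF of a mutation carried by a fraction CCF of tumor cells is
#   VAF = CCF * p * s / (p * C_t + (1 - p) * C_n)
# so CCF = VAF * (p * C_t + (1 - p) * C_n) / (p * s).

#' Convert variant allele frequency to cancer cell fraction
#'
#' @param vaf variant allele frequency in \[0,1\].
#' @param purity tumor cellularity in (0,1\].
#' @param total_cn_tumor total tumor copy number at the locus (>= 1);
#'   per-segment major + minor copy number, not ploidy-averaged.
#' @param s multiplicity factor: number of mutated allele copies (>= 1).
#' @param normal_cn copy number in contaminating normal cells (default 2).
#' @return CCF, unclamped: values above 1 are returned as-is (they flag
#'   an inconsistent purity/copy-number/multiplicity combination, and
#'   published per-mutation CCFs do reach ~1.2). Linear in `vaf` and
#'   homogeneous of degree -1 in `s`.
#' @examples
#' vaf_to_ccf(0.5, purity = 1, total_cn_tumor = 2, s = 1)   # 1: clonal het
#' vaf_to_ccf(0.087, 0.47, 2, s = 1)                        # ~0.37
#' @export
vaf_to_ccf <- function(vaf, purity, total_cn_tumor, s = 1, normal_cn = 2) {
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0,1]", call. = FALSE)
  if (any(total_cn_tumor < 1))
    stop("total_cn_tumor must be >= 1", call. = FALSE)
  if (any(s < 1)) stop("multiplicity s must be >= 1", call. = FALSE)
  vaf * (purity * total_cn_tumor + (1 - purity) * normal_cn) / (purity * s)
}

#' Enumerate feasible multiplicity factors at a locus
#'
#' The number of mutated allele copies is unknown a priori but cannot
#' exceed the major copy number, so the candidate set is {1, ..., major}.
#'
#' @param major_cn major allele copy number (integer >= 0).
#' @param minor_cn minor allele copy number (unused in the enumeration,
#'   accepted for interface symmetry; must be <= major_cn if given).
#' @return integer vector of candidates, with attribute `unambiguous`
#'   TRUE when only s = 1 is possible ("only one allele could be
#'   mutated").
#' @export
enumerate_multiplicities <- function(major_cn, minor_cn = NULL) {
  if (!is.null(minor_cn) && any(minor_cn > major_cn))
    stop("minor_cn must be <= major_cn", call. = FALSE)
  if (major_cn < 1)
    stop("homozygous deletion (major_cn = 0): no allele can be mutated",
         call. = FALSE)
  s <- seq_len(major_cn)
  attr(s, "unambiguous") <- major_cn == 1L
  s
}

#' Posterior draws of CCF from molecular-tag counts
#'
#' The VAF posterior under a Jeffreys Beta(1/2, 1/2) prior is
#' Beta(mt_alt + 1/2, mt_total - mt_alt + 1/2); each draw is mapped
#' through [vaf_to_ccf()]. Only count uncertainty is modeled; purity and
#' copy number enter as fixed values.
#'
#' @param mt_alt alternate-supporting molecular tags.
#' @param mt_total total molecular tags at the site.
#' @inheritParams vaf_to_ccf
#' @param n_draws number of posterior draws.
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of CCF draws (unclamped).
#' @export
ccf_posterior <- function(mt_alt, mt_total, purity, total_cn_tumor, s = 1,
                          normal_cn = 2, n_draws = 10000, seed = NULL) {
  stopifnot(mt_alt >= 0, mt_total >= 1, mt_alt <= mt_total, n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- stats::rbeta(n_draws, mt_alt + 0.5, mt_total - mt_alt + 0.5)
  vaf_to_ccf(v, purity, total_cn_tumor, s = s, normal_cn = normal_cn)
}

#' Estimate CCF at a mutation with multiplicity uncertainty
#'
#' Computes the point CCF for every feasible multiplicity s in
#' {1, ..., major_cn} (each exactly the s = 1 value divided by s), the
#' median across s, and optionally per-s posterior draws.
#'
#' @inheritParams ccf_posterior
#' @param major_cn,minor_cn allele-specific copy number at the locus.
#' @param n_draws posterior draws per s (0 to skip posterior sampling).
#' @return object of class `ccf_estimate`: list with `per_s` (named
#'   numeric), `median_across_s`, `s_candidates`, `unambiguous`,
#'   `superclonal` (any per-s value > 1), and `posterior` (list of draw
#'   vectors, or NULL).
#' @export
ccf_estimate <- function(mt_alt, mt_total, purity, major_cn, minor_cn,
                         normal_cn = 2, n_draws = 0, seed = NULL) {
  s_cand <- enumerate_multiplicities(major_cn, minor_cn)
  total_cn <- major_cn + minor_cn
  vaf <- mt_alt / mt_total
  ccf1 <- vaf_to_ccf(vaf, purity, total_cn, s = 1, normal_cn = normal_cn)
  per_s <- ccf1 / as.numeric(s_cand)
  names(per_s) <- paste0("s", s_cand)
  post <- NULL
  if (n_draws > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- stats::rbeta(n_draws, mt_alt + 0.5, mt_total - mt_alt + 0.5)
    base <- vaf_to_ccf(v, purity, total_cn, s = 1, normal_cn = normal_cn)
    post <- lapply(as.numeric(s_cand), function(s) base / s)
    names(post) <- names(per_s)
  }
  structure(list(
    vaf = vaf, per_s = per_s,
    median_across_s = stats::median(per_s),
    s_candidates = as.integer(s_cand),
    unambiguous = isTRUE(attr(s_cand, "unambiguous")),
    superclonal = any(per_s > 1),
    posterior = post
  ), class = "ccf_estimate")
}

#' Median CCF across feasible multiplicity factors
#'
#' @param x a `ccf_estimate` object or a numeric vector of per-s CCFs.
#' @return the standard median of the per-s values.
#' @export
median_ccf_across_s <- function(x) {
  v <- if (inherits(x, "ccf_estimate")) x$per_s else x
  if (length(v) < 1) stop("no multiplicity candidates", call. = FALSE)
  stats::median(v)
}

#' @export
print.ccf_estimate <- function(x, ...) {
  cat(sprintf("CCF estimate: VAF %.4g; median across s = %.4g%s\n",
              x$vaf, x$median_across_s,
              if (x$superclonal) " [superclonal: some per-s CCF > 1]" else ""))
  cat("  per s:", paste(sprintf("%s=%.4g", names(x$per_s), x$per_s),
                        collapse = ", "),
      if (x$unambiguous) "(unambiguous)" else "", "\n")
  invisible(x)
}
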
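# Limit-of-detection statistics: the smallest VAF (and, through the
# purity/copy-number conversion, the smallest CCF) at which a mutation is
# called with a stated probability, given the site's effective depth and
# the caller's minimum alternate-observation rule.

#' Sequencing-technology detection model
#'
#' A named bundle of the parameters that set a site's detection power:
#' the effective number of independent observations (molecular tags for
#' UDS-UMI, reads for WES) and the minimum number of alternate
#' observations the caller requires. Defaults reproduce the published
#' summary detection powers: UDS-UMI with 8 variant MTs required (~3%
#' median minCCF at ~1160 MTs, ~0.9% beyond 4000 MTs at typical
#' purity); WES at 50x with 5 variant reads required (median minCCF
#' ~0.5, a ~16x sensitivity gap to UDS-UMI).
#'
#' @param name "UDS-UMI" or "WES".
#' @param depth effective independent observations at a site; default
#'   NULL for UDS-UMI (per-site MT depth supplied at use) and 50 for WES.
#' @param min_alt_obs minimum alternate observations to call.
#' @param confidence detection probability target.
#' @return object of class `tech_model`.
#' @export
tech_model <- function(name = c("UDS-UMI", "WES"), depth = NULL,
                       min_alt_obs = NULL, confidence = 0.95) {
  name <- match.arg(name)
  if (is.null(min_alt_obs)) min_alt_obs <- if (name == "UDS-UMI") 8L else 5L
  if (is.null(depth) && name == "WES") depth <- 50L
  stopifnot(min_alt_obs >= 1, confidence > 0, confidence < 1)
  structure(list(name = name, depth = depth,
                 min_alt_obs = as.integer(min_alt_obs),
                 confidence = confidence),
            class = "tech_model")
}

#' @export
print.tech_model <- function(x, ...) {
  cat(sprintf("tech_model %s: depth=%s, min_alt_obs=%d, confidence=%.2f\n",
              x$name, if (is.null(x$depth)) "per-site" else x$depth,
              x$min_alt_obs, x$confidence))
  invisible(x)
}

#' Smallest VAF detectable with stated confidence
#'
#' The smallest v such that P\[Binomial(depth, v) >= min_alt_obs\] >=
#' confidence, found by bisection to an absolute tolerance of 1e-6
#' against the exact binomial tail. Non-increasing in depth,
#' non-decreasing in min_alt_obs and confidence.
#'
#' @param depth effective independent observations at the site
#'   (vectorized).
#' @param min_alt_obs minimum alternate observations the caller requires.
#' @param confidence detection probability target.
#' @param tol bisection tolerance on v.
#' @return smallest detectable VAF per depth; `NA` where depth <
#'   min_alt_obs (detection impossible at any VAF).
#' @examples
#' min_detectable_vaf(1160, min_alt_obs = 8)   # ~0.0113
#' @export
min_detectable_vaf <- function(depth, min_alt_obs = 8, confidence = 0.95,
                               tol = 1e-6) {
  stopifnot(min_alt_obs >= 1, confidence > 0, confidence < 1)
  vapply(depth, function(n) {
    if (n < min_alt_obs) return(NA_real_)
    tail_ok <- function(v)
      stats::pbinom(min_alt_obs - 1, n, v, lower.tail = FALSE) >= confidence
    lo <- 0; hi <- 1
    if (!tail_ok(1)) return(NA_real_)  # unreachable: v=1 gives tail 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (tail_ok(mid)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

#' Smallest CCF detectable with stated confidence at a site
#'
#' Converts [min_detectable_vaf()] through the VAF-to-CCF map at the
#' site's purity and copy number, by default at multiplicity s = 1 (a
#' single mutated allele, the conservative choice).
#'
#' @inheritParams min_detectable_vaf
#' @param purity tumor cellularity in (0,1\].
#' @param total_cn_tumor total tumor copy number at the site.
#' @param model a [tech_model()]; its `min_alt_obs`/`confidence` are
#'   used, and its fixed `depth` (if any, e.g. WES 50x) overrides the
#'   `depth` argument.
#' @param s multiplicity at which detection power is quoted.
#' @param normal_cn normal-cell copy number.
#' @return smallest detectable CCF (vectorized over depth/purity/CN);
#'   `NA` where detection is impossible.
#' @export
min_detectable_ccf <- function(depth, purity, total_cn_tumor,
                               model = tech_model("UDS-UMI"), s = 1,
                               normal_cn = 2) {
  if (!is.null(model$depth)) depth <- rep(model$depth, length.out =
    max(length(depth), length(purity), length(total_cn_tumor)))
  mv <- min_detectable_vaf(depth, model$min_alt_obs, model$confidence)
  vaf_to_ccf(mv, purity, total_cn_tumor, s = s, normal_cn = normal_cn)
}

#' Per-site detection-power table for UDS-UMI and WES models
#'
#' @param sites data.frame with columns `site_id`, `depth` (MTs),
#'   `purity`, `total_cn` (total tumor copy number at the site).
#' @param uds,wes technology models.
#' @return data.frame with per-site `min_vaf_uds`, `min_ccf_uds`,
#'   `min_vaf_wes`, `min_ccf_wes`.
#' @export
detection_power_table <- function(sites, uds = tech_model("UDS-UMI"),
                                  wes = tech_model("WES")) {
  stopifnot(all(c("site_id", "depth", "purity", "total_cn") %in%
                  names(sites)))
  data.frame(
    site_id = sites$site_id,
    depth = sites$depth,
    min_vaf_uds = min_detectable_vaf(sites$depth, uds$min_alt_obs,
                                     uds$confidence),
    min_ccf_uds = min_detectable_ccf(sites$depth, sites$purity,
                                     sites$total_cn, uds),
    min_vaf_wes = min_detectable_vaf(rep(wes$depth, nrow(sites)),
                                     wes$min_alt_obs, wes$confidence),
    min_ccf_wes = min_detectable_ccf(sites$depth, sites$purity,
                                     sites$total_cn, wes),
    stringsAsFactors = FALSE
  )
}
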
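# Subclone stratification of mutations, detection status of
# metastasis-specific mutations within the antecedent primary tumor,
# pigeonhole-principle co-clonality testing, and CCF upper bounds on
# hypothetical nested ancestral subclones.

#' Classify a mutation into a subclone stratum
#'
#' Strata follow the standard definitions: major subclone CCF >= 0.50,
#' minor subclone CCF < 0.50, rare subclone VAF < 0.10 (the VAF-based
#' rule takes precedence over the CCF rule when both apply, e.g. at low
#' purity; a flag records the conflict), undetected when not called.
#'
#' @param vaf variant allele frequency (vectorized).
#' @param ccf median-across-s CCF estimate.
#' @param called logical: did the variant pass the caller?
#' @param min_ccf site detection power, attached for undetected sites.
#' @param vaf_ceiling rare-subclone VAF ceiling.
#' @param major_ccf major-subclone CCF floor.
#' @return data.frame with `stratum` (major/minor/rare/undetected),
#'   `vaf`, `ccf`, `min_ccf`, and `rare_major_conflict`.
#' @export
classify_subclone <- function(vaf, ccf, called, min_ccf = NA_real_,
                              vaf_ceiling = 0.10, major_ccf = 0.50) {
  n <- max(length(vaf), length(ccf), length(called))
  vaf <- rep_len(vaf, n); ccf <- rep_len(ccf, n)
  called <- rep_len(called, n); min_ccf <- rep_len(min_ccf, n)
  stratum <- rep("undetected", n)
  stratum[called & ccf >= major_ccf] <- "major"
  stratum[called & ccf < major_ccf] <- "minor"
  rare <- called & vaf < vaf_ceiling
  conflict <- rare & ccf >= major_ccf
  stratum[rare] <- "rare"
  data.frame(stratum = stratum, vaf = vaf, ccf = ccf, min_ccf = min_ccf,
             rare_major_conflict = conflict, stringsAsFactors = FALSE)
}

#' Detection status of metastasis-specific mutations in a primary tumor
#'
#' For each metastasis-specific mutation site, looks up the matching row
#' of the primary tumor's UDS-UMI variant table, excludes sites with
#' inadequate coverage (below `coverage_floor` molecular tags) or absent
#' from the table, classifies the rest with [classify_subclone()] (CCF
#' as the median across feasible multiplicities), and attaches the
#' site's minimum detectable CCF.
#'
#' @param met_sites data.frame of assayed metastasis-specific mutations:
#'   columns chrom, pos, ref, alt (plus optional mutation_id).
#' @param primary_variants validated variant table of the primary sample
#'   (covering the panel sites whether called or not).
#' @param purity primary tumor cellularity.
#' @param cn_segments allele-specific copy-number segments for the
#'   primary; sites with no covering segment fall back to major 1 /
#'   minor 1.
#' @param model [tech_model()] used for per-site detection power.
#' @param coverage_floor minimum molecular tags for a site to be
#'   assayable.
#' @param vaf_ceiling,major_ccf stratum thresholds.
#' @return list with `per_mutation` (one row per met-specific mutation:
#'   stratum or exclusion reason, vaf, ccf, min_ccf, mt_total) and
#'   `summary` (n_assayed, n_detected_high_vaf, n_detected_rare,
#'   n_detected_minor, n_undetected, n_excluded, undetected_fraction
#'   among assayed non-major mutations).
#' @export
detect_metspec_in_primary <- function(met_sites, primary_variants, purity,
                                      cn_segments = NULL,
                                      model = tech_model("UDS-UMI"),
                                      coverage_floor = 100,
                                      vaf_ceiling = 0.10,
                                      major_ccf = 0.50) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  pv_key <- key(primary_variants)
  empty <- data.frame(mutation_id = character(0), chrom = character(0),
                      pos = integer(0), stratum = character(0),
                      reason = character(0), vaf = numeric(0),
                      ccf = numeric(0), min_ccf = numeric(0),
                      mt_total = integer(0), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(met_sites)), function(i) {
    k <- key(met_sites[i, , drop = FALSE])
    j <- match(k, pv_key)
    out <- data.frame(mutation_id =
        if (!is.null(met_sites$mutation_id)) met_sites$mutation_id[i] else k,
      chrom = met_sites$chrom[i], pos = met_sites$pos[i],
      stratum = NA_character_, reason = NA_character_,
      vaf = NA_real_, ccf = NA_real_, min_ccf = NA_real_,
      mt_total = NA_integer_, stringsAsFactors = FALSE)
    if (is.na(j)) {
      out$stratum <- "excluded"; out$reason <- "site absent from primary table"
      return(out)
    }
    v <- primary_variants[j, , drop = FALSE]
    out$mt_total <- v$mt_total
    if (v$mt_total < coverage_floor) {
      out$stratum <- "excluded"
      out$reason <- sprintf("coverage %d MTs below floor %d", v$mt_total,
                            coverage_floor)
      return(out)
    }
    seg <- if (is.null(cn_segments)) NULL else
      cn_lookup(cn_segments, v$chrom, v$pos)
    major <- if (is.null(seg)) 1L else seg$major_cn
    minor <- if (is.null(seg)) 1L else seg$minor_cn
    est <- ccf_estimate(v$mt_alt, v$mt_total, purity, max(major, 1L), minor)
    mc <- min_detectable_ccf(v$mt_total, purity, max(major + minor, 1L),
                             model)
    cls <- classify_subclone(v$vaf, est$median_across_s, v$called, mc,
                             vaf_ceiling, major_ccf)
    out$stratum <- cls$stratum; out$vaf <- v$vaf
    out$ccf <- est$median_across_s; out$min_ccf <- mc
    out
  })
  per_mutation <- if (length(rows)) do.call(rbind, rows) else empty
  st <- per_mutation$stratum
  n_assayed <- sum(st != "excluded")
  n_rare <- sum(st == "rare")
  n_major <- sum(st == "major")
  n_minor <- sum(st == "minor")
  n_undet <- sum(st == "undetected")
  non_major <- n_rare + n_minor + n_undet
  list(per_mutation = per_mutation,
       summary = data.frame(
         n_assayed = n_assayed, n_detected_high_vaf = n_major,
         n_detected_rare = n_rare, n_detected_minor = n_minor,
         n_undetected = n_undet, n_excluded = sum(st == "excluded"),
         undetected_fraction =
           if (non_major > 0) n_undet / non_major else NA_real_))
}

#' Pigeonhole co-clonality test from two CCF posteriors
#'
#' If two mutations' CCFs in the same sample sum to more than 1, some
#' cells must carry both, so the mutations lie in one clonal lineage.
#' The reported p-value is the posterior probability of the opposite,
#' P(CCF_a + CCF_b <= 1), estimated by Monte Carlo over the two
#' posteriors (with a Wilson interval), and analytically from a Gaussian
#' approximation to the sum — used as the reported tail when the Monte
#' Carlo estimate is 0, since true tails can sit far below Monte-Carlo
#' resolution.
#'
#' The test is refused when either mutation has an ambiguous
#' multiplicity factor (more than one feasible s), because the posterior
#' is then not a single distribution.
#'
#' @param posterior_a,posterior_b CCF posterior draws (numeric vectors,
#'   possibly length-1 point masses) or `ccf_estimate` objects carrying
#'   draws (must be unambiguous).
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @param alpha co-lineage declaration level.
#' @return list with `p` (reported tail), `p_mc`, `mc_ci` (Wilson),
#'   `p_gaussian`, `co_lineage` (p < alpha), `n_draws`.
#' @export
pigeonhole_sum_test <- function(posterior_a, posterior_b, n_draws = 1e7,
                                seed = 1, alpha = 0.05) {
  grab <- function(x, nm) {
    if (inherits(x, "ccf_estimate")) {
      if (!x$unambiguous)
        stop("pigeonhole test refused: ambiguous multiplicity for ", nm,
             call. = FALSE)
      if (is.null(x$posterior))
        stop("ccf_estimate has no posterior draws", call. = FALSE)
      return(x$posterior[[1]])
    }
    x
  }
  a <- grab(posterior_a, "posterior_a")
  b <- grab(posterior_b, "posterior_b")
  set.seed(seed)
  sa <- a[sample.int(length(a), n_draws, replace = TRUE)]
  sb <- b[sample.int(length(b), n_draws, replace = TRUE)]
  n_le <- sum(sa + sb <= 1)
  p_mc <- n_le / n_draws
  # Wilson interval on the MC proportion
  z <- stats::qnorm(0.975)
  ctr <- (n_le + z^2 / 2) / (n_draws + z^2)
  hw <- z * sqrt(n_le * (n_draws - n_le) / n_draws + z^2 / 4) /
    (n_draws + z^2)
  v0 <- function(x) if (length(x) < 2) 0 else stats::var(x)
  mu <- mean(a) + mean(b)
  sd2 <- v0(a) + v0(b)
  p_gauss <- if (sd2 > 0) stats::pnorm(1, mu, sqrt(sd2)) else
    as.numeric(mu <= 1)
  p <- if (p_mc == 0) p_gauss else p_mc
  list(p = p, p_mc = p_mc, mc_ci = c(max(0, ctr - hw), min(1, ctr + hw)),
       p_gaussian = p_gauss, co_lineage = p < alpha, n_draws = n_draws)
}

#' Mutations sequentially acquired within one clonal lineage
#'
#' By the pigeonhole principle, any two mutations each present in more
#' than half the tumor cells must share cells, so all mutations with
#' CCF > 0.50 in a sample were sequentially acquired within the same
#' clonal lineage.
#'
#' @param ccf numeric CCFs (median across s), optionally named with
#'   mutation ids.
#' @param threshold lineage CCF threshold.
#' @return list with `ids` (names or indices of the set), `ccf` (their
#'   CCFs) and `k` (set size, for the evolution framework).
#' @export
sequential_lineage_set <- function(ccf, threshold = 0.50) {
  sel <- which(ccf > threshold)
  ids <- if (!is.null(names(ccf))) names(ccf)[sel] else sel
  list(ids = ids, ccf = ccf[sel], k = length(sel))
}

#' CCF upper bound for a hypothetical nested ancestral subclone
#'
#' If all undetected metastasis-specific mutations had in fact been
#' sequentially acquired inside the detected ancestral rare subclone,
#' that nested lineage could comprise at most the smaller of (a) the
#' detected ancestral subclone's CCF and (b) the best (smallest)
#' detection power among the undetected mutations' sites — any larger
#' and at least one of them would have been seen.
#'
#' @param ancestral_ccf CCF of the detected ancestral subclone.
#' @param min_ccfs minimum detectable CCFs at the undetected mutations'
#'   sites.
#' @return list with `bound` and `limited_by` ("detection" or
#'   "ancestral"); with no undetected mutations the ancestral CCF is
#'   returned with `limited_by = "ancestral_only"`.
#' @export
nested_subclone_upper_bound <- function(ancestral_ccf, min_ccfs) {
  min_ccfs <- min_ccfs[!is.na(min_ccfs)]
  if (length(min_ccfs) == 0)
    return(list(bound = ancestral_ccf, limited_by = "ancestral_only"))
  m <- min(min_ccfs)
  list(bound = min(ancestral_ccf, m),
       limited_by = if (m < ancestral_ccf) "detection" else "ancestral")
}

#' Ratio of sequentially arising metastasis-specific to truncal mutations
#'
#' Counts mutations with CCF above the lineage threshold in each label
#' group; under an all-passenger model this ratio should be far below 1,
#' whereas driver-driven post-dissemination expansion pushes it above 1.
#'
#' @param mutation_class character vector of labels; "truncal" counts to
#'   the denominator, labels starting with "metspec" to the numerator.
#' @param ccf CCFs in the relevant (metastatic) sample.
#' @param threshold sequential-lineage CCF threshold.
#' @return list with `ratio` (NA with `undefined = TRUE` when there are
#'   no sequential truncal mutations), `n_metspec`, `n_truncal`.
#' @export
metspec_truncal_ratio <- function(mutation_class, ccf, threshold = 0.50) {
  seq_sel <- !is.na(ccf) & ccf > threshold
  n_met <- sum(seq_sel & startsWith(mutation_class, "metspec"))
  n_tru <- sum(seq_sel & mutation_class == "truncal")
  list(ratio = if (n_tru > 0) n_met / n_tru else NA_real_,
       undefined = n_tru == 0, n_metspec = n_met, n_truncal = n_tru)
}

#' Fraction of mutations within a window of another mutation
#'
#' Kataegis-style clustered mutagenesis generates several nearby
#' mutations in one event; a low clustered fraction supports treating
#' mutation acquisitions as independent events.
#'
#' @param chrom,pos mutation coordinates.
#' @param window distance window in bp.
#' @return fraction of mutations having at least one neighbor within
#'   `window` bp on the same chromosome.
#' @export
clustered_mutation_fraction <- function(chrom, pos, window = 1000) {
  if (length(pos) == 0) return(NA_real_)
  has_nb <- logical(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < 2) next
    p <- sort(pos[i])
    gaps <- diff(p)
    nb <- c(gaps <= window, FALSE) | c(FALSE, gaps <= window)
    has_nb[i[order(pos[i])]] <- nb
  }
  mean(has_nb)
}
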
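# Rare-subclonal background burden by trinucleotide context, and the
# fraction of FFPE deamination (C>T) artifacts removed by UDG treatment.
#
# FFPE fixation deaminates cytosine to uracil, which sequences as a
# C>T change at low VAF; UDG digests uracil-bearing templates before
# library preparation. Comparing the C>T-specific excess of
# rare-subclonal calls between UDG-treated and untreated aliquots of the
# same blocks estimates how completely the artifacts were removed.

# class strings are fixed-width "A[C>T]G": flank, ref pyrimidine, flank
class_triplet <- function(class) {
  paste0(substr(class, 1, 1), substr(class, 3, 3), substr(class, 7, 7))
}

canonical_triplet <- function(triplet) {
  triplet <- toupper(triplet)
  flip <- substr(triplet, 2, 2) %in% c("A", "G")
  triplet[flip] <- reverse_complement(triplet[flip])
  triplet
}

rare_background <- function(variants, vaf_ceiling) {
  keep <- variants$called & variants$vaf < vaf_ceiling
  if (!is.null(variants$mutation_class))
    keep <- keep & (is.na(variants$mutation_class) |
                      variants$mutation_class == "background")
  variants[keep, , drop = FALSE]
}

#' Rare-subclonal background mutation burden by trinucleotide context
#'
#' Counts called background variants with VAF strictly below
#' `vaf_ceiling` (the rare-subclone definition) against the number of
#' covered sites eligible for each of the 96 (context, substitution)
#' classes. A covered pyrimidine-centered site is eligible for the three
#' substitution classes sharing its trinucleotide.
#'
#' @param variants validated variant data.frame for ONE sample, with a
#'   canonical `context` column ([annotate_context()]). Rows labeled
#'   `metspec_driver`/`metspec_other`/`truncal` in `mutation_class` are
#'   excluded from the background.
#' @param roi_contexts reference trinucleotides of the covered panel
#'   sites, one per covered base (purine-centered triplets are collapsed
#'   to the pyrimidine strand).
#' @param vaf_ceiling rare-subclone VAF ceiling; variants at exactly the
#'   ceiling are excluded (strict inequality).
#' @return object of class `burden_profile`: list with `sample_id`,
#'   `n_rare`, `n_sites` (covered bases), `panel_rate`, and `per_class`
#'   (data.frame: class, substitution, n_var, n_sites, rate; rate is NA
#'   where a class has no covered sites).
#' @export
rare_subclonal_burden <- function(variants, roi_contexts,
                                  vaf_ceiling = 0.10) {
  stopifnot(length(unique(variants$sample_id)) <= 1)
  rare <- rare_background(variants, vaf_ceiling)
  classes <- context_classes()
  trip <- canonical_triplet(roi_contexts)
  site_tab <- table(trip)
  n_sites <- as.integer(site_tab[class_triplet(classes)])
  n_sites[is.na(n_sites)] <- 0L
  n_var <- as.integer(table(factor(rare$context, levels = classes)))
  rate <- ifelse(n_sites > 0, n_var / n_sites, NA_real_)
  structure(list(
    sample_id = if (nrow(variants)) variants$sample_id[1] else NA_character_,
    n_rare = nrow(rare),
    n_sites = length(roi_contexts),
    panel_rate = nrow(rare) / length(roi_contexts),
    per_class = data.frame(class = classes,
                           substitution = context_substitution(classes),
                           n_var = n_var, n_sites = n_sites, rate = rate,
                           stringsAsFactors = FALSE)
  ), class = "burden_profile")
}

#' @export
print.burden_profile <- function(x, ...) {
  cat(sprintf("burden_profile %s: %d rare-subclonal calls / %d sites (rate %.3g)\n",
              x$sample_id, x$n_rare, x$n_sites, x$panel_rate))
  invisible(x)
}

pool_profiles <- function(profiles) {
  pc <- profiles[[1]]$per_class[c("class", "substitution")]
  pc$n_var <- Reduce(`+`, lapply(profiles, function(p) p$per_class$n_var))
  pc$n_sites <- Reduce(`+`, lapply(profiles,
                                   function(p) p$per_class$n_sites))
  pc
}

ct_excess <- function(per_class) {
  by_sub <- split(per_class, per_class$substitution)
  rate_sub <- vapply(by_sub, function(d) {
    ns <- sum(d$n_sites)
    if (ns == 0) NA_real_ else sum(d$n_var) / ns
  }, numeric(1))
  unname(rate_sub[["C>T"]] -
           mean(rate_sub[names(rate_sub) != "C>T"], na.rm = TRUE))
}

#' UDG depletion of FFPE C>T artifacts
#'
#' For matched UDG-treated / untreated burden profiles of the same
#' blocks, estimates the fraction of the C>T-specific rare-subclonal
#' excess removed by treatment:
#' depletion = 1 - excess_treated / excess_untreated, where a sample's
#' excess is its per-site C>T rare-subclonal rate minus the mean rate
#' across the five non-C>T substitution types (the deamination-free
#' baseline). Counts are pooled across pairs before the ratio is taken.
#' Uncertainty comes from a seeded parametric bootstrap over covered
#' sites (per-class binomial redraw of mutated-site counts).
#'
#' @param treated,untreated lists of matched `burden_profile` objects.
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed.
#' @param conf CI level.
#' @return list with `depletion` (NA when the untreated excess is <= 0,
#'   i.e. an FFPE artifact burden is not demonstrable), `ci`
#'   (percentile bootstrap), `excess_treated`, `excess_untreated`,
#'   `per_pair` depletions, and `n_boot`.
#' @export
udg_depletion <- function(treated, untreated, n_boot = 1000, seed = 1,
                          conf = 0.95) {
  if (inherits(treated, "burden_profile")) treated <- list(treated)
  if (inherits(untreated, "burden_profile")) untreated <- list(untreated)
  stopifnot(length(treated) >= 1, length(treated) == length(untreated))
  pt <- pool_profiles(treated)
  pu <- pool_profiles(untreated)
  et <- ct_excess(pt)
  eu <- ct_excess(pu)
  per_pair <- mapply(function(a, b) {
    ea <- ct_excess(a$per_class); eb <- ct_excess(b$per_class)
    if (is.na(eb) || eb <= 0) NA_real_ else 1 - ea / eb
  }, treated, untreated)
  if (is.na(eu) || eu <= 0)
    return(list(depletion = NA_real_, ci = c(NA_real_, NA_real_),
                excess_treated = et, excess_untreated = eu,
                per_pair = per_pair, n_boot = n_boot,
                reason = "untreated C>T excess <= 0"))
  set.seed(seed)
  boot_one <- function(pc) {
    ok <- pc$n_sites > 0
    pc$n_var[ok] <- stats::rbinom(sum(ok), pc$n_sites[ok],
                                  pc$n_var[ok] / pc$n_sites[ok])
    ct_excess(pc)
  }
  draws <- vapply(seq_len(n_boot), function(i) {
    ebu <- boot_one(pu)
    if (is.na(ebu) || ebu <= 0) return(NA_real_)
    1 - boot_one(pt) / ebu
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(draws, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(depletion = 1 - et / eu, ci = ci, excess_treated = et,
       excess_untreated = eu, per_pair = per_pair, n_boot = n_boot)
}

#' Context spectrum of rare-subclonal calls
#'
#' Two normalized views over the 96 classes: the proportion of
#' rare-subclonal calls falling in each class, and (when covered-site
#' contexts are given) the per-class proportion of covered sites
#' mutated, normalized to sum to 1.
#'
#' @inheritParams rare_subclonal_burden
#' @param roi_contexts optional covered-site trinucleotides for the
#'   site-normalized view.
#' @return data.frame (class, substitution, n_var, prop_calls, and
#'   prop_sites_mutated when `roi_contexts` is given). Zero rows signal
#'   an empty spectrum.
#' @export
context_spectrum <- function(variants, roi_contexts = NULL,
                             vaf_ceiling = 0.10) {
  rare <- rare_background(variants, vaf_ceiling)
  classes <- context_classes()
  n_var <- as.integer(table(factor(rare$context, levels = classes)))
  if (sum(n_var) == 0) return(data.frame())
  out <- data.frame(class = classes,
                    substitution = context_substitution(classes),
                    n_var = n_var,
                    prop_calls = n_var / sum(n_var),
                    stringsAsFactors = FALSE)
  if (!is.null(roi_contexts)) {
    site_tab <- table(canonical_triplet(roi_contexts))
    n_sites <- as.integer(site_tab[class_triplet(classes)])
    n_sites[is.na(n_sites)] <- 0L
    frac <- ifelse(n_sites > 0, n_var / n_sites, 0)
    out$prop_sites_mutated <- if (sum(frac) > 0) frac / sum(frac) else frac
  }
  out
}
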
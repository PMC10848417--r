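# End-to-end orchestration: per-patient detection summaries, artifact
# significance, nested-subclone bounds, sequential-acquisition
# likelihoods, and the figure-data tables underlying the study-style
# summaries. Stages only read their inputs; outputs are plain tables.

#' Run the full rare-subclone analysis on a cohort
#'
#' Composes every stage on an in-memory cohort (as produced by
#' [simulate_cohort()], or assembled from files with the readers in this
#' package): per-site detection power, detection status of each assayed
#' metastasis-specific mutation in its primary, background burden and
#' artifact-sampling significance (panel-wide and trinucleotide modes,
#' combined by Fisher's method, plus the sample-permutation test),
#' nested-subclone CCF upper bounds, bounded sequential-acquisition
#' likelihoods, and the metastasis-specific:truncal sequential ratio.
#' Deterministic given `seed`.
#'
#' @param cohort list with `variants`, `samples`, `cn_segments`, `roi`,
#'   `met_sites`, and optionally `wes` (see [simulate_cohort()]).
#' @param model UDS detection model ([tech_model()]).
#' @param coverage_floor minimum MTs for a site to be assayable.
#' @param vaf_ceiling rare-subclone VAF ceiling.
#' @param major_ccf major-subclone CCF floor.
#' @param mu,T,f sequential-acquisition parameters for the bounded
#'   likelihood: per-site mutation rate per cell division (default 1e-9,
#'   the scale of a specific driver base — NOT the exome-wide rate used
#'   for passenger-vs-driver ratios), tumor size in cells, and the CCF
#'   detection-floor ceiling each expansion must stay beneath.
#' @param n_perm permutations for the sample-permutation test.
#' @param seed RNG seed.
#' @param outdir optional directory; when given, per-patient and cohort
#'   tables are written there as TSV.
#' @return list with `per_patient` (data.frame), `per_mutation`,
#'   `cohort_summary` (list), `figure_data` (list of plain tables).
#' @export
run_full_analysis <- function(cohort, model = tech_model("UDS-UMI"),
                              coverage_floor = 100, vaf_ceiling = 0.10,
                              major_ccf = 0.50, mu = 1e-9, T = 1e9,
                              f = 0.03, n_perm = 2000, seed = 1,
                              outdir = NULL) {
  samples <- cohort$samples
  prim <- samples[samples$role == "primary" & samples$udg_treated, ,
                  drop = FALSE]
  prim <- prim[!duplicated(prim$patient_id), , drop = FALSE]
  patients <- names(cohort$met_sites)
  per_patient <- list(); per_mutation <- list()
  tails_panel <- c(); tails_context <- c()
  assayed_keys <- list(); detected_keys <- list(); covered_keys <- list()
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

  for (pid in patients) {
    sm <- prim[prim$patient_id == pid, , drop = FALSE]
    pv <- cohort$variants[cohort$variants$sample_id == sm$sample_id, ,
                          drop = FALSE]
    det <- detect_metspec_in_primary(cohort$met_sites[[pid]], pv,
                                     sm$purity, cohort$cn_segments, model,
                                     coverage_floor, vaf_ceiling,
                                     major_ccf)
    pm <- det$per_mutation
    pm$patient_id <- rep_len(pid, nrow(pm))
    per_mutation[[pid]] <- pm

    # background burden on non-target sites -> artifact significance
    target_key <- key(cohort$met_sites[[pid]])
    bg <- pv[!(key(pv) %in% target_key), , drop = FALSE]
    target_pos <- paste(cohort$met_sites[[pid]]$chrom,
                        cohort$met_sites[[pid]]$pos)
    roi_bg <- cohort$roi[!(paste(cohort$roi$chrom, cohort$roi$pos) %in%
                             target_pos), , drop = FALSE]
    burden <- rare_subclonal_burden(bg, roi_bg$triplet, vaf_ceiling)
    am <- build_artifact_model(burden)
    n_assayed <- det$summary$n_assayed
    n_rare <- det$summary$n_detected_rare
    assayed <- pm[pm$stratum != "excluded", , drop = FALSE]
    ctx_rows <- match(assayed$mutation_id, pm$mutation_id)
    ms <- cohort$met_sites[[pid]]
    ctx <- vapply(seq_len(nrow(assayed)), function(i) {
      j <- match(assayed$mutation_id[i], ms$mutation_id)
      tri <- cohort$roi$triplet[match(paste(ms$chrom[j], ms$pos[j]),
                                      paste(cohort$roi$chrom,
                                            cohort$roi$pos))]
      if (is.na(tri)) NA_character_ else
        canonical_context(tri, ms$ref[j], ms$alt[j])
    }, character(1))
    p_panel <- if (n_assayed > 0)
      prob_false_detections(n_assayed, am, n_rare) else NA_real_
    p_ctx <- if (n_assayed > 0 && !anyNA(ctx))
      prob_false_detections(n_assayed, am, n_rare, contexts = ctx,
                            mode = "context") else NA_real_
    tails_panel <- c(tails_panel, p_panel)
    tails_context <- c(tails_context, p_ctx)

    # permutation-test bookkeeping (rare-subclonal calls in primary)
    assayed_keys[[pid]] <- key(ms)
    covered_keys[[pid]] <- key(pv[pv$mt_total >= coverage_floor, ,
                                  drop = FALSE])
    rare_calls <- pv[pv$called & pv$vaf < vaf_ceiling, , drop = FALSE]
    detected_keys[[pid]] <- key(rare_calls)

    # nested ancestral subclone bound and bounded likelihood
    anc <- if (n_rare > 0) max(assayed$ccf[assayed$stratum == "rare"])
      else NA_real_
    undet <- assayed[assayed$stratum == "undetected", , drop = FALSE]
    ub <- if (!is.na(anc))
      nested_subclone_upper_bound(anc, undet$min_ccf)$bound else NA_real_
    k_undet <- nrow(undet)
    log10_bounded <- if (k_undet >= 3)
      p_sequence_bounded(k_undet, k_undet - 1, mu, T, f)$log10 else
        NA_real_

    ratio <- if (!is.null(cohort$wes))
      with(cohort$wes[[pid]]$seq_counts,
           if (n_truncal_seq > 0) n_metspec_seq / n_truncal_seq else
             NA_real_) else NA_real_

    per_patient[[pid]] <- data.frame(
      patient_id = pid, n_assayed = n_assayed,
      n_detected_high_vaf = det$summary$n_detected_high_vaf,
      n_detected_rare = n_rare,
      n_detected_minor = det$summary$n_detected_minor,
      n_undetected = det$summary$n_undetected,
      n_excluded = det$summary$n_excluded,
      undetected_fraction = det$summary$undetected_fraction,
      background_rate = burden$panel_rate,
      p_artifact_panel = p_panel, p_artifact_context = p_ctx,
      ancestral_ccf = anc, nested_ccf_upper_bound = ub,
      log10_p_bounded = log10_bounded,
      metspec_truncal_ratio = ratio, stringsAsFactors = FALSE)
  }
  per_patient <- do.call(rbind, c(per_patient,
                                  list(make.row.names = FALSE)))
  per_mutation <- do.call(rbind, c(per_mutation,
                                   list(make.row.names = FALSE)))

  ok_panel <- !is.na(tails_panel)
  comb_panel <- combined_significance(tails_panel[ok_panel])
  ok_ctx <- !is.na(tails_context)
  comb_ctx <- if (any(ok_ctx))
    combined_significance(tails_context[ok_ctx]) else NULL
  perm <- if (length(patients) >= 3)
    sample_permutation_test(assayed_keys, detected_keys, covered_keys,
                            n_perm = n_perm, seed = seed) else NULL
  bounded <- per_patient$log10_p_bounded
  comb_evo <- if (any(!is.na(bounded)))
    combine_patient_probabilities(bounded[!is.na(bounded)], log10 = TRUE)
  else NULL

  st <- per_mutation$stratum
  non_major <- sum(st %in% c("rare", "minor", "undetected"))
  cohort_summary <- list(
    n_patients = length(patients),
    n_assayed = sum(st != "excluded"),
    n_detected_high_vaf = sum(st == "major"),
    n_detected_rare = sum(st == "rare"),
    n_undetected = sum(st == "undetected"),
    undetected_fraction = if (non_major > 0)
      sum(st == "undetected") / non_major else NA_real_,
    median_rare_ccf = stats::median(per_mutation$ccf[st == "rare"]),
    median_min_ccf = stats::median(per_mutation$min_ccf,
                                   na.rm = TRUE),
    combined_p_panel = comb_panel$p_fisher,
    combined_p_context = if (is.null(comb_ctx)) NA_real_ else
      comb_ctx$p_fisher,
    likelihood_product_panel = comb_panel$product,
    permutation_p = if (is.null(perm)) NA_real_ else perm$p,
    combined_log10_bounded = if (is.null(comb_evo)) NA_real_ else
      comb_evo$log10,
    mean_metspec_truncal_ratio =
      mean(per_patient$metspec_truncal_ratio, na.rm = TRUE))

  # figure-data analogues: stratum proportions, per-patient counts,
  # undetected fraction by coverage bin, rare-subclone CCF strip
  assayed_m <- per_mutation[st != "excluded", , drop = FALSE]
  bins <- cut(assayed_m$mt_total, c(100, 500, 1000, 2000, 4000, Inf),
              right = FALSE)
  fig_cov <- do.call(rbind, lapply(split(assayed_m, bins), function(d) {
    nm <- sum(d$stratum %in% c("rare", "minor", "undetected"))
    data.frame(n = nrow(d),
               undetected_fraction = if (nm > 0)
                 sum(d$stratum == "undetected") / nm else NA_real_)
  }))
  fig_cov$coverage_bin <- rownames(fig_cov)
  figure_data <- list(
    strata = as.data.frame(table(stratum = assayed_m$stratum),
                           stringsAsFactors = FALSE),
    per_patient_counts = per_patient[, c("patient_id", "n_detected_rare",
                                         "n_detected_high_vaf",
                                         "n_undetected")],
    undetected_by_coverage = fig_cov[, c("coverage_bin", "n",
                                         "undetected_fraction")],
    rare_ccfs = assayed_m[assayed_m$stratum == "rare",
                          c("patient_id", "mutation_id", "vaf", "ccf")])

  out <- list(per_patient = per_patient, per_mutation = per_mutation,
              cohort_summary = cohort_summary, figure_data = figure_data,
              permutation = perm)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(per_patient, file.path(outdir, "per_patient.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(per_mutation, file.path(outdir, "per_mutation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(metric = names(cohort_summary),
                 value = unlist(lapply(cohort_summary, format))),
      file.path(outdir, "cohort_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(figure_data))
      utils::write.table(figure_data[[nm]],
                         file.path(outdir, paste0("fig_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' WES vs UDS-UMI concordance report
#'
#' Recall of WES calls by UDS-UMI and the coefficient of determination
#' (squared Pearson correlation) of the two technologies' VAFs on the
#' intersection of call sets, keyed by (sample, chrom, pos, ref, alt).
#'
#' @param wes_calls data.frame with sample_id, chrom, pos, ref, alt,
#'   vaf (WES calls).
#' @param uds_calls data.frame with the same key columns plus vaf and
#'   called.
#' @return list with `recall`, `n_recalled`, `n_wes`, `r_squared`
#'   (NA with `empty_intersection = TRUE` when no keys are shared).
#' @export
concordance_report <- function(wes_calls, uds_calls) {
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt,
                           sep = ":")
  kw <- key(wes_calls)
  uds_called <- uds_calls[uds_calls$called, , drop = FALSE]
  ku <- key(uds_called)
  recalled <- kw %in% ku
  shared <- match(kw, ku)
  ok <- !is.na(shared)
  r2 <- if (sum(ok) >= 2 && stats::sd(wes_calls$vaf[ok]) > 0 &&
            stats::sd(uds_called$vaf[shared[ok]]) > 0)
    stats::cor(wes_calls$vaf[ok], uds_called$vaf[shared[ok]])^2 else
      NA_real_
  list(recall = mean(recalled), n_recalled = sum(recalled),
       n_wes = length(kw), r_squared = r2,
       empty_intersection = !any(ok))
}
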
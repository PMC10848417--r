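# Synthetic paired primary/metastasis cohorts with known ground truth.
#
# The generator emulates the statistical structure of an ultra-deep
# UMI panel study of paired tumors: a truncal clone plus nested
# subclones with assigned CCFs (rare ancestral subclones at CCF
# 0.01-0.30), metastasis-specific driver/passenger mutations acquired
# before or after dissemination, binomial molecular-tag sampling at
# log-normal depth (median 1160 MTs), shallow 50x WES resampling of the
# same mutations, and FFPE C>T artifact injection by trinucleotide
# context with a configurable UDG depletion factor. Subclone CCFs are
# specified, not grown: pipeline tests need controlled CCFs, not growth
# kinetics.

#' Simulation configuration
#'
#' Defaults restate the study-scale conditions: 21 patients, panel of
#' 204 ROIs of 11-22 bp, log-normal MT depth with median 1160 (IQR
#' roughly 600-2600), WES at 50x, ~7.5% of metastasis-specific mutations
#' acquired before dissemination within rare subclones of CCF 0.02-0.28,
#' untreated FFPE C>T artifact rate 0.01 per covered C site with UDG
#' efficiency 0.9, and a context-independent background somatic
#' rare-subclonal rate of 0.002 per covered site.
#'
#' @param n_patients patients in the cohort.
#' @param purity_range tumor cellularity range (uniform draw per block).
#' @param rare_ccf_range CCF range (log-uniform draw) of rare ancestral
#'   subclones carrying pre-dissemination mutations.
#' @param met_ccf_range CCF range of metastasis-specific mutations in
#'   the metastasis.
#' @param mean_metspec mean assayed metastasis-specific mutations per
#'   patient (negative-binomial draw, minimum 1).
#' @param frac_predissemination fraction of metastasis-specific
#'   mutations present in the primary before dissemination.
#' @param n_truncal truncal (panel) mutations per patient.
#' @param mt_depth_meanlog,mt_depth_sdlog log-normal MT depth parameters.
#' @param wes_depth WES read depth.
#' @param min_alt_obs molecular tags required for a UDS call.
#' @param wes_min_alt reads required for a WES call.
#' @param artifact_ct_rate untreated FFPE C>T artifact rate per covered
#'   C-context site.
#' @param udg_efficiency fraction of artifacts removed by UDG treatment.
#' @param background_rate bona fide background rare-subclonal somatic
#'   rate per covered site.
#' @param n_roi,roi_len_range panel geometry.
#' @param n_untreated_replicates number of patients whose primary block
#'   is re-sequenced without UDG treatment (matched pairs for the
#'   depletion estimate; the study used 5).
#' @param seed RNG seed; the whole cohort is deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 21,
                       purity_range = c(0.5, 0.9),
                       rare_ccf_range = c(0.02, 0.28),
                       met_ccf_range = c(0.6, 1.0),
                       mean_metspec = 6,
                       frac_predissemination = 0.075,
                       n_truncal = 3,
                       mt_depth_meanlog = log(1160),
                       mt_depth_sdlog = 1.1,
                       wes_depth = 50,
                       min_alt_obs = 8,
                       wes_min_alt = 4,
                       artifact_ct_rate = 0.01,
                       udg_efficiency = 0.9,
                       background_rate = 0.002,
                       n_roi = 204,
                       roi_len_range = c(11, 22),
                       n_untreated_replicates = 5,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1,
            all(cfg$rare_ccf_range > 0), all(cfg$rare_ccf_range <= 1),
            diff(cfg$rare_ccf_range) >= 0,
            cfg$udg_efficiency >= 0, cfg$udg_efficiency <= 1,
            cfg$artifact_ct_rate >= 0, cfg$artifact_ct_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

draw_depth <- function(n, cfg) {
  pmin(6000L, pmax(100L, as.integer(round(
    stats::rlnorm(n, cfg$mt_depth_meanlog, cfg$mt_depth_sdlog)))))
}

random_triplet <- function(n) {
  b <- c("A", "C", "G", "T")
  paste0(sample(b, n, TRUE), sample(b, n, TRUE), sample(b, n, TRUE))
}

#' Expected VAF of a mutation
#' @param ccf cancer cell fraction.
#' @param purity tumor cellularity.
#' @param total_cn total tumor copy number.
#' @param s multiplicity.
#' @param normal_cn normal-cell copy number.
#' @return expected VAF (inverse of [vaf_to_ccf()]).
#' @export
ccf_to_vaf <- function(ccf, purity, total_cn, s = 1, normal_cn = 2) {
  ccf * purity * s / (purity * total_cn + (1 - purity) * normal_cn)
}

#' Simulate a paired primary/metastasis UDS-UMI cohort
#'
#' For every mutation the true CCF per sample follows from its clone
#' membership; molecular-tag counts are Binomial(mt_total, VAF) with
#' VAF = CCF * purity * s / (purity * CN_t + 2(1 - purity));
#' post-dissemination mutations have true primary CCF 0. FFPE C>T
#' artifacts and background somatic rare variants are then injected into
#' the primary tables. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (UDS rows for every relevant site and
#'   sample, called or not, context-annotated), `samples` metadata,
#'   `cn_segments` (one diploid segment per chromosome), `roi` (per-base
#'   chrom/pos/triplet), `met_sites` (assayed metastasis-specific site
#'   lists per patient), `wes` (metastatic WES table with sequential
#'   metspec/truncal labels and 50x resampling of panel mutations), and
#'   `truth` (per-mutation ground truth).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  # panel: n_roi regions on chr1..22, one triplet per covered base
  chroms <- paste0("chr", rep_len(1:22, cfg$n_roi))
  lens <- sample(seq(cfg$roi_len_range[1], cfg$roi_len_range[2]),
                 cfg$n_roi, TRUE)
  starts <- sample.int(2e8, cfg$n_roi)
  roi <- data.frame(
    chrom = rep(chroms, lens),
    pos = unlist(mapply(function(s, l) seq(s, s + l - 1L), starts, lens,
                        SIMPLIFY = FALSE)),
    triplet = canonical_triplet(random_triplet(sum(lens))),
    stringsAsFactors = FALSE)
  cn_segments <- data.frame(chrom = paste0("chr", 1:22), start = 1L,
                            end = 3e8L, major_cn = 1L, minor_cn = 1L)

  variants <- list(); truth <- list(); wes <- list()
  samples <- list(); met_sites <- list()
  free_sites <- sample.int(nrow(roi))   # unique panel bases for mutations
  take_sites <- function(n) {
    idx <- free_sites[seq_len(n)]
    free_sites <<- free_sites[-seq_len(n)]
    idx
  }
  mut_base <- function(trip) {
    ref <- substr(trip, 2, 2)
    vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
           character(1), USE.NAMES = FALSE)
  }
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    pur_p <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    pur_m <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    replicate_untreated <- p <= cfg$n_untreated_replicates
    roles <- c("P", "M", if (replicate_untreated) "Pu")
    samples[[pid]] <- data.frame(
      patient_id = pid,
      sample_id = paste0(pid, "_", roles),
      block_id = c("PI", "MI", if (replicate_untreated) "PI"),
      role = ifelse(roles == "M", "metastasis", "primary"),
      purity = ifelse(roles == "M", pur_m, pur_p), ploidy = 2,
      preservation = ifelse(roles == "M", "frozen", "FFPE"),
      udg_treated = roles != "Pu",
      block_age_years = stats::runif(1, 2, 20), stringsAsFactors = FALSE)

    n_ms <- max(1L, stats::rnbinom(1, size = 0.9, mu = cfg$mean_metspec))
    rare_ccf <- exp(stats::runif(1, log(cfg$rare_ccf_range[1]),
                                 log(cfg$rare_ccf_range[2])))
    pre <- stats::runif(n_ms) < cfg$frac_predissemination
    idx <- take_sites(n_ms + cfg$n_truncal)
    ms_idx <- idx[seq_len(n_ms)]
    tr_idx <- idx[-seq_len(n_ms)]
    mut <- data.frame(
      mutation_id = c(sprintf("%s_ms%02d", pid, seq_len(n_ms)),
                      sprintf("%s_tr%02d", pid, seq_len(cfg$n_truncal))),
      patient_id = pid,
      chrom = roi$chrom[idx], pos = roi$pos[idx],
      triplet = roi$triplet[idx],
      mutation_class = c(ifelse(seq_len(n_ms) <= ceiling(n_ms / 3),
                                "metspec_driver", "metspec_other"),
                         rep("truncal", cfg$n_truncal)),
      pre_dissemination = c(pre, rep(TRUE, cfg$n_truncal)),
      true_ccf_primary = c(ifelse(pre, rare_ccf, 0),
                           rep(1, cfg$n_truncal)),
      true_ccf_met = c(stats::runif(n_ms, cfg$met_ccf_range[1],
                                    cfg$met_ccf_range[2]),
                       rep(1, cfg$n_truncal)),
      artifact = FALSE, stringsAsFactors = FALSE)
    mut$ref <- substr(mut$triplet, 2, 2)
    mut$alt <- mut_base(mut$triplet)
    met_sites[[pid]] <- data.frame(
      mutation_id = mut$mutation_id[seq_len(n_ms)],
      chrom = mut$chrom[seq_len(n_ms)], pos = mut$pos[seq_len(n_ms)],
      ref = mut$ref[seq_len(n_ms)], alt = mut$alt[seq_len(n_ms)],
      stringsAsFactors = FALSE)

    for (role in roles) {
      sid <- paste0(pid, "_", role)
      pur <- if (role == "M") pur_m else pur_p
      ccf <- if (role == "M") mut$true_ccf_met else mut$true_ccf_primary
      depth <- draw_depth(nrow(mut), cfg)
      vaf <- ccf_to_vaf(ccf, pur, total_cn = 2)
      alt <- stats::rbinom(nrow(mut), depth, vaf)
      variants[[paste0(sid, "_mut")]] <- data.frame(
        patient_id = pid, sample_id = sid,
        chrom = mut$chrom, pos = mut$pos, ref = mut$ref, alt = mut$alt,
        mt_alt = alt, mt_total = depth, vaf = alt / depth,
        called = alt >= cfg$min_alt_obs,
        context = canonical_context(mut$triplet, mut$ref, mut$alt),
        mutation_class = mut$mutation_class,
        mutation_id = mut$mutation_id, stringsAsFactors = FALSE)
    }
    truth[[pid]] <- mut

    # metastatic WES: exome-wide sequential metspec + truncal mutations
    # (cohort averages ~60 metspec vs ~20 truncal, mean ratio ~3), plus
    # a 50x resampling of the panel metspec mutations
    k_met <- stats::rpois(1, 60)
    k_tru <- stats::rpois(1, 20)
    wes_alt <- stats::rbinom(n_ms, cfg$wes_depth,
                             ccf_to_vaf(mut$true_ccf_met[seq_len(n_ms)],
                                        pur_m, 2))
    wes[[pid]] <- list(
      patient_id = pid,
      seq_counts = data.frame(patient_id = pid, n_metspec_seq = k_met,
                              n_truncal_seq = k_tru),
      exome = data.frame(
        patient_id = pid,
        chrom = paste0("chr", sample.int(22, k_met + k_tru, TRUE)),
        pos = sample.int(2.4e9, k_met + k_tru),
        mutation_class = c(rep("metspec_other", k_met),
                           rep("truncal", k_tru)),
        ccf_met = stats::runif(k_met + k_tru, 0.55, 1),
        stringsAsFactors = FALSE),
      panel = data.frame(
        mutation_id = mut$mutation_id[seq_len(n_ms)],
        wes_alt = wes_alt, wes_depth = cfg$wes_depth,
        wes_vaf = wes_alt / cfg$wes_depth,
        wes_called = wes_alt >= cfg$wes_min_alt,
        stringsAsFactors = FALSE))
  }
  cohort <- list(
    config = cfg,
    variants = do.call(rbind, c(variants, list(make.row.names = FALSE))),
    samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
    cn_segments = cn_segments, roi = roi, met_sites = met_sites,
    wes = wes,
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  cohort <- inject_ffpe_artifacts(cohort, cfg$artifact_ct_rate,
                                  cfg$udg_efficiency,
                                  seed = cfg$seed + 1L)
  cohort <- inject_background(cohort, cfg$background_rate,
                              seed = cfg$seed + 2L)
  cohort
}

artifact_like_rows <- function(cohort, site_idx, sample_row, label,
                               substitutions = NULL) {
  cfg <- cohort$config
  roi <- cohort$roi[site_idx, , drop = FALSE]
  n <- nrow(roi)
  depth <- draw_depth(n, cfg)
  vaf <- stats::runif(n, 1 / depth, 0.05)
  alt_count <- stats::rbinom(n, depth, vaf)
  ref <- substr(roi$triplet, 2, 2)
  alt <- if (is.null(substitutions)) {
    vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
           character(1), USE.NAMES = FALSE)
  } else substitutions
  keep <- alt_count >= cfg$min_alt_obs
  if (!any(keep)) return(NULL)
  data.frame(
    patient_id = sample_row$patient_id, sample_id = sample_row$sample_id,
    chrom = roi$chrom[keep], pos = roi$pos[keep],
    ref = ref[keep], alt = alt[keep],
    mt_alt = alt_count[keep], mt_total = depth[keep],
    vaf = alt_count[keep] / depth[keep], called = TRUE,
    context = canonical_context(roi$triplet[keep], ref[keep], alt[keep]),
    mutation_class = "background",
    mutation_id = sprintf("%s_%s_%s_%d", sample_row$sample_id, label,
                          roi$chrom[keep], roi$pos[keep]),
    stringsAsFactors = FALSE)
}

#' Inject FFPE C>T deamination artifacts into a simulated cohort
#'
#' Each FFPE-preserved sample receives artifact calls at C-context
#' covered sites at the configured per-site rate, multiplied by
#' (1 - udg_efficiency) when the sample is UDG-treated. Artifact VAFs
#' are drawn from Uniform(1/mt_total, 0.05); counts below the calling
#' threshold are dropped on both arms alike. Artifacts are labeled
#' `background` in the variant table and `artifact = TRUE` in the ground
#' truth.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param ct_rate untreated per-C-site artifact rate.
#' @param udg_efficiency fraction removed by UDG in treated samples.
#' @param seed RNG seed.
#' @return the cohort with artifact rows appended.
#' @export
inject_ffpe_artifacts <- function(cohort, ct_rate, udg_efficiency,
                                  seed = 1) {
  if (ct_rate <= 0) return(cohort)
  set.seed(seed)
  c_sites <- which(substr(cohort$roi$triplet, 2, 2) == "C")
  new_rows <- list(); new_truth <- list()
  for (i in seq_len(nrow(cohort$samples))) {
    sm <- cohort$samples[i, , drop = FALSE]
    if (sm$preservation != "FFPE") next
    rate <- ct_rate * if (sm$udg_treated) (1 - udg_efficiency) else 1
    hit <- c_sites[stats::runif(length(c_sites)) < rate]
    if (!length(hit)) next
    rows <- artifact_like_rows(cohort, hit, sm, "ffpe",
                               substitutions = rep("T", length(hit)))
    if (is.null(rows)) next
    new_rows[[sm$sample_id]] <- rows
    new_truth[[sm$sample_id]] <- data.frame(
      mutation_id = rows$mutation_id, patient_id = sm$patient_id,
      chrom = rows$chrom, pos = rows$pos, triplet = NA_character_,
      mutation_class = "background", pre_dissemination = NA,
      true_ccf_primary = 0, true_ccf_met = 0, artifact = TRUE,
      ref = rows$ref, alt = rows$alt, stringsAsFactors = FALSE)
  }
  if (length(new_rows)) {
    cohort$variants <- rbind(cohort$variants, do.call(rbind, new_rows))
    cohort$truth <- rbind(cohort$truth, do.call(rbind, new_truth))
  }
  cohort
}

# bona fide background somatic rare variants, context-independent
inject_background <- function(cohort, rate, seed = 1) {
  if (rate <= 0) return(cohort)
  set.seed(seed)
  new_rows <- list(); new_truth <- list()
  for (i in seq_len(nrow(cohort$samples))) {
    sm <- cohort$samples[i, , drop = FALSE]
    hit <- which(stats::runif(nrow(cohort$roi)) < rate)
    if (!length(hit)) next
    rows <- artifact_like_rows(cohort, hit, sm, "bg")
    if (is.null(rows)) next
    new_rows[[sm$sample_id]] <- rows
    new_truth[[sm$sample_id]] <- data.frame(
      mutation_id = rows$mutation_id, patient_id = sm$patient_id,
      chrom = rows$chrom, pos = rows$pos, triplet = NA_character_,
      mutation_class = "background", pre_dissemination = NA,
      true_ccf_primary = NA_real_, true_ccf_met = NA_real_,
      artifact = FALSE, ref = rows$ref, alt = rows$alt,
      stringsAsFactors = FALSE)
  }
  if (length(new_rows)) {
    cohort$variants <- rbind(cohort$variants, do.call(rbind, new_rows))
    cohort$truth <- rbind(cohort$truth, do.call(rbind, new_truth))
  }
  cohort
}

#' Ground-truth report for a simulated cohort
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @return data.frame keyed by `mutation_id`: true CCF per sample,
#'   driver flag, pre/post dissemination, artifact flag. Every
#'   non-background variant row joins losslessly.
#' @export
ground_truth_report <- function(cohort) {
  t <- cohort$truth
  data.frame(mutation_id = t$mutation_id, patient_id = t$patient_id,
             chrom = t$chrom, pos = t$pos,
             mutation_class = t$mutation_class,
             driver = t$mutation_class == "metspec_driver",
             pre_dissemination = t$pre_dissemination,
             true_ccf_primary = t$true_ccf_primary,
             true_ccf_met = t$true_ccf_met,
             artifact = t$artifact, stringsAsFactors = FALSE)
}
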
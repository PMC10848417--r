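# Shared fixtures, built in code at test time.

# minimal valid variant data.frame
make_variants <- function(n = 3, sample_id = "S1", called = TRUE,
                          mt_alt = 10, mt_total = 1000, vaf = NULL,
                          context = NULL, mutation_class = NULL) {
  m <- max(n, 1L)
  d <- data.frame(
    patient_id = "P1", sample_id = sample_id, chrom = "chr1",
    pos = seq_len(m) * 100L, ref = "C", alt = "T",
    mt_alt = rep_len(mt_alt, m), mt_total = rep_len(mt_total, m),
    called = rep_len(called, m), stringsAsFactors = FALSE)
  d <- d[seq_len(n), , drop = FALSE]
  if (!is.null(vaf)) {
    d$mt_alt <- round(rep_len(vaf, n) * d$mt_total)
  }
  d$vaf <- d$mt_alt / d$mt_total
  if (!is.null(context)) d$context <- rep_len(context, n)
  if (!is.null(mutation_class)) d$mutation_class <- mutation_class
  d
}

# a burden profile built from explicit per-substitution counts: covered
# pyrimidine sites split evenly over flanks
make_burden <- function(sample_id, n_c_sites, n_t_sites, counts) {
  # counts: named vector over the 6 substitution types (variant counts)
  ctx_c <- rep(c("ACA", "ACG", "CCT", "GCA"), length.out = n_c_sites)
  ctx_t <- rep(c("ATA", "ATG", "CTT", "GTA"), length.out = n_t_sites)
  vars <- list()
  for (sub in names(counts)) {
    k <- counts[[sub]]
    if (k == 0) next
    ref <- substr(sub, 1, 1); alt <- substr(sub, 3, 3)
    trip <- if (ref == "C") ctx_c[seq_len(k)] else ctx_t[seq_len(k)]
    vars[[sub]] <- data.frame(
      patient_id = "P1", sample_id = sample_id, chrom = "chr1",
      pos = seq_len(k), ref = ref, alt = alt, mt_alt = 20,
      mt_total = 1000, vaf = 0.02, called = TRUE,
      context = canonical_context(trip, ref, alt),
      stringsAsFactors = FALSE)
  }
  v <- if (length(vars)) do.call(rbind, vars) else
    make_variants(0)
  rare_subclonal_burden(v, c(ctx_c, ctx_t))
}

# small cached cohort shared across tests (deterministic)
shared_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- simulate_cohort(sim_config(n_patients = 10,
                                                       seed = 42))
    co
  }
})
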
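# Readers, writers and validation for the flat tables the pipeline
# consumes: UMI-collapsed variant tables (TSV), allele-specific copy
# number segments (TSV), panel ROI intervals (BED, converted to 1-based),
# sample metadata (TSV), and trinucleotide-context annotation.

VARIANT_REQUIRED_COLS <- c("patient_id", "sample_id", "chrom", "pos",
                           "ref", "alt", "mt_alt", "mt_total", "called")

#' Validate a variant table in place
#'
#' Enforces the row invariants: 0 <= mt_alt <= mt_total, pos >= 1,
#' ref != alt, and vaf == mt_alt/mt_total (recomputed when absent).
#' Errors name the offending row.
#' @param x data.frame of variant calls.
#' @return the validated data.frame with a `vaf` column.
#' @export
validate_variant_table <- function(x) {
  missing_cols <- setdiff(VARIANT_REQUIRED_COLS, names(x))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("variant table row %d: %s", i[1], what), call. = FALSE)
  }
  bad(x$mt_alt < 0 | x$mt_total < 1, "mt counts out of range")
  bad(x$mt_alt > x$mt_total, "mt_alt > mt_total")
  bad(x$pos < 1, "pos must be >= 1")
  bad(x$ref == x$alt, "ref equals alt")
  v <- x$mt_alt / x$mt_total
  if (!is.null(x$vaf)) {
    bad(abs(x$vaf - v) > 1e-6, "vaf inconsistent with mt_alt/mt_total")
  }
  x$vaf <- v
  x$called <- as.logical(x$called)
  x
}

#' Read a UMI-collapsed variant table (TSV)
#'
#' Required columns: patient_id, sample_id, chrom, pos, ref, alt, mt_alt,
#' mt_total, called. Optional columns (vaf, context, mutation_class, and
#' any extras) are preserved; `vaf` is recomputed and checked.
#'
#' @param path TSV file path.
#' @return validated data.frame, one row per variant observation.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_variant_table(x)
}

#' Write a variant table as TSV
#' @param x variant data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments (TSV)
#'
#' Columns: chrom, start, end (1-based inclusive), major_cn, minor_cn.
#' Segments must be non-overlapping within a chromosome.
#' @param path TSV path.
#' @return validated data.frame of segments.
#' @export
read_cn_segments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cn_segments(x)
}

#' @rdname read_cn_segments
#' @param x data.frame of segments to validate.
#' @export
validate_cn_segments <- function(x) {
  need <- c("chrom", "start", "end", "major_cn", "minor_cn")
  if (!all(need %in% names(x)))
    stop("copy-number table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(x$start > x$end)) stop("segment with start > end", call. = FALSE)
  if (any(x$minor_cn > x$major_cn) || any(x$minor_cn < 0))
    stop("need major_cn >= minor_cn >= 0", call. = FALSE)
  for (ch in unique(x$chrom)) {
    seg <- x[x$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping copy-number segments on ", ch, call. = FALSE)
  }
  x
}

#' Look up the copy-number segment covering a position
#' @param segments data.frame from [read_cn_segments()].
#' @param chrom,pos query coordinate (1-based).
#' @return the covering one-row data.frame, or NULL when no segment
#'   covers the position.
#' @export
cn_lookup <- function(segments, chrom, pos) {
  hit <- segments$chrom == chrom & segments$start <= pos &
    segments$end >= pos
  if (!any(hit)) return(NULL)
  segments[which(hit)[1], , drop = FALSE]
}

#' Read panel regions of interest from BED
#'
#' BED is 0-based half-open; coordinates are converted to 1-based
#' inclusive on read. Region lengths must lie in \[1, 10000\].
#' @param path BED path (3+ columns, no header).
#' @return data.frame with chrom, start, end (1-based inclusive) and
#'   name (if present).
#' @export
read_roi_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- x[[4]]
  len <- out$end - out$start + 1L
  if (any(len < 1) || any(len > 10000))
    stop("ROI length out of [1, 10000]", call. = FALSE)
  out
}

#' Read block-level tumor sample metadata (TSV)
#'
#' Columns: patient_id, sample_id, block_id, role (primary/metastasis),
#' purity in (0,1], ploidy > 0, preservation (FFPE/frozen), udg_treated
#' (logical), optional block_age_years.
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_metadata(x)
}

#' @rdname read_sample_metadata
#' @param x data.frame to validate.
#' @export
validate_sample_metadata <- function(x) {
  need <- c("patient_id", "sample_id", "role", "purity", "ploidy",
            "preservation", "udg_treated")
  if (!all(need %in% names(x)))
    stop("sample metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(x$purity <= 0) || any(x$purity > 1))
    stop("purity must be in (0,1]", call. = FALSE)
  if (any(x$ploidy <= 0)) stop("ploidy must be > 0", call. = FALSE)
  if (!all(x$role %in% c("primary", "metastasis")))
    stop("role must be primary or metastasis", call. = FALSE)
  x$udg_treated <- as.logical(x$udg_treated)
  x
}

reverse_complement <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Canonical pyrimidine-centered context class
#'
#' Collapses a reference trinucleotide and substitution to one of the 96
#' signature-analysis classes (6 pyrimidine substitution types x 16
#' flanks), reverse-complementing when the reference base is a purine.
#'
#' @param triplet reference trinucleotide centered on the variant site.
#' @param ref,alt reference and alternate base of the substitution.
#' @return class string like "A\[C>T\]G" (vectorized).
#' @examples
#' canonical_context("ACG", "C", "T")  # "A[C>T]G"
#' canonical_context("TGA", "G", "A")  # "T[C>T]A" (reverse-complemented)
#' @export
canonical_context <- function(triplet, ref, alt) {
  triplet <- toupper(triplet); ref <- toupper(ref); alt <- toupper(alt)
  if (any(substr(triplet, 2, 2) != ref))
    stop("triplet center does not match ref base", call. = FALSE)
  flip <- ref %in% c("A", "G")
  triplet[flip] <- reverse_complement(triplet[flip])
  alt[flip] <- reverse_complement(alt[flip])
  ref[flip] <- substr(triplet[flip], 2, 2)
  paste0(substr(triplet, 1, 1), "[", ref, ">", alt, "]",
         substr(triplet, 3, 3))
}

#' All 96 canonical (context, substitution) classes
#' @return character vector of length 96, in substitution-major order.
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (b5 in bases) for (b3 in bases)
    out <- c(out, paste0(b5, "[", s, "]", b3))
  out
}

#' Substitution type of a canonical context class
#' @param class canonical class strings like "A\[C>T\]G".
#' @return substitution strings like "C>T".
#' @export
context_substitution <- function(class) {
  sub("^.\\[(.>.)\\].$", "\\1", class)
}

#' Annotate variants with canonical trinucleotide context
#'
#' Resolves each SNV's reference trinucleotide either from a pre-supplied
#' `context` column (raw reference triplets or already-canonical class
#' strings) or from a reference genome, then stores the canonical
#' pyrimidine-centered class in `context`. Idempotent.
#'
#' @param variants validated variant data.frame.
#' @param reference NULL (use the `context` column), a named character
#'   vector of chromosome sequences, or a FASTA path (read with
#'   Biostrings).
#' @return the data.frame with canonical `context`.
#' @export
annotate_context <- function(variants, reference = NULL) {
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  if (is.null(reference)) {
    if (is.null(variants$context))
      stop("no context column and no reference supplied", call. = FALSE)
    ctx <- variants$context
    canonical <- grepl("^.\\[.>.\\].$", ctx)
    out <- ctx
    raw <- snv & !canonical & !is.na(ctx)
    out[raw] <- canonical_context(ctx[raw], variants$ref[raw],
                                  variants$alt[raw])
    variants$context <- out
    return(variants)
  }
  seqs <- reference
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read a FASTA reference",
           call. = FALSE)
    dna <- Biostrings::readDNAStringSet(reference)
    names(dna) <- sub("\\s.*", "", names(dna))
    seqs <- vapply(seq_along(dna), function(i) as.character(dna[[i]]),
                   character(1))
    names(seqs) <- names(dna)
  }
  ctx <- rep(NA_character_, nrow(variants))
  for (i in which(snv)) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    if (!chrom %in% names(seqs))
      stop("chromosome not in reference: ", chrom, call. = FALSE)
    triplet <- toupper(substr(seqs[[chrom]], pos - 1, pos + 1))
    if (substr(triplet, 2, 2) != toupper(variants$ref[i]))
      stop(sprintf(
        "reference mismatch at %s:%d (table says %s, FASTA says %s)",
        chrom, pos, variants$ref[i], substr(triplet, 2, 2)), call. = FALSE)
    ctx[i] <- canonical_context(triplet, variants$ref[i], variants$alt[i])
  }
  variants$context <- ctx
  variants
}

#' Export called variants as a minimal VCF
#'
#' CHROM, POS, REF, ALT plus INFO fields MTA (alt molecular tags) and MTT
#' (total molecular tags). Not a full VCF writer.
#' @param variants validated variant data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf_minimal <- function(variants, path) {
  v <- variants[variants$called, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MTA,Number=1,Type=Integer,Description=\"Alt molecular tags\">",
               "##INFO=<ID=MTT,Number=1,Type=Integer,Description=\"Total molecular tags\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMTA=%d;MTT=%d",
                       v$chrom, v$pos, v$ref, v$alt, v$mt_alt, v$mt_total),
               con)
  invisible(path)
}
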
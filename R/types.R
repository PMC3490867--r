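#' Construct a mature miRNA record
#'
#' A mature miRNA sequence in 5'->3' orientation with its derived seed
#' subsequences. Seed positions follow the standard 1-based miRNA numbering:
#' `seed6` spans nucleotides 2-7 (the canonical seed), `seed7` spans
#' nucleotides 2-8 (the extended seed used for accessibility assessment and
#' as the family key).
#'
#' @param name miRNA identifier.
#' @param sequence RNA string (A/C/G/U), length 18-25 nt.
#' @return An object of class `MatureMiRNA` with fields `name`, `sequence`,
#'   `seed6`, `seed7`, `family_key`.
#' @examples
#' mir <- mature_mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' mir$seed7
#' @export
mature_mirna <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (grepl("T", sequence)) sequence <- dna_to_rna(sequence)
  if (!grepl("^[ACGU]+$", sequence))
    stop("miRNA sequence must use the RNA alphabet {A,C,G,U}: ", name)
  if (nchar(sequence) < 18L || nchar(sequence) > 25L)
    stop("mature miRNA length must be within [18,25] nt: ", name)
  structure(
    list(name = as.character(name),
         sequence = sequence,
         seed6 = substr(sequence, 2L, 7L),
         seed7 = substr(sequence, 2L, 8L),
         family_key = substr(sequence, 2L, 8L)),
    class = "MatureMiRNA")
}

#' @export
print.MatureMiRNA <- function(x, ...) {
  cat(sprintf("<MatureMiRNA %s: %s (seed7 %s)>\n", x$name, x$sequence, x$seed7))
  invisible(x)
}

#' Construct a 3'-UTR allele record
#'
#' Coordinates are 0-based half-open on the genome; `sequence` is stored in
#' transcription (sense) orientation, so minus-strand records hold the
#' reverse complement of the genomic slice. `known_mask` lists 0-based
#' sequence offsets whose base is unknown (e.g. prematurely truncated
#' allele sequences); downstream classification refuses to call a site
#' "disrupted" when its span overlaps unknown sequence.
#'
#' @param gene_id,transcript_id identifiers.
#' @param contig contig/chromosome name.
#' @param start,end 0-based half-open genomic interval, `end > start`.
#' @param strand `"+"` or `"-"`.
#' @param sequence DNA string (A/C/G/T/N), sense orientation,
#'   `nchar(sequence) == end - start`.
#' @param known_mask integer vector of 0-based offsets with unknown base.
#' @return An object of class `UTRRecord`.
#' @export
utr_record <- function(gene_id, transcript_id, contig, start, end, strand,
                       sequence, known_mask = integer(0)) {
  start <- as.integer(start); end <- as.integer(end)
  sequence <- toupper(as.character(sequence))
  if (end <= start) stop("UTR interval must satisfy end > start: ", gene_id)
  if (nchar(sequence) != end - start)
    stop("sequence length must equal end - start for ", gene_id)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("UTR sequence alphabet must be {A,C,G,T,N}: ", gene_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  known_mask <- sort(unique(as.integer(known_mask)))
  if (length(known_mask) && (min(known_mask) < 0L || max(known_mask) >= end - start))
    stop("known_mask offsets out of range for ", gene_id)
  structure(
    list(gene_id = as.character(gene_id),
         transcript_id = as.character(transcript_id),
         contig = as.character(contig), start = start, end = end,
         strand = strand, sequence = sequence, known_mask = known_mask),
    class = "UTRRecord")
}

#' @export
print.UTRRecord <- function(x, ...) {
  cat(sprintf("<UTRRecord %s/%s %s:%d-%d(%s) %d nt%s>\n", x$gene_id,
              x$transcript_id, x$contig, x$start, x$end, x$strand,
              nchar(x$sequence),
              if (length(x$known_mask)) sprintf(", %d masked", length(x$known_mask)) else ""))
  invisible(x)
}

#' Construct a biallelic SNP record
#'
#' Positions use the 1-based VCF convention and are converted to 0-based
#' offsets only at the sequence boundary ([apply_variant()]). `allele_counts`
#' is a named list of `c(ref_reads, alt_reads)` per sample. `depth` is the
#' caller's reported depth and is not required to equal the allele-count sum.
#'
#' @param contig contig name.
#' @param position 1-based genome coordinate.
#' @param ref_allele,alt_allele single DNA bases, distinct.
#' @param quality phred-scaled call quality (>= 0).
#' @param depth total read depth at the site.
#' @param allele_counts named list of two-element non-negative integer
#'   vectors `c(ref, alt)`.
#' @param provenance `"novel"`, `"known"` or `"both"`.
#' @return An object of class `SNPRecord`; `$snp_id` is
#'   `contig:position:ref>alt`.
#' @export
snp_record <- function(contig, position, ref_allele, alt_allele,
                       quality = 0, depth = 0, allele_counts = list(),
                       provenance = c("novel", "known", "both")) {
  provenance <- match.arg(provenance)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L)
    stop("only single-base substitutions are supported")
  if (ref_allele == alt_allele) stop("ref and alt alleles must differ")
  if (quality < 0) stop("SNP quality must be >= 0")
  for (ac in allele_counts) {
    if (length(ac) != 2L || any(ac < 0)) stop("allele counts must be c(ref, alt) >= 0")
  }
  structure(
    list(contig = as.character(contig), position = as.integer(position),
         ref_allele = ref_allele, alt_allele = alt_allele,
         quality = as.numeric(quality), depth = as.integer(depth),
         allele_counts = allele_counts, provenance = provenance,
         snp_id = sprintf("%s:%d:%s>%s", contig, as.integer(position),
                          ref_allele, alt_allele)),
    class = "SNPRecord")
}

#' @export
print.SNPRecord <- function(x, ...) {
  cat(sprintf("<SNPRecord %s qual=%g depth=%d %s>\n", x$snp_id, x$quality,
              x$depth, x$provenance))
  invisible(x)
}

#' Pipeline configuration
#'
#' Houses every tunable threshold of the analysis. Defaults are the
#' published operating point of the workflow this package implements:
#' minimum SNP quality 50 and depth 15 (inclusive), UTR "covered" above 50%
#' (strict), read length per sequencing dataset (35/50/70/90 bp) with 2
#' mismatches for mappability, a 2x-read-length averaging window retaining
#' only SNPs at average mappability exactly 1, a perturbation score delta of
#' >2 units, co-expression gates of >10 miRNA reads and >1 FPKM (strict),
#' an allele-specific-expression alpha of 0.001 and a cross-tissue Fisher
#' alpha of 0.05.
#'
#' `context_scale` and `position_bonus` parameterise the simplified
#' three-term context score (see [context_score()]); scores are expressed in
#' "units" of `context_scale` times the raw term sum so realistic deltas are
#' commensurate with the >2-unit perturbation rule.
#'
#' @param min_snp_quality,min_depth inclusive SNP filters.
#' @param coverage_fraction_threshold strict lower bound for "covered".
#' @param read_length read length L for mappability (one of 35/50/70/90 in
#'   the source datasets; any positive L is accepted).
#' @param mismatches mismatches m allowed when assessing mappability.
#' @param mappability_retain_value retained iff window average equals this.
#' @param perturbation_delta strict score-difference threshold (units).
#' @param coexpr_min_mirna_reads,coexpr_min_fpkm strict co-expression gates.
#' @param ase_alpha binomial ASE significance threshold.
#' @param allelic_fisher_alpha cross-tissue Fisher significance threshold.
#' @param folding_window width (nt) of the folding window for accessibility.
#' @param context_scale,position_bonus context-score constants.
#' @param strand_mode `"forward"` or `"both"` for mappability counting.
#' @param rng_seed integer seed threaded through every stochastic step.
#' @return An object of class `PipelineConfig` (a named list).
#' @export
pipeline_config <- function(min_snp_quality = 50,
                            min_depth = 15,
                            coverage_fraction_threshold = 0.5,
                            read_length = 35L,
                            mismatches = 2L,
                            mappability_retain_value = 1.0,
                            perturbation_delta = 2.0,
                            coexpr_min_mirna_reads = 10,
                            coexpr_min_fpkm = 1.0,
                            ase_alpha = 0.001,
                            allelic_fisher_alpha = 0.05,
                            folding_window = 150L,
                            context_scale = 10,
                            position_bonus = 0.3,
                            strand_mode = c("forward", "both"),
                            rng_seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  cfg <- list(min_snp_quality = min_snp_quality, min_depth = min_depth,
              coverage_fraction_threshold = coverage_fraction_threshold,
              read_length = as.integer(read_length),
              mismatches = as.integer(mismatches),
              mappability_window = 2L * as.integer(read_length),
              mappability_retain_value = mappability_retain_value,
              perturbation_delta = perturbation_delta,
              coexpr_min_mirna_reads = coexpr_min_mirna_reads,
              coexpr_min_fpkm = coexpr_min_fpkm,
              ase_alpha = ase_alpha,
              allelic_fisher_alpha = allelic_fisher_alpha,
              folding_window = as.integer(folding_window),
              context_scale = context_scale,
              position_bonus = position_bonus,
              strand_mode = strand_mode,
              rng_seed = as.integer(rng_seed))
  num <- vapply(cfg[!(names(cfg) %in% "strand_mode")], as.numeric, numeric(1))
  if (any(num < 0)) stop("all thresholds must be non-negative")
  if (cfg$read_length <= 0L) stop("read_length must be positive")
  structure(cfg, class = c("PipelineConfig", "list"))
}

# empty site table with the TargetSite schema
empty_sites <- function() {
  data.frame(utr_id = character(0), mirna_name = character(0),
             start = integer(0), end = integer(0),
             site_type = character(0), predictor = character(0),
             score = numeric(0), accessible = logical(0),
             stringsAsFactors = FALSE)
}
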
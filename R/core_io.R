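#' Extract 3'-UTR sequences from a genome
#'
#' Slices annotated 3'-UTR intervals out of a genome and returns sense-
#' orientation records: minus-strand intervals are reverse complemented, so
#' every downstream site scan runs 5'->3' on the transcribed strand.
#' Coordinates are preserved as annotated (0-based half-open).
#'
#' @param genome named character vector (or `Biostrings::DNAStringSet`)
#'   mapping contig names to sequences.
#' @param annotation data.frame with columns `gene_id`, `transcript_id`,
#'   `contig`, `start`, `end`, `strand` (see [read_utr_annotation()]).
#' @return list of [utr_record()] objects.
#' @export
extract_utr_sequences <- function(genome, annotation) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  need <- c("gene_id", "transcript_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    if (!a$contig %in% names(genome))
      stop("contig not in genome for record ", a$transcript_id, ": ", a$contig)
    clen <- nchar(genome[[a$contig]])
    if (a$start < 0 || a$end > clen)
      stop("interval [", a$start, ",", a$end, ") exceeds contig '", a$contig,
           "' bounds (length ", clen, ") for record ", a$transcript_id)
    s <- substr(genome[[a$contig]], a$start + 1L, a$end)
    if (a$strand == "-") s <- revcomp_dna(s)
    utr_record(a$gene_id, a$transcript_id, a$contig, a$start, a$end,
               a$strand, s)
  })
}

#' Apply a single-base substitution to a 3'-UTR allele
#'
#' Produces the variant allele of a UTR. The SNP is given in genome
#' coordinates with genome-strand alleles; for minus-strand UTRs both
#' alleles are complemented onto the sense strand. The reference base at the
#' mapped offset must match `ref_allele`, otherwise a consistency error is
#' raised. Applying the allele-swapped SNP to the result returns the
#' original sequence (involution).
#'
#' @param utr a [utr_record()].
#' @param snp a [snp_record()] falling inside the UTR interval.
#' @return a new `UTRRecord` differing from `utr` at exactly one offset;
#'   `known_mask` is carried over unchanged.
#' @export
apply_variant <- function(utr, snp) {
  g0 <- snp$position - 1L                      # 0-based genome position
  if (snp$contig != utr$contig || g0 < utr$start || g0 >= utr$end)
    stop("SNP ", snp$snp_id, " outside UTR ", utr$transcript_id,
         " [", utr$start, ",", utr$end, ")")
  if (utr$strand == "+") {
    off <- g0 - utr$start
    ref_sense <- snp$ref_allele
    alt_sense <- snp$alt_allele
  } else {
    off <- utr$end - 1L - g0
    ref_sense <- comp_dna(snp$ref_allele)
    alt_sense <- comp_dna(snp$alt_allele)
  }
  have <- substr(utr$sequence, off + 1L, off + 1L)
  if (have != ref_sense)
    stop("reference allele mismatch at ", snp$snp_id, ": UTR has '", have,
         "' (sense), expected '", ref_sense, "'")
  seq2 <- utr$sequence
  substr(seq2, off + 1L, off + 1L) <- alt_sense
  out <- utr
  out$sequence <- seq2
  out
}

# 0-based offset of a SNP within a UTR's sense sequence
snp_utr_offset <- function(utr, snp) {
  g0 <- snp$position - 1L
  if (utr$strand == "+") g0 - utr$start else utr$end - 1L - g0
}

#' Collapse identical 3'-UTR alleles
#'
#' Deduplication key is exact string identity of the full sequence (N is a
#' literal). The first-seen record is kept as the representative.
#'
#' @param records list of [utr_record()] objects.
#' @return `list(unique = <representatives>, multiplicity = <named integer
#'   vector keyed by sequence>)`; multiplicities sum to `length(records)`.
#' @export
deduplicate_utrs <- function(records) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  mult <- table(factor(seqs, levels = unique(seqs)))
  keep <- !duplicated(seqs)
  list(unique = records[keep],
       multiplicity = setNames(as.integer(mult), names(mult)))
}

#' Column-wise nucleotide variation of aligned sequences
#'
#' Fraction of alignment columns that are polymorphic: a column is eligible
#' when it holds at least two non-gap characters, and polymorphic when it
#' holds at least two distinct non-gap, non-N characters. Returns 0 when no
#' column is eligible. Gap characters are `-` and `.`.
#'
#' @param aligned character vector of >= 2 equal-length gapped sequences.
#' @return fraction in `[0, 1]`.
#' @export
nucleotide_variation <- function(aligned) {
  if (length(aligned) < 2L) stop("need at least two aligned sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  eligible <- 0L
  poly <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    nongap <- col[!col %in% c("-", ".")]
    if (length(nongap) >= 2L) {
      eligible <- eligible + 1L
      if (length(unique(nongap[nongap != "N"])) >= 2L) poly <- poly + 1L
    }
  }
  if (eligible == 0L) return(0)
  poly / eligible
}

## ---- standard-format I/O -------------------------------------------------

#' Read a genome (or any) FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences (uppercase).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chartr("U", "T", seqs)), path)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#' @param path FASTA of mature miRNAs (RNA or DNA alphabet; T is read as U).
#' @return list of [mature_mirna()] objects.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  mapply(mature_mirna, nm, toupper(as.character(ss)),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write mature miRNAs to FASTA
#' @param mirnas list of [mature_mirna()] objects.
#' @param path output file.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  lines <- unlist(lapply(mirnas, function(m) c(paste0(">", m$name), m$sequence)))
  writeLines(lines, path)
  invisible(path)
}

#' Read 3'-UTR annotation from BED or GFF3
#'
#' BED input uses the 6-column dialect (name = `gene_id|transcript_id`, or
#' just the gene id). GFF3 input keeps `three_prime_UTR` features and reads
#' `gene_id`/`ID` (or `Parent`) attributes.
#'
#' @param path `.bed`, `.gff3` or `.gff` file.
#' @return data.frame with columns `gene_id`, `transcript_id`, `contig`,
#'   `start`, `end`, `strand` (0-based half-open coordinates).
#' @export
read_utr_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("type" %in% names(md)) {         # GFF3
    keep <- md$type == "three_prime_UTR"
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]
    gene <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else
      as.character(md$ID)
    tx <- if ("ID" %in% names(md)) as.character(md$ID) else gene
    tx[is.na(tx)] <- gene[is.na(tx)]
  } else {                             # BED
    nm <- as.character(md$name)
    parts <- strsplit(nm, "|", fixed = TRUE)
    gene <- vapply(parts, `[`, character(1), 1L)
    tx <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L],
                 character(1))
  }
  data.frame(gene_id = gene, transcript_id = tx,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a UTR annotation as 6-column BED
#' @param utrs list of [utr_record()] objects or an annotation data.frame.
#' @param path output BED file.
#' @export
write_utr_bed <- function(utrs, path) {
  if (is.data.frame(utrs)) {
    df <- utrs
  } else {
    df <- do.call(rbind, lapply(utrs, function(u) {
      data.frame(gene_id = u$gene_id, transcript_id = u$transcript_id,
                 contig = u$contig, start = u$start, end = u$end,
                 strand = u$strand, stringsAsFactors = FALSE)
    }))
  }
  bed <- data.frame(df$contig, df$start, df$end,
                    paste(df$gene_id, df$transcript_id, sep = "|"),
                    0L, df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNPs from a VCF
#'
#' QUAL supplies the call quality, `INFO/DP` the depth and per-sample
#' `FORMAT/AD` the allele read counts. Multi-allelic records are split into
#' biallelic records. Provenance is read from `INFO/PROV` when present.
#'
#' @param path VCF (v4.x) file, plain text.
#' @return list of [snp_record()] objects.
#' @export
read_snps_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "custom")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  qual <- rr$QUAL
  info <- VariantAnnotation::info(vcf)
  dp <- if ("DP" %in% names(info)) info$DP else rep(0L, length(rr))
  prov <- if ("PROV" %in% names(info)) as.character(info$PROV)
          else rep("novel", length(rr))
  gen <- VariantAnnotation::geno(vcf)
  ad <- if ("AD" %in% names(gen)) gen$AD else NULL
  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    if (nchar(ref[i]) != 1L || nchar(alt[i]) != 1L) next  # substitutions only
    ac <- list()
    if (!is.null(ad)) {
      # Number=R fields come back as a 3-d array (variant x sample x allele)
      # or as a matrix of lists, depending on ploidy of the file
      for (s in seq_len(dim(ad)[2])) {
        v <- if (length(dim(ad)) == 3L) ad[i, s, ] else ad[i, s][[1]]
        if (length(v) >= 2L && !any(is.na(v)))
          ac[[colnames(ad)[s]]] <- as.integer(v[1:2])
      }
    }
    out[[i]] <- snp_record(
      as.character(GenomicRanges::seqnames(rr))[i],
      GenomicRanges::start(rr)[i], ref[i], alt[i],
      quality = ifelse(is.na(qual[i]), 0, qual[i]),
      depth = ifelse(is.na(dp[i]), 0L, dp[i]),
      allele_counts = ac,
      provenance = if (prov[i] %in% c("novel", "known", "both")) prov[i] else "novel")
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write SNP records as a minimal VCF v4.2
#'
#' Emits QUAL, `INFO/DP`, `INFO/PROV` and per-sample `FORMAT/GT:AD` so that
#' [read_snps_vcf()] round-trips every field. A `FILTER` annotation may be
#' attached per record via `filters`.
#'
#' @param snps list of [snp_record()] objects.
#' @param path output file.
#' @param filters optional character vector (one per SNP) for the FILTER
#'   column; default `"."`.
#' @export
write_snps_vcf <- function(snps, path, filters = NULL) {
  samples <- unique(unlist(lapply(snps, function(s) names(s$allele_counts))))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=PROV,Number=1,Type=String,Description=\"SNP provenance\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read counts\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) c("FORMAT", samples)),
                 collapse = "\t"))
  if (is.null(filters)) filters <- rep(".", length(snps))
  rows <- vapply(seq_along(snps), function(i) {
    s <- snps[[i]]
    cells <- c(s$contig, s$position, s$snp_id, s$ref_allele, s$alt_allele,
               format(s$quality, trim = TRUE), filters[i],
               sprintf("DP=%d;PROV=%s", s$depth, s$provenance))
    if (length(samples)) {
      cells <- c(cells, "GT:AD",
                 vapply(samples, function(sm) {
                   ac <- s$allele_counts[[sm]]
                   if (is.null(ac)) "./.:.,." else
                     sprintf("0/1:%d,%d", ac[1], ac[2])
                 }, character(1)))
    }
    paste(cells, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write UTR allele sequences to FASTA (headers carry coordinates)
#' @param utrs list of [utr_record()] objects.
#' @param path output file.
#' @export
write_utr_fasta <- function(utrs, path) {
  lines <- unlist(lapply(utrs, function(u) {
    c(sprintf(">%s|%s|%s:%d-%d(%s)", u$gene_id, u$transcript_id, u$contig,
              u$start, u$end, u$strand), u$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base depth track from a BedGraph-like TSV
#'
#' Four columns (contig, start, end, depth), 0-based half-open, no header.
#'
#' @param path BedGraph file.
#' @param contig_lengths named integer vector giving full contig lengths
#'   (positions not covered by any interval get depth 0).
#' @return object of class `DepthTrack`: `list(depth = <named list of
#'   integer vectors>)`.
#' @export
read_depth_bedgraph <- function(path, contig_lengths) {
  bg <- read.delim(path, header = FALSE,
                   col.names = c("contig", "start", "end", "depth"),
                   stringsAsFactors = FALSE)
  depth <- lapply(contig_lengths, function(n) integer(n))
  for (i in seq_len(nrow(bg))) {
    ctg <- bg$contig[i]
    if (!ctg %in% names(depth)) stop("bedgraph contig not in genome: ", ctg)
    idx <- (bg$start[i] + 1L):bg$end[i]
    depth[[ctg]][idx] <- bg$depth[i]
  }
  structure(list(depth = depth), class = "DepthTrack")
}

#' Write a per-position integer track as BedGraph (run-length merged)
#' @param values named list of integer vectors (per contig, value per
#'   position starting at 0).
#' @param path output file.
#' @export
write_bedgraph <- function(values, path) {
  rows <- list()
  for (ctg in names(values)) {
    v <- values[[ctg]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    rows[[ctg]] <- data.frame(ctg, starts, ends, r$values)
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param track a `DepthTrack`.
#' @export
write_depth_bedgraph <- function(track, path) write_bedgraph(track$depth, path)

# plain TSV helpers used by the CLI and pipeline reports
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
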
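test_that("domain type constructors enforce their invariants", {
  m <- mature_mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(m$seed6, "GAGGUA")
  expect_equal(m$seed7, "GAGGUAG")
  expect_identical(m$family_key, m$seed7)
  expect_error(mature_mirna("x", "ACGU"), "length")
  expect_error(mature_mirna("x", strrep("ACGX", 5)), "alphabet")

  expect_error(utr_record("g", "t", "c", 10, 10, "+", ""), "end > start")
  expect_error(utr_record("g", "t", "c", 0, 4, "+", "ACG"), "length")
  expect_error(utr_record("g", "t", "c", 0, 4, "+", "ACGT", known_mask = 4),
               "known_mask")

  expect_error(snp_record("c", 5, "A", "A"), "differ")
  expect_error(snp_record("c", 5, "AC", "G"), "single-base")
  s <- snp_record("c", 5, "A", "G", quality = 60, depth = 20)
  expect_equal(s$snp_id, "c:5:A>G")
})

test_that("extract_utr_sequences slices and orients correctly", {
  genome <- c(ctg = "AACCGGTT")
  ann <- data.frame(gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"),
                    contig = "ctg", start = c(2L, 0L), end = c(6L, 4L),
                    strand = c("+", "-"))
  utrs <- extract_utr_sequences(genome, ann)
  expect_equal(utrs[[1]]$sequence, "CCGG")
  expect_equal(utrs[[2]]$sequence, "GGTT")   # revcomp of "AACC"
  bad <- data.frame(gene_id = "g", transcript_id = "t", contig = "ctg",
                    start = 5L, end = 12L, strand = "+")
  expect_error(extract_utr_sequences(genome, bad), "bounds")
})

test_that("apply_variant substitutes exactly one sense-strand base", {
  u <- utr_record("g", "t", "c", 100L, 110L, "+", "AAAAAAAAAA")
  s <- snp_record("c", 106L, "A", "G")   # 1-based VCF pos for offset 5
  v <- apply_variant(u, s)
  expect_equal(v$sequence, "AAAAAGAAAA")
  expect_identical(v$known_mask, u$known_mask)
  # range and consistency errors
  expect_error(apply_variant(u, snp_record("c", 100L, "A", "G")), "outside")
  expect_error(apply_variant(u, snp_record("c", 106L, "C", "G")), "mismatch")
})

test_that("minus-strand apply_variant equals re-extraction from an edited genome", {
  set.seed(42)
  for (rep in 1:5) {
    gseq <- random_seq(60)
    genome <- c(chr = gseq)
    ann <- data.frame(gene_id = "g", transcript_id = "t", contig = "chr",
                      start = 10L, end = 50L, strand = "-")
    u <- extract_utr_sequences(genome, ann)[[1]]
    pos <- sample(11:50, 1)               # 1-based genome position in UTR
    ref <- substr(gseq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- apply_variant(u, snp_record("chr", pos, ref, alt))
    g2 <- gseq
    substr(g2, pos, pos) <- alt
    u2 <- extract_utr_sequences(c(chr = g2), ann)[[1]]
    expect_equal(v$sequence, u2$sequence)
  }
})

test_that("apply_variant is an involution under allele swap", {
  set.seed(7)
  for (strand in c("+", "-")) {
    gseq <- random_seq(40)
    ann <- data.frame(gene_id = "g", transcript_id = "t", contig = "chr",
                      start = 0L, end = 40L, strand = strand)
    u <- extract_utr_sequences(c(chr = gseq), ann)[[1]]
    pos <- 17L
    ref <- substr(gseq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- apply_variant(u, snp_record("chr", pos, ref, alt))
    back <- apply_variant(v, snp_record("chr", pos, alt, ref))
    expect_equal(back$sequence, u$sequence)
  }
})

test_that("deduplicate_utrs keeps first-seen representatives and counts", {
  mk <- function(seqs) lapply(seq_along(seqs), function(i)
    utr_record(paste0("g", i), paste0("t", i), "c", 0L, nchar(seqs[i]), "+",
               seqs[i]))
  r <- deduplicate_utrs(mk(c("ACGT", "ACGT", "ACGA")))
  expect_length(r$unique, 2)
  expect_equal(r$multiplicity, c(ACGT = 2L, ACGA = 1L))
  expect_equal(r$unique[[1]]$gene_id, "g1")
  # identity case
  r2 <- deduplicate_utrs(mk(c("AAAA", "CCCC")))
  expect_length(r2$unique, 2)
  expect_true(all(r2$multiplicity == 1L))
})

test_that("44 alleles with 12 planted duplicates collapse to 32 uniques", {
  set.seed(1)
  base <- unique(replicate(40, random_seq(30)))[1:32]
  seqs <- c(base, sample(base, 12, replace = TRUE))   # 44 alleles
  seqs <- sample(seqs)
  utrs <- lapply(seq_along(seqs), function(i)
    utr_record(paste0("g", i), paste0("t", i), "c", 0L, 30L, "+", seqs[i]))
  r <- deduplicate_utrs(utrs)
  expect_length(r$unique, 32)
  expect_equal(sum(r$multiplicity), 44L)
})

test_that("nucleotide_variation matches its column definition", {
  expect_equal(nucleotide_variation(c("ACGTACGTAC", "ACGTACGTAC")), 0)
  expect_equal(nucleotide_variation(c("ACGTACGTAC", "ACGTACGTAT")), 0.1)
  expect_error(nucleotide_variation(c("ACGT", "ACG")), "equal length")
  expect_error(nucleotide_variation("ACGT"), "two")
  # gaps and N: a column needs >=2 non-gap chars to be eligible, and >=2
  # distinct non-N chars to be polymorphic
  expect_equal(nucleotide_variation(c("AC-N", "AG-N", "ACTA")), 1 / 3)
  expect_equal(nucleotide_variation(c("A-", "A-", "A-")), 0)
})

test_that("nucleotide_variation equals an independent column scan on random alignments", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    len <- sample(20:60, 1)
    al <- replicate(n, random_seq(len, c("A", "C", "G", "T", "N", "-")))
    m <- do.call(rbind, strsplit(al, ""))
    elig <- poly <- 0
    for (j in seq_len(len)) {
      cc <- m[, j]; cc <- cc[cc != "-"]
      if (length(cc) >= 2) {
        elig <- elig + 1
        if (length(unique(setdiff(cc, "N"))) >= 2) poly <- poly + 1
      }
    }
    want <- if (elig == 0) 0 else poly / elig
    expect_equal(nucleotide_variation(al), want)
  }
})

test_that("nucleotide_variation is permutation-invariant", {
  set.seed(5)
  al <- replicate(5, random_seq(40, c("A", "C", "G", "T", "-")))
  expect_equal(nucleotide_variation(al), nucleotide_variation(rev(al)))
  expect_equal(nucleotide_variation(al), nucleotide_variation(sample(al)))
})

test_that("FASTA / BED / VCF round-trips preserve fields", {
  tmp <- withr::local_tempdir()
  genome <- c(chrA = "ACGTACGTACGTACGTACGT", chrB = "TTTTACGCGCGCATTTTTTT")
  fa <- file.path(tmp, "g.fa")
  write_genome_fasta(genome, fa)
  expect_identical(read_genome_fasta(fa), genome)

  utrs <- list(utr_record("g1", "t1", "chrA", 2L, 12L, "+",
                          substr(genome[1], 3, 12)),
               utr_record("g2", "t2", "chrB", 0L, 10L, "-",
                          rcmp(substr(genome[2], 1, 10))))
  bed <- file.path(tmp, "u.bed")
  write_utr_bed(utrs, bed)
  ann <- read_utr_annotation(bed)
  expect_equal(ann$gene_id, c("g1", "g2"))
  expect_equal(ann$transcript_id, c("t1", "t2"))
  expect_equal(ann$start, c(2L, 0L))
  expect_equal(ann$end, c(12L, 10L))
  expect_equal(ann$strand, c("+", "-"))
  back <- extract_utr_sequences(genome, ann)
  expect_equal(back[[2]]$sequence, utrs[[2]]$sequence)

  snps <- list(
    snp_record("chrA", 5L, "A", "G", quality = 60, depth = 22,
               allele_counts = list(s1 = c(12L, 10L), s2 = c(0L, 9L)),
               provenance = "novel"),
    snp_record("chrB", 3L, "T", "C", quality = 51.5, depth = 15,
               allele_counts = list(s1 = c(7L, 8L), s2 = c(3L, 3L)),
               provenance = "known"))
  vcf <- file.path(tmp, "s.vcf")
  write_snps_vcf(snps, vcf)
  got <- read_snps_vcf(vcf)
  expect_length(got, 2)
  for (i in 1:2) {
    for (f in c("contig", "position", "ref_allele", "alt_allele", "quality",
                "depth", "provenance", "snp_id"))
      expect_equal(got[[i]][[f]], snps[[i]][[f]], info = f)
    expect_equal(got[[i]]$allele_counts, snps[[i]]$allele_counts)
  }

  mirs <- synth_mirnas(3, 5)
  mfa <- file.path(tmp, "m.fa")
  write_mirna_fasta(mirs, mfa)
  got_m <- read_mirna_fasta(mfa)
  expect_equal(lapply(got_m, unclass), lapply(mirs, unclass))
})

test_that("depth bedgraph round-trips through DepthTrack", {
  tmp <- withr::local_tempdir()
  lens <- c(c1 = 30L, c2 = 15L)
  set.seed(3)
  tr <- structure(list(depth = lapply(lens, function(n)
    as.integer(rpois(n, 2)))), class = "DepthTrack")
  bg <- file.path(tmp, "d.bedgraph")
  write_depth_bedgraph(tr, bg)
  got <- read_depth_bedgraph(bg, lens)
  expect_equal(got$depth, tr$depth)
})
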
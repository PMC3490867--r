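# Independent oracles and fixture builders. These deliberately use different
# code paths than the package (Biostrings reverse complement, offset-shift
# Hamming scans, log-factorial enumeration) so that each check is dual-route.

rcmp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

random_seq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# Brute-force canonical site scan: test every offset of the seed6 match
# pattern built via Biostrings, then apply the type hierarchy explicitly.
oracle_seed_sites <- function(utr, mirna) {
  dna <- chartr("U", "T", mirna$sequence)
  p6 <- rcmp(substr(dna, 2, 7))
  m8 <- rcmp(substr(dna, 8, 8))
  n <- nchar(utr)
  rows <- list()
  if (n >= 6) for (s in 0:(n - 6)) {
    if (substr(utr, s + 1, s + 6) != p6) next
    m8ok <- s >= 1 && substr(utr, s, s) == m8
    a1ok <- s + 7 <= n && substr(utr, s + 7, s + 7) == "A"
    rows[[length(rows) + 1L]] <-
      if (m8ok && a1ok) data.frame(start = s - 1, end = s + 7, site_type = "8mer")
      else if (m8ok) data.frame(start = s - 1, end = s + 6, site_type = "7mer-m8")
      else if (a1ok) data.frame(start = s, end = s + 7, site_type = "7mer-A1")
      else data.frame(start = s, end = s + 6, site_type = "6mer")
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# All-pairs Hamming mappability oracle for a single contig, via offset-shift
# cumulative sums: for each pair offset d, the Hamming distance of every
# aligned L-mer pair is a windowed sum of the per-base mismatch indicator.
oracle_mappability <- function(contig, L, m) {
  g <- strsplit(contig, "", fixed = TRUE)[[1]]
  n <- length(g)
  P <- n - L + 1L
  isN <- !(g %in% c("A", "C", "G", "T"))
  csN <- cumsum(isN)
  hasN <- (csN[L:n] - c(0, csN[seq_len(n - L)])) > 0
  hasN <- hasN[seq_len(P)]
  cnt <- rep(1L, P)
  if (P >= 2) for (d in seq_len(P - 1L)) {
    x <- g[seq_len(n - d)]
    y <- g[(1 + d):n]
    mm <- (x != y) | isN[seq_len(n - d)] | isN[(1 + d):n]
    cs <- cumsum(mm)
    npair <- P - d
    ham <- cs[L:(npair + L - 1L)] - c(0, cs[seq_len(npair - 1L)])
    ok <- which(ham <= m & !hasN[seq_len(npair)] & !hasN[seq_len(npair) + d])
    cnt[ok] <- cnt[ok] + 1L
    cnt[ok + d] <- cnt[ok + d] + 1L
  }
  cnt[hasN] <- 1L
  cnt
}

# Literal double-loop brute force (multi-contig, both-strand capable); only
# for tiny genomes.
oracle_mappability_tiny <- function(genome, L, m, both_strands = FALSE) {
  kmers <- list(); hasN <- logical(0); ctg_of <- character(0)
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    for (i in seq_len(nchar(s) - L + 1L)) {
      k <- substr(s, i, i + L - 1L)
      kmers[[length(kmers) + 1L]] <- k
      hasN <- c(hasN, grepl("[^ACGT]", k))
      ctg_of <- c(ctg_of, ctg)
    }
  }
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  P <- length(kmers)
  cnt <- rep(1L, P)
  for (i in seq_len(P)) {
    if (hasN[i]) next
    for (j in seq_len(P)) {
      if (hasN[j]) next
      if (j != i && ham(kmers[[i]], kmers[[j]]) <= m) cnt[i] <- cnt[i] + 1L
      if (both_strands && ham(kmers[[i]], rcmp(kmers[[j]])) <= m)
        cnt[i] <- cnt[i] + 1L
    }
  }
  split(cnt, factor(ctg_of, levels = names(genome)))
}

# Two-sided Fisher p by direct log-factorial enumeration of all tables with
# the observed margins.
oracle_fisher <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b; N <- m + n
  lp <- function(x) {
    lfactorial(m) - lfactorial(x) - lfactorial(m - x) +
      lfactorial(n) - lfactorial(k - x) - lfactorial(n - k + x) -
      (lfactorial(N) - lfactorial(k) - lfactorial(N - k))
  }
  xs <- max(0, k - n):min(k, m)
  p <- exp(vapply(xs, lp, numeric(1)))
  min(1, sum(p[p <= exp(lp(a)) * (1 + 1e-7)]))
}

# Closed-form two-sided exact binomial p at p = 0.5 (doubled smaller tail).
oracle_binomial <- function(a, b) {
  n <- a + b
  if (a == b) return(1)
  min(1, 2 * pbinom(min(a, b), n, 0.5))
}

# Venn regions by literal membership enumeration over key sets.
oracle_venn <- function(A, B, C) {
  keys <- unique(c(A, B, C))
  reg <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L)
  for (k in keys) {
    a <- k %in% A; b <- k %in% B; cc <- k %in% C
    idx <- if (a && !b && !cc) 1 else if (!a && b && !cc) 2
      else if (!a && !b && cc) 3 else if (a && b && !cc) 4
      else if (a && !b && cc) 5 else if (!a && b && cc) 6 else 7
    reg[idx] <- reg[idx] + 1L
  }
  reg
}

# designed accessibility fixtures (see test-target_prediction.R): miRNAs
# whose 8mer sites leave exactly 4 / exactly 3 seed positions as A in a
# T-free context, so the forced G/C duplex determines pairedness
boundary_mirna_free4 <- function()
  mature_mirna("boundary4", paste0("A", "UUUUCG", "C", strrep("A", 14)))
boundary_mirna_free3 <- function()
  mature_mirna("boundary3", paste0("A", "UUUGCG", "C", strrep("A", 14)))

make_test_utr <- function(sequence, gene = "g1", contig = "chr1",
                          start = 0L, strand = "+", mask = integer(0))
  utr_record(gene, paste0(gene, ".t1"), contig, start,
             start + nchar(sequence), strand, sequence, mask)
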
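#' Generate random mature miRNAs with distinct seeds
#'
#' Draws `n` 22-nt RNA sequences (uniform composition) with pairwise
#' distinct seed-7 subsequences. Deterministic given `rng_seed`.
#'
#' @param n number of miRNAs (>= 1; must not exceed 4^7 distinct seeds).
#' @param rng_seed integer seed.
#' @return list of [mature_mirna()] objects named `synthmiR-1..n`.
#' @export
synth_mirnas <- function(n, rng_seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (n > 4^7) stop("n exceeds the number of distinct 7-nt seeds")
  with_seed(rng_seed, {
    seqs <- character(0)
    seeds <- character(0)
    guard <- 0L
    while (length(seqs) < n) {
      s <- random_dna(22, c("A", "C", "G", "U"))
      sd <- substr(s, 2, 8)
      if (!sd %in% seeds) {
        seqs <- c(seqs, s)
        seeds <- c(seeds, sd)
      }
      guard <- guard + 1L
      if (guard > 1000L * n) stop("unable to draw distinct seeds")
    }
    mapply(mature_mirna, sprintf("synthmiR-%d", seq_len(n)), seqs,
           SIMPLIFY = FALSE, USE.NAMES = FALSE)
  })
}

# the 8-nt mRNA string forming a perfect 8mer site for `mirna`:
# complement of nt 8, then the seed6 match, then the A1 adenosine
mirna_8mer_site <- function(mirna) {
  mseq <- rna_to_dna(mirna$sequence)
  paste0(comp_dna(substr(mseq, 8, 8)), revcomp_dna(substr(mseq, 2, 7)), "A")
}

# canonical site keys of `sequence` over all miRNAs, for generation-time
# self-checks
all_site_keys <- function(sequence, mirnas) {
  unlist(lapply(mirnas, function(m) {
    st <- find_seed_sites(sequence, m)
    if (!nrow(st)) character(0)
    else paste(st$mirna_name, st$start, st$end, st$site_type, sep = "\r")
  }))
}

#' Generate a poly-miRTS scenario with planted truth
#'
#' Builds one UTR per gene (its own contig, plus strand, uniform-composition
#' random sequence) and plants biallelic SNPs of three kinds:
#' * **created** -- the reference carries an 8mer site broken at one seed
#'   position; the SNP restores it, so the site exists in the variant only;
#' * **disrupted** -- the reference carries a perfect 8mer; the SNP breaks
#'   one seed-core position, so the site exists in the reference only;
#' * **neutral** -- a substitution that changes no predicted site.
#'
#' Every placement is verified at generation time by scanning both alleles
#' against all miRNAs: the canonical site-set difference must be exactly the
#' intended one (bounded rejection sampling, default 1000 retries), so
#' recovery tests isolate pipeline defects rather than generator accidents.
#' At most one SNP is planted per gene.
#'
#' @param n_genes number of genes/UTRs.
#' @param mirnas list of [mature_mirna()] objects (e.g. [synth_mirnas()]).
#' @param n_created,n_disrupted,n_neutral planted SNP counts
#'   (sum <= `n_genes`).
#' @param utr_len UTR length in nt (>= 60).
#' @param rng_seed integer seed.
#' @param max_retries placement retries per SNP.
#' @return list with `utrs` (list of [utr_record()]), `snps` (list of
#'   [snp_record()]), `genome` (named character, one contig per gene),
#'   `mirnas`, and `truth` -- a data.frame `snp_id`, `gene`, `mirna`,
#'   `status`, `start`, `end`, `site_type` (spans of the planted 8mers;
#'   neutral SNPs have status `"neutral"` and `NA` site fields).
#' @export
synth_polymirts_scenario <- function(n_genes, mirnas, n_created,
                                     n_disrupted, n_neutral,
                                     utr_len = 300L, rng_seed = 1L,
                                     max_retries = 1000L) {
  total <- n_created + n_disrupted + n_neutral
  if (total > n_genes)
    stop("requested SNPs exceed gene capacity (one per gene)")
  if (utr_len < 60L) stop("utr_len must be >= 60")
  with_seed(rng_seed, {
    seqs <- vapply(seq_len(n_genes), function(i) random_dna(utr_len),
                   character(1))
    genes <- sprintf("gene_%03d", seq_len(n_genes))
    names(seqs) <- genes
    pick <- sample(n_genes, total)
    plan <- data.frame(
      gene_idx = pick,
      status = rep(c("created", "disrupted", "neutral"),
                   c(n_created, n_disrupted, n_neutral)),
      stringsAsFactors = FALSE)
    snps <- list()
    truth <- list()
    for (i in seq_len(nrow(plan))) {
      gi <- plan$gene_idx[i]
      status <- plan$status[i]
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        if (status == "neutral") {
          off <- sample(10:(utr_len - 10L), 1)
          ref_base <- substr(seqs[[gi]], off + 1L, off + 1L)
          alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
          ref_seq <- seqs[[gi]]
          var_seq <- ref_seq
          substr(var_seq, off + 1L, off + 1L) <- alt_base
          if (!identical(sort(all_site_keys(ref_seq, mirnas)),
                         sort(all_site_keys(var_seq, mirnas)))) next
          site <- list(start = NA_integer_, end = NA_integer_,
                       type = NA_character_, mirna = NA_character_)
        } else {
          mir <- mirnas[[sample(length(mirnas), 1)]]
          p <- sample(20:(utr_len - 30L), 1)
          d <- sample(1:6, 1)                 # defect within the seed6 core
          eight <- mirna_8mer_site(mir)
          good_base <- substr(eight, d + 1L, d + 1L)
          bad_base <- sample(setdiff(c("A", "C", "G", "T"), good_base), 1)
          ref_seq <- seqs[[gi]]
          substr(ref_seq, p + 1L, p + 8L) <- eight
          if (status == "created") {          # reference holds the broken site
            substr(ref_seq, p + d + 1L, p + d + 1L) <- bad_base
            ref_allele <- bad_base; alt_allele <- good_base
          } else {                            # reference holds the intact site
            ref_allele <- good_base; alt_allele <- bad_base
          }
          off <- p + d
          var_seq <- ref_seq
          substr(var_seq, off + 1L, off + 1L) <- alt_allele
          rk <- all_site_keys(ref_seq, mirnas)
          vk <- all_site_keys(var_seq, mirnas)
          want <- paste(mir$name, p, p + 8L, "8mer", sep = "\r")
          gained <- setdiff(vk, rk)
          lost <- setdiff(rk, vk)
          if (status == "created" &&
              !(identical(gained, want) && !length(lost))) next
          if (status == "disrupted" &&
              !(identical(lost, want) && !length(gained))) next
          site <- list(start = p, end = p + 8L, type = "8mer",
                       mirna = mir$name)
        }
        seqs[[gi]] <- ref_seq
        if (status == "neutral") {
          ref_allele <- substr(ref_seq, off + 1L, off + 1L)
          alt_allele <- alt_base
        }
        ref_n <- rbinom(1, 60, 0.5)
        snp <- snp_record(genes[gi], off + 1L, ref_allele, alt_allele,
                          quality = 99, depth = 100,
                          allele_counts = list(s1 = c(ref_n, 60L - ref_n)))
        snps[[length(snps) + 1L]] <- snp
        truth[[length(truth) + 1L]] <- data.frame(
          snp_id = snp$snp_id, gene = genes[gi], mirna = site$mirna,
          status = status, start = site$start, end = site$end,
          site_type = site$type, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("unable to place a ", status, " SNP after ", max_retries,
             " retries")
    }
    utrs <- lapply(seq_len(n_genes), function(i)
      utr_record(genes[i], paste0(genes[i], ".t1"), genes[i], 0L, utr_len,
                 "+", seqs[[i]]))
    list(utrs = utrs, snps = snps, genome = seqs, mirnas = mirnas,
         truth = do.call(rbind, truth))
  })
}

#' Generate a genome with planted (possibly diverged) repeats
#'
#' Concatenates unique random spacers with `n_copies` copies of one repeat
#' unit; copies after the first receive `divergence` random substitutions
#' each. When `L` and `m` are supplied, the expected multi-mapping status of
#' every start position lying fully inside a copy is computed directly from
#' the copy strings (pairwise Hamming distance of the aligned windows).
#'
#' @param unique_len spacer length.
#' @param repeat_len repeat-unit length (at least the read length to be
#'   tested).
#' @param n_copies number of repeat copies (>= 1).
#' @param divergence substitutions planted per additional copy.
#' @param rng_seed integer seed.
#' @param L,m optional read length / mismatches for the expectation table.
#' @return list with `genome` (named character, single contig `"chr1"`),
#'   `copies` (data.frame `start`, `end`, 0-based half-open),
#'   `divergence_sites` (list of copy-local 0-based offsets) and, when `L`
#'   is given, `expected` (data.frame `pos`, `copy`, `multi`).
#' @export
synth_repeat_genome <- function(unique_len, repeat_len, n_copies,
                                divergence = 0L, rng_seed = 1L,
                                L = NULL, m = NULL) {
  with_seed(rng_seed, {
    unit <- random_dna(repeat_len)
    copies <- character(n_copies)
    div_sites <- vector("list", n_copies)
    copies[1] <- unit
    div_sites[[1]] <- integer(0)
    if (n_copies > 1) {
      for (k in 2:n_copies) {
        s <- unit
        if (divergence > 0) {
          pos <- sample(repeat_len, divergence)
          for (q in pos) {
            old <- substr(s, q, q)
            substr(s, q, q) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          }
          div_sites[[k]] <- sort(pos - 1L)
        } else div_sites[[k]] <- integer(0)
        copies[k] <- s
      }
    }
    spacers <- vapply(seq_len(n_copies + 1L), function(i)
      random_dna(unique_len), character(1))
    parts <- character(0)
    starts <- integer(n_copies)
    at <- 0L
    for (k in seq_len(n_copies)) {
      parts <- c(parts, spacers[k])
      at <- at + unique_len
      starts[k] <- at
      parts <- c(parts, copies[k])
      at <- at + repeat_len
    }
    parts <- c(parts, spacers[n_copies + 1L])
    genome <- c(chr1 = paste(parts, collapse = ""))
    copies_df <- data.frame(start = starts, end = starts + repeat_len)
    expected <- NULL
    if (!is.null(L)) {
      if (is.null(m)) m <- 0L
      cm <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
      rows <- list()
      for (k in seq_len(n_copies)) {
        for (o in 0:(repeat_len - L)) {
          multi <- FALSE
          for (j in seq_len(n_copies)[-k]) {
            dd <- sum(cm[k, (o + 1L):(o + L)] != cm[j, (o + 1L):(o + L)])
            if (dd <= m) { multi <- TRUE; break }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            pos = starts[k] + o, copy = k, multi = multi)
        }
      }
      expected <- do.call(rbind, rows)
    }
    list(genome = genome, copies = copies_df, divergence_sites = div_sites,
         expected = expected)
  })
}

#' Sample allelic read counts at given true proportions
#'
#' Reference reads are drawn `Binomial(depth, prop)` per (snp, tissue);
#' variant reads make up the remainder. Deterministic given `rng_seed`.
#'
#' @param true_proportions data.frame `snp_id`, `tissue`, `prop` (reference-
#'   allele proportion in `[0, 1]`).
#' @param depth total reads per site (>= 1).
#' @param rng_seed integer seed.
#' @return data.frame `snp_id`, `tissue`, `ref_reads`, `var_reads`.
#' @export
synth_allelic_counts <- function(true_proportions, depth, rng_seed = 1L) {
  stopifnot(depth >= 1, all(true_proportions$prop >= 0),
            all(true_proportions$prop <= 1))
  with_seed(rng_seed, {
    ref <- rbinom(nrow(true_proportions), depth, true_proportions$prop)
    data.frame(snp_id = true_proportions$snp_id,
               tissue = true_proportions$tissue,
               ref_reads = ref, var_reads = as.integer(depth) - ref,
               stringsAsFactors = FALSE)
  })
}

#' Generate tissue expression with planted inverse miRNA/allele structure
#'
#' For each (snp, gene, mirna, status) pair, emits per-tissue miRNA read
#' counts, gene FPKM and allelic read counts such that
#' * **planted inverse pairs** satisfy the [flag_inverse_expression()] rule
#'   by construction: miRNA expression ramps up across tissues while the
#'   targeted-allele proportion ramps down (0.85 to 0.15 at `depth` reads),
#'   giving strict anti-concordance and a Fisher-significant extreme pair --
#'   verified post-generation and resampled if violated;
#' * remaining pairs alternate between **concordant** (targeted proportion
#'   ramps up with the miRNA; verified strictly ascending) and **flat**
#'   (constant miRNA expression, so no ordered tissue pair exists) -- both
#'   deterministically unflaggable.
#'
#' All pairs are co-expressed in every tissue (miRNA reads > 10, FPKM > 1).
#'
#' @param pairs data.frame `snp_id`, `gene`, `mirna`, `status`
#'   (created/disrupted), no duplicated snp_id/gene/mirna.
#' @param n_tissues number of tissues (>= 2).
#' @param inverse_pairs integer indices into `pairs` to plant as inverse.
#' @param rng_seed integer seed.
#' @param depth allelic read depth per tissue.
#' @param config a [pipeline_config()] (supplies the Fisher alpha used in
#'   the self-check).
#' @param max_retries resampling bound for the self-check.
#' @return list with `mirna_expr` (`mirna`, `tissue`, `reads`), `mrna_expr`
#'   (`gene`, `tissue`, `fpkm`), `allelic_counts` (`snp_id`, `tissue`,
#'   `ref_reads`, `var_reads`), `pairs` (input plus a `class` column) and
#'   `truth` (the planted inverse subset of `pairs`).
#' @export
synth_expression_matrix <- function(pairs, n_tissues = 3L, inverse_pairs,
                                    rng_seed = 1L, depth = 400L,
                                    config = pipeline_config(),
                                    max_retries = 100L) {
  if (n_tissues < 2L) stop("need at least two tissues")
  if (anyDuplicated(pairs$snp_id) || anyDuplicated(pairs$mirna) ||
      anyDuplicated(pairs$gene))
    stop("pairs must have unique snp_id, gene and mirna")
  stopifnot(all(pairs$status %in% c("created", "disrupted")))
  tissues <- sprintf("T%d", seq_len(n_tissues))
  with_seed(rng_seed, {
    cls <- rep(c("concordant", "flat"), length.out = nrow(pairs))
    cls[inverse_pairs] <- "inverse"
    me <- list(); ge <- list(); ac <- list()
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      ramp <- 30 * 3^(seq_len(n_tissues) - 1)    # strictly increasing reads
      mir_reads <- switch(cls[i],
                          inverse = ramp, concordant = ramp,
                          flat = rep(100, n_tissues))
      fpkm <- runif(n_tissues, 5, 50)
      tprop <- switch(cls[i],
                      inverse = seq(0.85, 0.15, length.out = n_tissues),
                      concordant = seq(0.15, 0.85, length.out = n_tissues),
                      flat = rep(0.5, n_tissues))
      ref_prop <- if (p$status == "created") 1 - tprop else tprop
      for (try in seq_len(max_retries)) {
        ref <- rbinom(n_tissues, depth, ref_prop)
        var <- as.integer(depth) - ref
        targeted <- if (p$status == "created") var else ref
        oprop <- targeted / depth
        if (cls[i] == "inverse") {
          ok <- all(diff(oprop) < 0)
          if (ok) {
            pv <- apply(combn(n_tissues, 2), 2, function(ij)
              fisher_allelic_proportion_test(c(ref[ij[1]], var[ij[1]]),
                                             c(ref[ij[2]], var[ij[2]])))
            ok <- min(pv) < config$allelic_fisher_alpha
          }
        } else if (cls[i] == "concordant") {
          ok <- all(diff(oprop) > 0)
        } else ok <- TRUE
        if (ok) break
        if (try == max_retries)
          stop("self-check failed for pair ", i, " after ", max_retries,
               " resamples")
      }
      me[[i]] <- data.frame(mirna = p$mirna, tissue = tissues,
                            reads = mir_reads, stringsAsFactors = FALSE)
      ge[[i]] <- data.frame(gene = p$gene, tissue = tissues, fpkm = fpkm,
                            stringsAsFactors = FALSE)
      ac[[i]] <- data.frame(snp_id = p$snp_id, tissue = tissues,
                            ref_reads = ref, var_reads = var,
                            stringsAsFactors = FALSE)
    }
    pairs$class <- cls
    list(mirna_expr = do.call(rbind, me), mrna_expr = do.call(rbind, ge),
         allelic_counts = do.call(rbind, ac), pairs = pairs,
         truth = pairs[pairs$class == "inverse",
                       c("snp_id", "gene", "mirna", "status")])
  })
}
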
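## Canonical site-type taxonomy (strongest first). A site matching the
## complement of miRNA nt 2-8 plus an A opposite nt 1 is an 8mer; nt 2-8
## alone a 7mer-m8; nt 2-7 plus the A1 a 7mer-A1; nt 2-7 alone a 6mer.
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

# type term of the context score (per-site-type efficacy ordering)
TYPE_TERM <- c("8mer" = 1.0, "7mer-m8" = 0.6, "7mer-A1" = 0.4, "6mer" = 0.2)

#' Find canonical seed-match target sites in a 3'-UTR
#'
#' Scans the sense-orientation UTR sequence for perfect Watson-Crick
#' complementarity to the miRNA seed and reports every occurrence of the
#' four canonical site types. Each occurrence is maximal: an 8mer is
#' reported once as an 8mer, never additionally as its nested 7mers/6mer.
#' Site spans cover the matched nucleotides including the A1 position where
#' applicable. `N` never matches, and no reported span may intersect
#' `known_mask`.
#'
#' @param utr_sequence DNA string (sense orientation, A/C/G/T/N).
#' @param mirna a [mature_mirna()].
#' @param utr_id identifier copied into the output.
#' @param known_mask 0-based offsets with unknown base; spans touching these
#'   are suppressed.
#' @return data.frame of TargetSite rows (`utr_id`, `mirna_name`, `start`,
#'   `end` 0-based half-open, `site_type`, `predictor = NA`, `score = NA`,
#'   `accessible = NA`), ordered by `start`.
#' @examples
#' let7 <- mature_mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' find_seed_sites("GGGGCTACCTCAGGGG", let7)
#' @export
find_seed_sites <- function(utr_sequence, mirna, utr_id = "utr",
                            known_mask = integer(0)) {
  utr_sequence <- toupper(utr_sequence)
  n <- nchar(utr_sequence)
  mseq <- rna_to_dna(mirna$sequence)
  site6 <- revcomp_dna(substr(mseq, 2L, 7L))   # mRNA match to seed nt 2-7
  m8c <- comp_dna(substr(mseq, 8L, 8L))        # mRNA base pairing nt 8
  if (n < 6L) return(empty_sites())
  hits <- gregexpr(paste0("(?=", site6, ")"), utr_sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(empty_sites())
  rows <- lapply(as.integer(hits), function(p) {   # p: 1-based match start
    s6 <- p - 1L                                   # 0-based seed6 start
    has_m8 <- s6 >= 1L &&
      substr(utr_sequence, s6, s6) == m8c
    has_a1 <- s6 + 7L <= n &&
      substr(utr_sequence, s6 + 7L, s6 + 7L) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer"; start <- s6 - 1L; end <- s6 + 7L
    } else if (has_m8) {
      type <- "7mer-m8"; start <- s6 - 1L; end <- s6 + 6L
    } else if (has_a1) {
      type <- "7mer-A1"; start <- s6; end <- s6 + 7L
    } else {
      type <- "6mer"; start <- s6; end <- s6 + 6L
    }
    if (length(known_mask) && any(known_mask >= start & known_mask < end))
      return(NULL)
    data.frame(utr_id = utr_id, mirna_name = mirna$name, start = start,
               end = end, site_type = type, predictor = NA_character_,
               score = NA_real_, accessible = NA, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_sites())
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Local-context score for a canonical site
#'
#' A simplified three-term surrogate for seed-context scoring: a site-type
#' term (8mer 1.0 > 7mer-m8 0.6 > 7mer-A1 0.4 > 6mer 0.2), a local-AU term
#' (fraction of A/T in the 30-nt flanks on each side, clipped at the UTR
#' ends) and a position bonus when the site start lies within 15-500 nt of
#' either UTR end. The sum is scaled by `config$context_scale` (default 10)
#' so that score "units" are commensurate with the >2-unit perturbation
#' rule. Higher means stronger predicted repression; the score is
#' deterministic in its inputs.
#'
#' @param site one TargetSite row (data.frame or list with `start`, `end`,
#'   `site_type`).
#' @param utr_sequence the UTR the site was predicted on.
#' @param mirna the targeting miRNA (unused by the surrogate terms but part
#'   of the scoring interface).
#' @param config a [pipeline_config()].
#' @return numeric score.
#' @export
context_score <- function(site, utr_sequence, mirna,
                          config = pipeline_config()) {
  if (site$site_type == "compensatory")
    stop("context_score is undefined for compensatory sites")
  if (!site$site_type %in% SITE_TYPES)
    stop("unknown site type: ", site$site_type)
  n <- nchar(utr_sequence)
  type_term <- TYPE_TERM[[site$site_type]]
  lo <- max(0L, site$start - 30L)
  hi <- min(n, site$end + 30L)
  flanks <- paste0(substr(utr_sequence, lo + 1L, site$start),
                   substr(utr_sequence, site$end + 1L, hi))
  au_term <- if (nchar(flanks) == 0L) 0 else {
    ch <- strsplit(flanks, "", fixed = TRUE)[[1]]
    mean(ch %in% c("A", "T", "U"))
  }
  d5 <- site$start
  d3 <- n - site$start
  pos_term <- if ((d5 >= 15 && d5 <= 500) || (d3 >= 15 && d3 <= 500))
    config$position_bonus else 0
  (type_term + au_term + pos_term) * config$context_scale
}

#' Assess site accessibility in the predicted secondary structure
#'
#' Folds a window of `folding_window` nt centred on the site (clipped at
#' the UTR ends) with a maximum-pairing dynamic program standing in for
#' minimum-free-energy folding, and checks whether at least four of the
#' seven UTR nucleotides pairing miRNA nt 2-8 are unpaired (in an open
#' loop). Positions falling outside the sequence are ignored; the >= 4 rule
#' applies to the positions that exist.
#'
#' @param site TargetSite row (canonical type).
#' @param utr_sequence the UTR sequence.
#' @param folding_window window width in nt (default 150).
#' @return `TRUE` if the site is accessible.
#' @export
assess_accessibility <- function(site, utr_sequence, folding_window = 150L) {
  if (!site$site_type %in% SITE_TYPES)
    stop("accessibility is assessed for canonical sites only")
  n <- nchar(utr_sequence)
  # 0-based start of the seed6 match within the span
  s6 <- if (site$site_type %in% c("8mer", "7mer-m8")) site$start + 1L else site$start
  seed_pos <- (s6 - 1L):(s6 + 5L)              # pairs miRNA nt 8..2
  seed_pos <- seed_pos[seed_pos >= 0L & seed_pos < n]
  centre <- floor((site$start + site$end) / 2)
  half <- floor(folding_window / 2)
  w0 <- max(0L, centre - half)
  w1 <- min(n, w0 + folding_window)
  w0 <- max(0L, w1 - folding_window)           # keep full width when clipped
  win <- substr(utr_sequence, w0 + 1L, w1)
  partner <- .fold_pairs_cpp(win)
  if (length(partner) != nchar(win))
    stop("folding backend failed on window [", w0, ",", w1, ")")
  local <- seed_pos - w0 + 1L                  # 1-based within window
  local <- local[local >= 1L & local <= length(partner)]
  sum(partner[local] == 0L) >= 4L
}

#' Over-representation score for accessible seed matches
#'
#' Upper-tail binomial probability of observing at least `count` seed
#' matches in the UTR, under a null where each of the `L - 6` possible
#' 7-mer start positions independently matches the extended seed with
#' probability given by the UTR's mononucleotide composition. Smaller
#' values indicate over-representation; a count of 0 scores 1.0.
#'
#' @param accessible_site_count non-negative integer.
#' @param utr_sequence the UTR sequence.
#' @param mirna the miRNA whose seed-7 target is assessed.
#' @return p-value-like score in `(0, 1]`.
#' @export
rank_overrepresentation <- function(accessible_site_count, utr_sequence,
                                    mirna) {
  stopifnot(accessible_site_count >= 0)
  if (accessible_site_count == 0) return(1.0)
  target <- revcomp_dna(rna_to_dna(mirna$seed7))
  ch <- strsplit(toupper(utr_sequence), "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(ch)) return(1.0)
  freq <- table(factor(ch, levels = c("A", "C", "G", "T"))) / length(ch)
  p_site <- prod(freq[strsplit(target, "", fixed = TRUE)[[1]]])
  n_pos <- max(0L, nchar(utr_sequence) - 7L + 1L)
  if (n_pos == 0L) return(1.0)
  stats::pbinom(accessible_site_count - 1, n_pos, p_site, lower.tail = FALSE)
}

# Watson-Crick pair between a miRNA base (DNA-coded, 5'->3') and an mRNA base
is_wc <- function(mi, mr) {
  (mi == "A" & mr == "T") | (mi == "T" & mr == "A") |
    (mi == "G" & mr == "C") | (mi == "C" & mr == "G")
}

#' Find 3'-compensatory (non-canonical) target sites
#'
#' Reports sites where pairing of miRNA nt 2-8 to the UTR contains exactly
#' one defect -- a mismatch, a G:U wobble, or a single-nucleotide bulge on
#' the UTR side -- and where the defect is compensated by at least four
#' consecutive Watson-Crick pairs between miRNA nt 13-17 and the UTR
#' upstream (5') of the seed match, separated from it by an unpaired gap of
#' 1-6 nt. Perfect-seed sites are never reported here, and no reported span
#' coincides with a canonical span from [find_seed_sites()].
#'
#' The score is the number of Watson-Crick seed pairs plus the length of
#' the best consecutive 3'-pairing run.
#'
#' @inheritParams find_seed_sites
#' @return data.frame of TargetSite rows with `site_type = "compensatory"`,
#'   `predictor = "compensatory"`.
#' @export
find_compensatory_sites <- function(utr_sequence, mirna, utr_id = "utr",
                                    known_mask = integer(0)) {
  utr_sequence <- toupper(utr_sequence)
  n <- nchar(utr_sequence)
  if (n < 14L) return(empty_sites())
  u <- strsplit(utr_sequence, "", fixed = TRUE)[[1]]
  mseq <- strsplit(rna_to_dna(mirna$sequence), "", fixed = TRUE)[[1]]
  if (length(mseq) < 17L) return(empty_sites())
  seed <- mseq[8:2]     # pairs the UTR window 5'->3'
  m3p <- mseq[17:13]    # nt 17..13 pair the upstream UTR segment 5'->3'

  # >=4 consecutive WC pairs between nt 13-17 and the 5-nt UTR segment
  # ending `gap` nt upstream of seed-window start s (0-based)
  has_3p_support <- function(s) {
    best <- 0L
    for (gap in 1:6) {
      a <- s - gap - 5L         # 0-based start of the 5-nt segment
      if (a < 0L) next
      seg <- u[(a + 1L):(a + 5L)]
      if (any(seg == "N")) next
      wc <- is_wc(m3p, seg)
      r <- rle(wc)
      run <- max(c(0L, r$lengths[r$values]))
      if (run > best) best <- run
    }
    best
  }

  canon <- find_seed_sites(utr_sequence, mirna, utr_id)
  canon_keys <- paste(canon$start, canon$end)

  rows <- list()
  # (a) one mismatch or G:U wobble within a 7-nt seed window
  for (s in 0:(n - 7L)) {
    w <- u[(s + 1L):(s + 7L)]
    if (any(w == "N")) next
    wc <- is_wc(seed, w)
    if (sum(wc) != 6L) next
    run <- has_3p_support(s)
    if (run < 4L) next
    span <- c(s, s + 7L)
    if (paste(span[1], span[2]) %in% canon_keys) next
    if (length(known_mask) && any(known_mask >= span[1] & known_mask < span[2]))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      utr_id = utr_id, mirna_name = mirna$name, start = span[1],
      end = span[2], site_type = "compensatory", predictor = "compensatory",
      score = 6 + run, accessible = NA, stringsAsFactors = FALSE)
  }
  # (b) single-nucleotide bulge on the UTR side: an 8-nt window that pairs
  # nt 2-8 perfectly once one internal base is looped out
  for (s in 0:(n - 8L)) {
    w <- u[(s + 1L):(s + 8L)]
    if (any(w == "N")) next
    hit <- FALSE
    for (b in 2:7) {            # bulged base must be internal
      if (all(is_wc(seed, w[-b]))) { hit <- TRUE; break }
    }
    if (!hit) next
    run <- has_3p_support(s)
    if (run < 4L) next
    span <- c(s, s + 8L)
    if (paste(span[1], span[2]) %in% canon_keys) next
    if (length(known_mask) && any(known_mask >= span[1] & known_mask < span[2]))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      utr_id = utr_id, mirna_name = mirna$name, start = span[1],
      end = span[2], site_type = "compensatory", predictor = "compensatory",
      score = 7 + run, accessible = NA, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_sites())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Presence-based conservation check in an ortholog UTR
#'
#' A site is called conserved when the ortholog 3'-UTR contains at least one
#' canonical site for the same miRNA family (same seed-7). The check is
#' presence-based; no positional alignment is attempted.
#'
#' @param site TargetSite row (used only to assert a site exists).
#' @param ortholog_utr_sequence non-empty ortholog UTR sequence.
#' @param mirna the targeting miRNA.
#' @return logical.
#' @export
check_conservation <- function(site, ortholog_utr_sequence, mirna) {
  if (!nzchar(ortholog_utr_sequence))
    stop("ortholog UTR sequence must be non-empty")
  nrow(find_seed_sites(ortholog_utr_sequence, mirna)) > 0L
}

#' Predict target sites on one UTR under the three criteria
#'
#' Runs the three per-predictor pipelines on a single UTR allele:
#' * `seed_context`: canonical seed sites scored by [context_score()];
#' * `accessibility`: canonical seed sites kept only when
#'   [assess_accessibility()] holds, scored by `-log10` of the
#'   per-miRNA [rank_overrepresentation()] of its accessible sites;
#' * `compensatory`: [find_compensatory_sites()] with the pairing score.
#'
#' @param utr a [utr_record()] or a plain sequence string.
#' @param mirnas list of [mature_mirna()] objects.
#' @param config a [pipeline_config()].
#' @param predictors subset of the three predictor names.
#' @param utr_id identifier used when `utr` is a plain string.
#' @return data.frame of TargetSite rows across miRNAs and predictors.
#' @export
predict_sites <- function(utr, mirnas,
                          config = pipeline_config(),
                          predictors = c("seed_context", "accessibility",
                                         "compensatory"),
                          utr_id = "utr") {
  if (inherits(utr, "UTRRecord")) {
    seqs <- utr$sequence; mask <- utr$known_mask; utr_id <- utr$transcript_id
  } else {
    seqs <- as.character(utr); mask <- integer(0)
  }
  if (inherits(mirnas, "MatureMiRNA")) mirnas <- list(mirnas)
  out <- list()
  for (mir in mirnas) {
    canon <- find_seed_sites(seqs, mir, utr_id, mask)
    if ("seed_context" %in% predictors && nrow(canon)) {
      sc <- canon
      sc$predictor <- "seed_context"
      sc$score <- vapply(seq_len(nrow(sc)), function(i)
        context_score(sc[i, ], seqs, mir, config), numeric(1))
      out[[length(out) + 1L]] <- sc
    }
    if ("accessibility" %in% predictors && nrow(canon)) {
      acc <- vapply(seq_len(nrow(canon)), function(i)
        assess_accessibility(canon[i, ], seqs, config$folding_window),
        logical(1))
      if (any(acc)) {
        ac <- canon[acc, , drop = FALSE]
        ac$predictor <- "accessibility"
        ac$accessible <- TRUE
        p <- rank_overrepresentation(nrow(ac), seqs, mir)
        ac$score <- -log10(max(p, .Machine$double.xmin))
        out[[length(out) + 1L]] <- ac
      }
    }
    if ("compensatory" %in% predictors) {
      cp <- find_compensatory_sites(seqs, mir, utr_id, mask)
      if (nrow(cp)) out[[length(out) + 1L]] <- cp
    }
  }
  if (!length(out)) return(empty_sites())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
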
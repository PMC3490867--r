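#' Compute a genome mappability track
#'
#' For every L-mer start position in the genome, counts the number of start
#' positions (including itself) whose L-mer lies within Hamming distance `m`
#' -- the number of places a read of length `L` originating there could map
#' with at most `m` mismatches. A count of 1 means the read maps back
#' uniquely to its region of origin. L-mers containing `N` match nothing:
#' they are recorded with count 1 and flagged low-confidence. With
#' `strand_mode = "both"` reverse-complement matches are also counted.
#'
#' Counting is exact (all-pairs with early exit); the contract is
#' correctness at desk scale, not production whole-genome throughput.
#'
#' @param genome named character vector of contig sequences.
#' @param L read length (must not exceed the shortest contig).
#' @param m allowed mismatches (>= 0).
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @return object of class `MappabilityTrack`: list with `counts` and
#'   `flagged` (named lists of per-start-position vectors, length
#'   `contig length - L + 1`), and parameters `L`, `m`, `strand_mode`.
#' @export
compute_mappability <- function(genome, L, m, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  L <- as.integer(L); m <- as.integer(m)
  if (m < 0L) stop("mismatches m must be >= 0")
  if (any(nchar(genome) < L))
    stop("read length L (", L, ") exceeds the shortest contig")
  res <- .mapp_counts_cpp(toupper(genome), L, m, strand_mode == "both")
  structure(list(counts = res$counts, flagged = res$flagged,
                 L = L, m = m, strand_mode = strand_mode),
            class = "MappabilityTrack")
}

#' @export
print.MappabilityTrack <- function(x, ...) {
  cat(sprintf("<MappabilityTrack L=%d m=%d %s; %d contig(s), %d positions>\n",
              x$L, x$m, x$strand_mode, length(x$counts),
              sum(lengths(x$counts))))
  invisible(x)
}

#' Average mappability in the window around a SNP
#'
#' Arithmetic mean of the mappability counts at L-mer start positions within
#' the 2L-wide window centred on the SNP: starts in `[pos - L, pos + L)` in
#' 0-based position space, clipped to valid start positions.
#'
#' @param track a [compute_mappability()] result.
#' @param contig contig of the SNP.
#' @param position 1-based SNP coordinate (VCF convention).
#' @return mean count (>= 1).
#' @export
snp_window_mappability <- function(track, contig, position) {
  if (!contig %in% names(track$counts))
    stop("contig not in mappability track: ", contig)
  v <- track$counts[[contig]]
  pos0 <- as.integer(position) - 1L
  lo <- max(0L, pos0 - track$L)
  hi <- min(length(v) - 1L, pos0 + track$L - 1L)
  if (hi < lo)
    stop("no valid L-mer start position in the window around ", contig, ":",
         position)
  mean(v[(lo + 1L):(hi + 1L)])
}

#' Filter SNPs by window mappability
#'
#' Retains a SNP only when the average mappability of its 2L window equals
#' `config$mappability_retain_value` (1.0: every read spanning the SNP maps
#' back uniquely). Rejected SNPs carry the computed value.
#'
#' @param snps list of [snp_record()] objects.
#' @param track a [compute_mappability()] result.
#' @param config a [pipeline_config()].
#' @return `list(retained = <snp list>, rejected = <data.frame snp_id,
#'   contig, position, mappability>)`.
#' @export
filter_by_mappability <- function(snps, track, config = pipeline_config()) {
  vals <- vapply(snps, function(s)
    snp_window_mappability(track, s$contig, s$position), numeric(1))
  keep <- vals == config$mappability_retain_value
  rejected <- if (any(!keep)) {
    data.frame(snp_id = vapply(snps[!keep], `[[`, character(1), "snp_id"),
               contig = vapply(snps[!keep], `[[`, character(1), "contig"),
               position = vapply(snps[!keep], `[[`, integer(1), "position"),
               mappability = vals[!keep], stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(0), contig = character(0),
               position = integer(0), mappability = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(retained = snps[keep], rejected = rejected)
}

#' Write a mappability track as BedGraph
#' @param track a `MappabilityTrack`.
#' @param path output file.
#' @export
write_mappability_bedgraph <- function(track, path)
  write_bedgraph(track$counts, path)
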
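#' Filter candidate SNPs by call quality, depth and UTR membership
#'
#' A SNP is retained iff its quality is at least `min_snp_quality`, its
#' depth at least `min_depth` (both inclusive -- they are minima) and its
#' position falls inside at least one annotated 3'-UTR interval. The filter
#' is idempotent and order-independent.
#'
#' @param snps list of [snp_record()] objects.
#' @param utrs list of [utr_record()] objects (or an annotation data.frame
#'   with `contig`, `start`, `end`).
#' @param config a [pipeline_config()].
#' @return the retained subset of `snps`.
#' @export
filter_candidate_snps <- function(snps, utrs, config = pipeline_config()) {
  if (is.data.frame(utrs)) {
    iv <- utrs[c("contig", "start", "end")]
  } else {
    iv <- data.frame(
      contig = vapply(utrs, `[[`, character(1), "contig"),
      start = vapply(utrs, `[[`, integer(1), "start"),
      end = vapply(utrs, `[[`, integer(1), "end"),
      stringsAsFactors = FALSE)
  }
  keep <- vapply(snps, function(s) {
    if (s$quality < config$min_snp_quality) return(FALSE)
    if (s$depth < config$min_depth) return(FALSE)
    g0 <- s$position - 1L
    any(iv$contig == s$contig & iv$start <= g0 & g0 < iv$end)
  }, logical(1))
  snps[keep]
}

#' Merge novel SNPs with known database SNPs
#'
#' Union keyed by `(contig, position, ref, alt)`. A key present in both
#' inputs collapses to a single record with `provenance = "both"` (novel
#' record's call metadata is kept); otherwise records keep their own
#' provenance (`novel` / `known`).
#'
#' @param novel_snps,known_snps lists of [snp_record()] objects.
#' @return merged list; its length is `|novel| + |known| - |shared keys|`.
#' @export
merge_with_known <- function(novel_snps, known_snps) {
  key <- function(s) paste(s$contig, s$position, s$ref_allele, s$alt_allele)
  nk <- vapply(novel_snps, key, character(1))
  kk <- vapply(known_snps, key, character(1))
  out <- lapply(novel_snps, function(s) {
    s$provenance <- if (key(s) %in% kk) "both" else "novel"
    s
  })
  extra <- known_snps[!(kk %in% nk)]
  extra <- lapply(extra, function(s) { s$provenance <- "known"; s })
  c(out, extra)
}

#' Fraction of a 3'-UTR covered by reads
#'
#' A UTR qualifies as "covered" when strictly more than 50% (or
#' `config$coverage_fraction_threshold`) of its bases have depth >= 1.
#'
#' @param depth a `DepthTrack` (see [read_depth_bedgraph()]).
#' @param utr a [utr_record()].
#' @param config a [pipeline_config()].
#' @return `list(fraction = <numeric in [0,1]>, covered = <logical>)`.
#' @export
utr_coverage_fraction <- function(depth, utr, config = pipeline_config()) {
  if (!utr$contig %in% names(depth$depth))
    stop("contig missing from depth track: ", utr$contig)
  v <- depth$depth[[utr$contig]][(utr$start + 1L):utr$end]
  fraction <- mean(v >= 1L)
  list(fraction = fraction,
       covered = fraction > config$coverage_fraction_threshold)
}

#' Percentage of reads mapping to a region
#'
#' `100 * region / total`, rounded half-up to one decimal (the printed
#' style of mapping-statistics tables).
#'
#' @param region_read_count reads in the region (`<= total_mapped`).
#' @param total_mapped total mapped reads (> 0).
#' @return percentage with one decimal.
#' @examples
#' region_read_proportion(1177825, 31487788)  # 3.7
#' @export
region_read_proportion <- function(region_read_count, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  if (region_read_count > total_mapped)
    stop("region_read_count cannot exceed total_mapped")
  round_half_up(100 * region_read_count / total_mapped, 1)
}
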
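#' Fragments per kilobase of exon per million mapped reads
#'
#' `count * 1e9 / (effective_length_bp * total_mapped)`: linear in the
#' count, inverse-linear in length and library size.
#'
#' @param count fragment count (>= 0).
#' @param effective_length_bp effective feature length in bp (> 0).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return FPKM value.
#' @export
compute_fpkm <- function(count, effective_length_bp, total_mapped) {
  if (any(effective_length_bp <= 0)) stop("effective length must be > 0")
  if (any(total_mapped <= 0)) stop("total mapped reads must be > 0")
  count * 1e9 / (effective_length_bp * total_mapped)
}

#' Co-expression gate for a miRNA / mRNA pair
#'
#' A pair counts as co-expressed in a tissue when the miRNA is represented
#' by strictly more than 10 reads and the mRNA by strictly more than 1 FPKM
#' (both thresholds configurable, both strict).
#'
#' @param mirna_reads miRNA read count in the tissue.
#' @param mrna_fpkm mRNA FPKM in the tissue.
#' @param config a [pipeline_config()].
#' @return logical.
#' @export
is_coexpressed <- function(mirna_reads, mrna_fpkm,
                           config = pipeline_config()) {
  mirna_reads > config$coexpr_min_mirna_reads &
    mrna_fpkm > config$coexpr_min_fpkm
}

#' Two-sided Fisher exact test of allelic proportions between two tissues
#'
#' Exact test on the 2x2 table `[[refA, varA], [refB, varB]]` by
#' minimum-likelihood summation: the p-value is the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed table's (a relative tolerance of
#' 1e-7 guards ties against floating-point noise, the conventional exact-
#' test definition).
#'
#' @param counts_a,counts_b two-element vectors `c(ref_reads, var_reads)`
#'   (or rows of an AllelicCounts table), each with positive total.
#' @return two-sided p-value in `(0, 1]`.
#' @export
fisher_allelic_proportion_test <- function(counts_a, counts_b) {
  a <- as.numeric(counts_a[1]); b <- as.numeric(counts_a[2])
  c_ <- as.numeric(counts_b[1]); d <- as.numeric(counts_b[2])
  if (a + b <= 0 || c_ + d <= 0)
    stop("both tissues need a positive allele-count total")
  m <- a + c_          # ref margin
  n <- b + d           # var margin
  k <- a + b           # tissue-A margin
  if (m == 0 || n == 0) stop("undefined test: an allele margin is zero")
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Two-sided exact binomial test for allele-specific expression
#'
#' Tests the null that variant and reference read counts are equal
#' (binomial success probability 0.5) with the minimum-likelihood two-sided
#' convention: the p-value sums the probabilities of all outcomes no more
#' likely than the observed one. At p = 0.5 this equals the doubled smaller
#' tail (capped at 1). Significance is called at `alpha` (default 0.001).
#'
#' @param ref_reads,var_reads non-negative counts with positive sum.
#' @param alpha significance threshold for the returned flag.
#' @return `list(p_value, significant)`; the test is symmetric in its
#'   arguments.
#' @export
binomial_ase_test <- function(ref_reads, var_reads, alpha = 0.001) {
  x <- as.numeric(ref_reads); y <- as.numeric(var_reads)
  if (x < 0 || y < 0) stop("read counts must be non-negative")
  n <- x + y
  if (n == 0) stop("undefined test: zero total read count")
  dens <- dbinom(0:n, n, 0.5)
  p_obs <- dens[x + 1]
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  list(p_value = p, significant = p < alpha)
}

#' Flag poly-miRTS / miRNA pairs with inverse expression across tissues
#'
#' Formalises the inverse-expression read-out: for each created or disrupted
#' poly-miRTS and its cognate miRNA, the targeted allele (the variant for
#' created sites, the reference for disrupted sites) should be relatively
#' less expressed where the miRNA is more expressed. A pair must be
#' co-expressed ([is_coexpressed()]) with observable allelic counts in at
#' least two tissues; it is flagged iff
#' (a) at least one tissue pair differs significantly in allelic proportion
#' ([fisher_allelic_proportion_test()] p below
#' `config$allelic_fisher_alpha`), and
#' (b) across all co-expressed tissue pairs with strictly different miRNA
#' expression, the tissue with the higher miRNA read count has the strictly
#' lower targeted-allele proportion (strict sign concordance; at least one
#' such ordered pair must exist).
#'
#' @param polymirts data.frame from [classify_polymirts()]; only
#'   created/disrupted rows are evaluated (one row per (snp, mirna) pair
#'   after deduplication over predictors).
#' @param allelic_counts data.frame `snp_id`, `tissue`, `ref_reads`,
#'   `var_reads`.
#' @param mirna_expression data.frame `mirna`, `tissue`, `reads`.
#' @param mrna_expression data.frame `gene`, `tissue`, `fpkm` (`gene`
#'   matches `polymirts$utr_id`).
#' @param config a [pipeline_config()].
#' @return data.frame with one row per evaluated (snp, mirna) pair:
#'   `snp_id`, `mirna_name`, `gene`, `status`, `n_tissues`, `min_fisher_p`,
#'   `concordant`, `flagged`.
#' @export
flag_inverse_expression <- function(polymirts, allelic_counts,
                                    mirna_expression, mrna_expression,
                                    config = pipeline_config()) {
  empty <- data.frame(snp_id = character(0), mirna_name = character(0),
                      gene = character(0), status = character(0),
                      n_tissues = integer(0), min_fisher_p = numeric(0),
                      concordant = logical(0), flagged = logical(0),
                      stringsAsFactors = FALSE)
  pm <- polymirts[polymirts$status %in% c("created", "disrupted"), ,
                  drop = FALSE]
  if (!nrow(pm)) return(empty)
  pairs <- unique(pm[c("snp_id", "mirna_name", "utr_id", "status")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    ac <- allelic_counts[allelic_counts$snp_id == p$snp_id, , drop = FALSE]
    me <- mirna_expression[mirna_expression$mirna == p$mirna_name, ,
                           drop = FALSE]
    ge <- mrna_expression[mrna_expression$gene == p$utr_id, , drop = FALSE]
    tissues <- Reduce(intersect, list(ac$tissue, me$tissue, ge$tissue))
    ok <- vapply(tissues, function(tt) {
      isTRUE(is_coexpressed(me$reads[me$tissue == tt][1],
                            ge$fpkm[ge$tissue == tt][1], config)) &&
        sum(ac$ref_reads[ac$tissue == tt][1],
            ac$var_reads[ac$tissue == tt][1]) > 0
    }, logical(1))
    tissues <- tissues[ok]
    if (length(tissues) < 2L)
      return(data.frame(snp_id = p$snp_id, mirna_name = p$mirna_name,
                        gene = p$utr_id, status = p$status,
                        n_tissues = length(tissues), min_fisher_p = NA_real_,
                        concordant = NA, flagged = FALSE,
                        stringsAsFactors = FALSE))
    ref <- vapply(tissues, function(tt) ac$ref_reads[ac$tissue == tt][1],
                  numeric(1))
    var <- vapply(tissues, function(tt) ac$var_reads[ac$tissue == tt][1],
                  numeric(1))
    mir <- vapply(tissues, function(tt) me$reads[me$tissue == tt][1],
                  numeric(1))
    targeted <- if (p$status == "created") var else ref
    prop <- targeted / (ref + var)
    cmb <- combn(length(tissues), 2)
    pvals <- apply(cmb, 2, function(ij)
      fisher_allelic_proportion_test(c(ref[ij[1]], var[ij[1]]),
                                     c(ref[ij[2]], var[ij[2]])))
    ordered_pairs <- 0L
    concordant <- TRUE
    for (jj in seq_len(ncol(cmb))) {
      i1 <- cmb[1, jj]; i2 <- cmb[2, jj]
      if (mir[i1] == mir[i2]) next
      ordered_pairs <- ordered_pairs + 1L
      hi <- if (mir[i1] > mir[i2]) i1 else i2
      lo <- if (mir[i1] > mir[i2]) i2 else i1
      if (!(prop[hi] < prop[lo])) concordant <- FALSE
    }
    concordant <- concordant && ordered_pairs > 0L
    data.frame(snp_id = p$snp_id, mirna_name = p$mirna_name, gene = p$utr_id,
               status = p$status, n_tissues = length(tissues),
               min_fisher_p = min(pvals),
               concordant = concordant,
               flagged = concordant && min(pvals) < config$allelic_fisher_alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
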
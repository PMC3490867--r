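site_key <- function(sites) {
  paste(sites$mirna_name, sites$start, sites$end, sites$site_type,
        sites$predictor, sep = "\r")
}

#' Classify reference-vs-variant site differences as poly-miRTSs
#'
#' Compares per-predictor site sets predicted on the reference and variant
#' alleles of one UTR. Sites are matched by exact key
#' `(mirna, start, end, type, predictor)` -- substitution SNPs preserve
#' coordinates, so gapped matching is unnecessary. A key present only in the
#' variant is a **created** site; only in the reference a **disrupted**
#' site, except that a reference span overlapping the variant's unknown-
#' sequence mask yields **unknown** (absence of sequence information must
#' not be counted as disruption). A key present in both alleles whose
#' per-predictor score difference exceeds `perturbation_delta` (strict, in
#' absolute value) is **perturbed**. Unchanged sites produce no record.
#'
#' Any ref/var prediction difference is attributed to the applied SNP, even
#' when distant from it (e.g. accessibility changes through secondary
#' structure); `snp_distance` records the gap in nt between SNP and site
#' span (0 when overlapping, `NA` when `utr` is not supplied).
#'
#' @param ref_sites,var_sites TargetSite data.frames from the same UTR
#'   coordinates (see [predict_sites()]).
#' @param snp the applied [snp_record()].
#' @param variant_known_mask 0-based offsets of unknown sequence in the
#'   variant allele.
#' @param config a [pipeline_config()] (supplies `perturbation_delta`).
#' @param utr optional [utr_record()] used to compute `snp_distance`.
#' @return data.frame of PolyMiRTS rows: `snp_id`, `utr_id`, `mirna_name`,
#'   `predictor`, `status` in created/disrupted/perturbed/unknown,
#'   `ref_score`, `var_score`, `start`, `end`, `site_type`, `snp_distance`.
#' @export
classify_polymirts <- function(ref_sites, var_sites, snp,
                               variant_known_mask = integer(0),
                               config = pipeline_config(), utr = NULL) {
  ids <- unique(c(ref_sites$utr_id, var_sites$utr_id))
  if (length(ids) > 1L)
    stop("ref and var site lists mix different UTRs: ",
         paste(ids, collapse = ", "))
  utr_id <- if (length(ids)) ids else NA_character_
  rk <- site_key(ref_sites)
  vk <- site_key(var_sites)
  snp_off <- if (!is.null(utr)) snp_utr_offset(utr, snp) else NA_integer_

  rec <- function(row, status, ref_score, var_score) {
    dist <- if (is.na(snp_off)) NA_integer_ else {
      if (snp_off >= row$start && snp_off < row$end) 0L
      else as.integer(min(abs(snp_off - row$start),
                          abs(snp_off - (row$end - 1L))))
    }
    data.frame(snp_id = snp$snp_id, utr_id = utr_id,
               mirna_name = row$mirna_name, predictor = row$predictor,
               status = status, ref_score = ref_score, var_score = var_score,
               start = row$start, end = row$end, site_type = row$site_type,
               snp_distance = dist, stringsAsFactors = FALSE)
  }

  out <- list()
  created <- var_sites[!(vk %in% rk), , drop = FALSE]
  for (i in seq_len(nrow(created)))
    out[[length(out) + 1L]] <- rec(created[i, ], "created",
                                   NA_real_, created$score[i])
  lost <- ref_sites[!(rk %in% vk), , drop = FALSE]
  for (i in seq_len(nrow(lost))) {
    row <- lost[i, ]
    masked <- length(variant_known_mask) &&
      any(variant_known_mask >= row$start & variant_known_mask < row$end)
    out[[length(out) + 1L]] <- rec(row,
                                   if (masked) "unknown" else "disrupted",
                                   row$score, NA_real_)
  }
  shared_r <- ref_sites[rk %in% vk, , drop = FALSE]
  if (nrow(shared_r)) {
    vmap <- setNames(var_sites$score, vk)
    for (i in seq_len(nrow(shared_r))) {
      rs <- shared_r$score[i]
      vs <- vmap[[site_key(shared_r[i, ])]]
      if (is.finite(rs) && is.finite(vs) &&
          abs(vs - rs) > config$perturbation_delta)
        out[[length(out) + 1L]] <- rec(shared_r[i, ], "perturbed", rs, vs)
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(0), utr_id = character(0),
                      mirna_name = character(0), predictor = character(0),
                      status = character(0), ref_score = numeric(0),
                      var_score = numeric(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      snp_distance = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn-region consensus of the three predictors
#'
#' Partitions the distinct `(mirna, start, end)` sites of one UTR into the
#' seven exclusive Venn regions over the predictor sets.
#'
#' @param sites_by_predictor named list with elements `seed_context`,
#'   `accessibility`, `compensatory`, each a TargetSite data.frame (missing
#'   elements are treated as empty).
#' @return object of class `ConsensusSummary`: named integer vector with
#'   regions `seed_context_only`, `accessibility_only`, `compensatory_only`,
#'   `seed_context+accessibility`, `seed_context+compensatory`,
#'   `accessibility+compensatory`, `all_three`, plus attribute `total`
#'   (the number of distinct sites; the regions sum to it).
#' @export
summarize_consensus <- function(sites_by_predictor) {
  keyset <- function(df) {
    if (is.null(df) || !nrow(df)) character(0)
    else unique(paste(df$mirna_name, df$start, df$end, sep = "\r"))
  }
  A <- keyset(sites_by_predictor$seed_context)
  B <- keyset(sites_by_predictor$accessibility)
  C <- keyset(sites_by_predictor$compensatory)
  all_keys <- unique(c(A, B, C))
  ina <- all_keys %in% A; inb <- all_keys %in% B; inc <- all_keys %in% C
  out <- c(
    "seed_context_only"          = sum(ina & !inb & !inc),
    "accessibility_only"         = sum(!ina & inb & !inc),
    "compensatory_only"          = sum(!ina & !inb & inc),
    "seed_context+accessibility" = sum(ina & inb & !inc),
    "seed_context+compensatory"  = sum(ina & !inb & inc),
    "accessibility+compensatory" = sum(!ina & inb & inc),
    "all_three"                  = sum(ina & inb & inc))
  structure(out, total = length(all_keys), class = "ConsensusSummary")
}

#' @export
print.ConsensusSummary <- function(x, ...) {
  cat("Predictor consensus (", attr(x, "total"), " distinct sites)\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-28s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Tally created and disrupted poly-miRTSs per gene and predictor
#'
#' Counts classification records by status within each (gene, predictor)
#' cell. Records with status `unknown` are excluded from the created and
#' disrupted tallies and reported in their own column.
#'
#' @param polymirts data.frame from [classify_polymirts()] (rows from
#'   several SNPs/UTRs may be concatenated).
#' @return data.frame with columns `utr_id`, `predictor`, `created`,
#'   `disrupted`, `perturbed`, `unknown`.
#' @export
tally_created_disrupted <- function(polymirts) {
  if (!nrow(polymirts))
    return(data.frame(utr_id = character(0), predictor = character(0),
                      created = integer(0), disrupted = integer(0),
                      perturbed = integer(0), unknown = integer(0),
                      stringsAsFactors = FALSE))
  cells <- unique(polymirts[c("utr_id", "predictor")])
  rownames(cells) <- NULL
  for (st in c("created", "disrupted", "perturbed", "unknown")) {
    cells[[st]] <- vapply(seq_len(nrow(cells)), function(i) {
      sum(polymirts$utr_id == cells$utr_id[i] &
            polymirts$predictor == cells$predictor[i] &
            polymirts$status == st)
    }, integer(1))
  }
  cells
}
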
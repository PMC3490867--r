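#' Read a flat key=value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. File-path keys
#' (`genome_fasta`, `utr_annotation`, `mirna_fasta`, `snps_vcf`, optional
#' `known_snps_vcf`, `depth_bedgraph`, `allelic_counts_tsv`,
#' `mirna_expr_tsv`, `mrna_expr_tsv`, `out_dir`) are kept as strings;
#' any key matching a [pipeline_config()] field overrides its default.
#'
#' @param path config file.
#' @return list with `paths` (named character) and `config`
#'   (a `PipelineConfig`).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  names(vals) <- keys
  path_keys <- c("genome_fasta", "utr_annotation", "mirna_fasta", "snps_vcf",
                 "known_snps_vcf", "depth_bedgraph", "allelic_counts_tsv",
                 "mirna_expr_tsv", "mrna_expr_tsv", "out_dir")
  paths <- vals[names(vals) %in% path_keys]
  cfg_args <- vals[!(names(vals) %in% path_keys)]
  defaults <- pipeline_config()
  unknown <- setdiff(names(cfg_args), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg_args <- lapply(cfg_args, function(v)
    if (v %in% c("forward", "both")) v else as.numeric(v))
  cfg_args$mappability_window <- NULL
  cfg <- do.call(pipeline_config, cfg_args)
  list(paths = paths, config = cfg)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the poly-miRTS pipeline end to end
#'
#' Stages, in order: load inputs; filter candidate SNPs (quality, depth,
#' UTR membership) and merge known SNPs; mappability filter; 3'-UTR
#' coverage report (when a depth track is given); per-SNP target prediction
#' on reference and variant alleles under the three predictors and
#' poly-miRTS classification; predictor consensus per UTR; allele-specific
#' expression tests; inverse-expression flags (when expression tables are
#' given). Outputs are deterministic given identical inputs and config.
#'
#' @param config_path flat key=value config file
#'   (see [read_pipeline_config()]).
#' @return invisibly, the output directory. Files written: `sites.tsv`,
#'   `polymirts.tsv`, `consensus.tsv`, `tally.tsv`, `snp_filter.vcf`,
#'   `mappability.bedgraph`, `coverage.tsv`, `ase_tests.tsv`,
#'   `inverse_flags.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config_path) {
  pc <- read_pipeline_config(config_path)
  paths <- pc$paths
  config <- pc$config
  set.seed(config$rng_seed)
  for (k in c("genome_fasta", "utr_annotation", "mirna_fasta", "snps_vcf"))
    if (!k %in% names(paths)) stop("config is missing required path: ", k)
  for (k in names(paths)) {
    if (k != "out_dir" && !file.exists(paths[[k]]))
      stop("input file for '", k, "' not found: ", paths[[k]])
  }
  out_dir <- if ("out_dir" %in% names(paths)) paths[["out_dir"]] else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage_log("load", "reading inputs")
  genome <- read_genome_fasta(paths[["genome_fasta"]])
  annotation <- read_utr_annotation(paths[["utr_annotation"]])
  utrs <- extract_utr_sequences(genome, annotation)
  mirnas <- read_mirna_fasta(paths[["mirna_fasta"]])
  snps <- read_snps_vcf(paths[["snps_vcf"]])
  n_input_snps <- length(snps)

  stage_log("filter", "%d candidate SNPs", length(snps))
  snps <- filter_candidate_snps(snps, utrs, config)
  n_after_quality <- length(snps)
  if ("known_snps_vcf" %in% names(paths)) {
    known <- read_snps_vcf(paths[["known_snps_vcf"]])
    snps <- merge_with_known(snps, known)
  }
  n_after_merge <- length(snps)

  stage_log("mappability", "L=%d m=%d (%s)", config$read_length,
            config$mismatches, config$strand_mode)
  track <- compute_mappability(genome, config$read_length, config$mismatches,
                               config$strand_mode)
  write_mappability_bedgraph(track, file.path(out_dir, "mappability.bedgraph"))
  mf <- filter_by_mappability(snps, track, config)
  snps <- mf$retained
  stage_log("mappability", "%d retained / %d rejected", length(snps),
            nrow(mf$rejected))
  write_snps_vcf(snps, file.path(out_dir, "snp_filter.vcf"),
                 filters = rep("PASS", length(snps)))

  coverage <- data.frame(gene_id = character(0), transcript_id = character(0),
                         fraction = numeric(0), covered = logical(0),
                         stringsAsFactors = FALSE)
  if ("depth_bedgraph" %in% names(paths)) {
    dt <- read_depth_bedgraph(paths[["depth_bedgraph"]],
                              setNames(nchar(genome), names(genome)))
    coverage <- do.call(rbind, lapply(utrs, function(u) {
      cv <- utr_coverage_fraction(dt, u, config)
      data.frame(gene_id = u$gene_id, transcript_id = u$transcript_id,
                 fraction = cv$fraction, covered = cv$covered,
                 stringsAsFactors = FALSE)
    }))
  }
  write_tsv(coverage, file.path(out_dir, "coverage.tsv"))

  stage_log("predict", "%d UTRs x %d miRNAs", length(utrs), length(mirnas))
  utr_by_tx <- setNames(utrs, vapply(utrs, `[[`, character(1), "transcript_id"))
  ref_sites <- lapply(utr_by_tx, predict_sites, mirnas = mirnas,
                      config = config)
  all_sites <- do.call(rbind, c(ref_sites, list(empty_sites())))
  write_tsv(all_sites, file.path(out_dir, "sites.tsv"))

  pm_list <- list()
  for (snp in snps) {
    hosts <- Filter(function(u) snp$contig == u$contig &&
                      snp$position - 1L >= u$start &&
                      snp$position - 1L < u$end, utrs)
    for (u in hosts) {
      var_u <- apply_variant(u, snp)
      vs <- predict_sites(var_u, mirnas, config)
      pm <- classify_polymirts(ref_sites[[u$transcript_id]], vs, snp,
                               variant_known_mask = var_u$known_mask,
                               config = config, utr = u)
      if (nrow(pm)) pm_list[[length(pm_list) + 1L]] <- pm
    }
  }
  polymirts <- if (length(pm_list)) do.call(rbind, pm_list) else
    classify_polymirts(empty_sites(), empty_sites(),
                       snp_record("x", 1, "A", "C"))
  write_tsv(polymirts, file.path(out_dir, "polymirts.tsv"))
  write_tsv(tally_created_disrupted(polymirts),
            file.path(out_dir, "tally.tsv"))

  consensus <- do.call(rbind, lapply(names(ref_sites), function(tx) {
    st <- ref_sites[[tx]]
    cs <- summarize_consensus(split(st, st$predictor))
    cbind(data.frame(transcript_id = tx, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(as.integer(cs), make.names(names(cs))))),
          total = attr(cs, "total"))
  }))
  if (is.null(consensus)) consensus <- data.frame()
  write_tsv(consensus, file.path(out_dir, "consensus.tsv"))

  stage_log("ase", "%d SNPs", length(snps))
  ase <- list()
  for (snp in snps) {
    for (sm in names(snp$allele_counts)) {
      ac <- snp$allele_counts[[sm]]
      if (sum(ac) == 0) next
      tst <- binomial_ase_test(ac[1], ac[2], alpha = config$ase_alpha)
      ase[[length(ase) + 1L]] <- data.frame(
        snp_id = snp$snp_id, sample = sm, ref_reads = ac[1],
        var_reads = ac[2], p_value = tst$p_value,
        significant = tst$significant, stringsAsFactors = FALSE)
    }
  }
  ase <- if (length(ase)) do.call(rbind, ase) else
    data.frame(snp_id = character(0), sample = character(0),
               ref_reads = integer(0), var_reads = integer(0),
               p_value = numeric(0), significant = logical(0))
  write_tsv(ase, file.path(out_dir, "ase_tests.tsv"))

  inverse <- data.frame(snp_id = character(0), mirna_name = character(0),
                        gene = character(0), status = character(0),
                        n_tissues = integer(0), min_fisher_p = numeric(0),
                        concordant = logical(0), flagged = logical(0))
  if (all(c("allelic_counts_tsv", "mirna_expr_tsv", "mrna_expr_tsv") %in%
          names(paths))) {
    stage_log("coexpression", "flagging inverse expression")
    inverse <- flag_inverse_expression(
      polymirts, read_tsv(paths[["allelic_counts_tsv"]]),
      read_tsv(paths[["mirna_expr_tsv"]]),
      read_tsv(paths[["mrna_expr_tsv"]]), config)
  }
  write_tsv(inverse, file.path(out_dir, "inverse_flags.tsv"))

  manifest <- list(
    tool = "polymirts",
    version = as.character(utils::packageVersion("polymirts")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    inputs = as.list(vapply(paths[names(paths) != "out_dir"], function(p)
      unname(tools::md5sum(p)), character(1))),
    counts = list(
      snps_input = n_input_snps,
      snps_after_quality_depth_utr = n_after_quality,
      snps_after_known_merge = n_after_merge,
      snps_after_mappability = length(snps),
      reference_sites = nrow(all_sites),
      sites_per_predictor = as.list(table(all_sites$predictor)),
      polymirts_by_status = as.list(table(polymirts$status)),
      ase_tests = nrow(ase),
      ase_significant = sum(ase$significant),
      inverse_pairs_evaluated = nrow(inverse),
      inverse_pairs_flagged = if (nrow(inverse)) sum(inverse$flagged) else 0L))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done", "outputs in %s", out_dir)
  invisible(out_dir)
}

#' Write a complete synthetic scenario directory
#'
#' Emits every input the pipeline consumes -- genome FASTA, UTR BED, miRNA
#' FASTA, SNP VCF, a full-coverage depth BedGraph, expression TSVs -- plus a
#' `truth.jsonl` ground-truth file and a ready-to-run `config.txt`.
#'
#' @param dir output directory.
#' @param n_genes,n_mirnas,n_created,n_disrupted,n_neutral,utr_len scenario
#'   shape (see [synth_polymirts_scenario()]).
#' @param rng_seed integer seed.
#' @param config a [pipeline_config()] written into `config.txt`.
#' @return invisibly, the scenario (with `dir` attached).
#' @export
write_scenario <- function(dir, n_genes = 20L, n_mirnas = 10L,
                           n_created = 3L, n_disrupted = 3L, n_neutral = 3L,
                           utr_len = 300L, rng_seed = 1L,
                           config = pipeline_config(rng_seed = rng_seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- synth_mirnas(n_mirnas, rng_seed)
  sc <- synth_polymirts_scenario(n_genes, mirnas, n_created, n_disrupted,
                                 n_neutral, utr_len, rng_seed)
  write_genome_fasta(sc$genome, file.path(dir, "genome.fa"))
  write_utr_bed(sc$utrs, file.path(dir, "utrs.bed"))
  write_mirna_fasta(mirnas, file.path(dir, "mirnas.fa"))
  write_snps_vcf(sc$snps, file.path(dir, "snps.vcf"))
  # uniform depth 20 everywhere: every UTR fully covered
  write_bedgraph(lapply(setNames(nchar(sc$genome), names(sc$genome)),
                        function(n) rep(20L, n)),
                 file.path(dir, "depth.bedgraph"))
  truth_lines <- vapply(seq_len(nrow(sc$truth)), function(i)
    jsonlite::toJSON(as.list(sc$truth[i, ]), auto_unbox = TRUE,
                     na = "null"), character(1))
  writeLines(truth_lines, file.path(dir, "truth.jsonl"))
  cfg_lines <- c(
    sprintf("genome_fasta = %s", file.path(dir, "genome.fa")),
    sprintf("utr_annotation = %s", file.path(dir, "utrs.bed")),
    sprintf("mirna_fasta = %s", file.path(dir, "mirnas.fa")),
    sprintf("snps_vcf = %s", file.path(dir, "snps.vcf")),
    sprintf("depth_bedgraph = %s", file.path(dir, "depth.bedgraph")),
    sprintf("out_dir = %s", file.path(dir, "out")),
    vapply(setdiff(names(config), c("strand_mode", "mappability_window")),
           function(k) sprintf("%s = %s", k, format(config[[k]])),
           character(1)),
    sprintf("strand_mode = %s", config$strand_mode))
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  attr(sc, "dir") <- dir
  invisible(sc)
}
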
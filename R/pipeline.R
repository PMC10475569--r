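#' Pipeline run configuration
#'
#' Bundles all parameters of a pipeline invocation. Defaults reproduce the
#' scan's standard settings: 10,000-bp windows sliding in 5,000-bp steps,
#' 5% tails, variant filters QUAL > 30 / 5x < depth < 18x / missing < 0.1,
#' extreme-difference threshold 0.95, strong-LD threshold r2 >= 0.8.
#'
#' @param subcommand One of `"simulate"`, `"scan"`, `"loci"`, `"ld"`,
#'   `"assoc"`, `"expr"`.
#' @param vcf,groups,genes,counts,ct Input file paths (which are required
#'   depends on the subcommand): genotype VCF, sample-to-group TSV, gene
#'   interval BED/TSV, locus-count CSV, long-format Ct CSV.
#' @param numerator Numerator group label for the log2 pi ratio (required
#'   by `scan`).
#' @param window_size,step Scan window size and step (bp).
#' @param tail_q Tail fraction, strictly in (0, 0.5).
#' @param qual_min,dp_low,dp_high,miss_max Variant filter thresholds.
#' @param min_freq Extreme-difference threshold.
#' @param r2_threshold Strong-LD threshold.
#' @param target_gene,reference_gene,calibrator Expression settings for
#'   `expr` (target assay, housekeeping assay, calibrator group).
#' @param sim A [sim_config()] for `simulate` (its seed is overridden by
#'   `seed`).
#' @param seed Integer seed applied to every stochastic step.
#' @param out Output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(subcommand,
                       vcf = NULL, groups = NULL, genes = NULL,
                       counts = NULL, ct = NULL,
                       numerator = NULL,
                       window_size = 10000, step = 5000, tail_q = 0.05,
                       qual_min = 30, dp_low = 5, dp_high = 18,
                       miss_max = 0.1, min_freq = 0.95, r2_threshold = 0.8,
                       target_gene = "MITF", reference_gene = "GAPDH",
                       calibrator = NULL,
                       sim = sim_config(), seed = 1L, out = "beakscan_out") {
  subcommand <- as.character(subcommand)
  if (!subcommand %in% c("simulate", "scan", "loci", "ld", "assoc", "expr")) {
    abort(paste0("unknown subcommand: ", subcommand))
  }
  if (!is.numeric(tail_q) || tail_q <= 0 || tail_q >= 0.5) {
    abort("usage error: --tail-q must lie strictly between 0 and 0.5")
  }
  structure(
    list(subcommand = subcommand, vcf = vcf, groups = groups, genes = genes,
         counts = counts, ct = ct, numerator = numerator,
         window_size = window_size, step = step, tail_q = tail_q,
         qual_min = qual_min, dp_low = dp_low, dp_high = dp_high,
         miss_max = miss_max, min_freq = min_freq,
         r2_threshold = r2_threshold, target_gene = target_gene,
         reference_gene = reference_gene, calibrator = calibrator,
         sim = sim, seed = as.integer(seed), out = out),
    class = "run_config"
  )
}

#' Execute a pipeline subcommand
#'
#' Runs the configured stage, writes its artifacts under `config$out`, and
#' writes a JSON run manifest (`manifest.json`) recording the parameters,
#' seed, package version, input checksums and every artifact path.
#' Identical configuration and seed yield byte-identical outputs.
#'
#' Subcommands: `simulate` (panel VCF + group map + truth BED), `scan`
#' (per-window TSV + merged-region BED), `loci` (per-locus counts and the
#' extreme-difference subset), `ld` (pairwise LD TSV + square r2 CSV),
#' `assoc` (frequency/chi-square report from a locus-count CSV), `expr`
#' (per-sample folds + group summary + ANOVA from a long Ct CSV).
#'
#' @param config A [run_config()].
#' @return Invisibly, a character vector of artifact paths (manifest last).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(vcf = config$vcf, groups = config$groups, genes = config$genes,
              counts = config$counts, ct = config$ct)
  for (p in inputs) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input file not found: ", p))
    }
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  artifacts <- switch(
    config$subcommand,
    simulate = pipeline_simulate(config),
    scan = pipeline_scan(config),
    loci = pipeline_loci(config),
    ld = pipeline_ld(config),
    assoc = pipeline_assoc(config),
    expr = pipeline_expr(config)
  )
  manifest <- file.path(config$out, "manifest.json")
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(
    list(
      tool = "beakscan",
      version = as.character(utils::packageVersion("beakscan")),
      subcommand = config$subcommand,
      seed = config$seed,
      parameters = cfg[!vapply(cfg, is.null, TRUE)],
      input_checksums = if (length(inputs)) {
        as.list(tools::md5sum(unlist(inputs)))
      } else list(),
      artifacts = as.list(artifacts)
    ),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  inform(paste0("[", config$subcommand, "] wrote ", length(artifacts),
                " artifact(s) to ", config$out))
  invisible(c(artifacts, manifest))
}

write_tsv_plain <- function(df, path) {
  df <- as_tibble(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ","), "")
    }
  }
  readr::write_tsv(df, path, progress = FALSE)
  path
}

load_panel <- function(config, filter = TRUE) {
  if (is.null(config$vcf) || is.null(config$groups)) {
    abort("usage error: this subcommand requires --vcf and --groups")
  }
  m <- read_vcf(config$vcf, read_group_map(config$groups))
  n0 <- n_variants(m)
  if (filter) {
    m <- filter_variants(m, config$qual_min, config$dp_low, config$dp_high,
                         config$miss_max)
    inform(paste0("variant filter: ", n0, " -> ", n_variants(m),
                  " biallelic SNPs retained"))
    if (n_variants(m) == 0) abort("no variants pass the filters")
  }
  m
}

pipeline_simulate <- function(config) {
  cfg <- config$sim
  cfg$seed <- config$seed
  m <- simulate_two_pop(sim_config(
    n_pop1 = cfg$n_pop1, n_pop2 = cfg$n_pop2, chrom = cfg$chrom,
    chrom_length = cfg$chrom_length, n_snps = cfg$n_snps,
    sweep_start = cfg$sweep_start, sweep_end = cfg$sweep_end,
    background_beta = cfg$background_beta, sweep_freqs = cfg$sweep_freqs,
    groups = cfg$groups, seed = cfg$seed
  ))
  vcf <- file.path(config$out, "simulated.vcf")
  gmap <- file.path(config$out, "groups.tsv")
  truth <- file.path(config$out, "sweep_truth.bed")
  write_vcf(m, vcf)
  write_group_map(m$samples, gmap)
  tr <- sweep_truth(m)
  tr$name <- "planted_sweep"
  write_bed(tr, truth)
  c(vcf, gmap, truth)
}

pipeline_scan <- function(config) {
  m <- load_panel(config)
  genes <- if (!is.null(config$genes)) read_intervals(config$genes) else NULL
  sc <- scan_selection(m, genes = genes, size = config$window_size,
                       step = config$step, q = config$tail_q,
                       numerator = config$numerator)
  inform(paste0("scan: ", nrow(sc$windows), " windows -> ",
                nrow(sc$selected), " selected -> ", nrow(sc$regions),
                " merged regions (", length(unique(unlist(sc$regions$genes))),
                " genes)"))
  wtsv <- file.path(config$out, "windows.tsv")
  rbed <- file.path(config$out, "regions.bed")
  ttsv <- file.path(config$out, "thresholds.tsv")
  write_tsv_plain(tidy(sc), wtsv)
  write_bed(sc$regions, rbed, name_col = "genes")
  write_tsv_plain(sc$thresholds, ttsv)
  c(wtsv, rbed, ttsv)
}

pipeline_loci <- function(config) {
  m <- load_panel(config)
  counts <- counts_by_group(m)
  extreme <- extreme_diff_filter(counts, min_freq = config$min_freq)
  inform(paste0("loci: ", n_variants(m), " loci -> ", nrow(extreme),
                " extreme-difference loci at min_freq ", config$min_freq))
  ctsv <- file.path(config$out, "locus_counts.tsv")
  etsv <- file.path(config$out, "extreme_loci.tsv")
  write_tsv_plain(frequency_report(counts), ctsv)
  write_tsv_plain(extreme, etsv)
  c(ctsv, etsv)
}

pipeline_ld <- function(config) {
  m <- load_panel(config)
  extreme <- extreme_diff_filter(counts_by_group(m),
                                 min_freq = config$min_freq)
  loci <- which(paste(m$variants$chrom, m$variants$pos) %in%
                  paste(extreme$chrom, extreme$pos))
  if (length(loci) < 2) {
    abort("fewer than 2 extreme-difference loci: nothing to pair")
  }
  ld <- ld_matrix(m, loci, r2_threshold = config$r2_threshold)
  inform(paste0("ld: ", length(loci), " loci, ", nrow(ld), " pairs, ",
                sprintf("%.1f%%", 100 * attr(ld, "frac_high")),
                " with r2 >= ", config$r2_threshold))
  ptsv <- file.path(config$out, "ld_pairs.tsv")
  rcsv <- file.path(config$out, "r2_matrix.csv")
  stsv <- file.path(config$out, "ld_summary.tsv")
  write_tsv_plain(as_tibble(ld), ptsv)
  utils::write.csv(r2_matrix(ld), rcsv)
  write_tsv_plain(glance(ld), stsv)
  c(ptsv, rcsv, stsv)
}

pipeline_assoc <- function(config) {
  if (is.null(config$counts)) {
    abort("usage error: assoc requires --counts (locus-count CSV)")
  }
  counts <- readr::read_csv(config$counts, show_col_types = FALSE,
                            progress = FALSE)
  report <- frequency_report(counts)
  tests <- counts |>
    group_by(.data$chrom, .data$pos) |>
    dplyr::group_modify(~ assoc_test(.x)) |>
    ungroup()
  rtsv <- file.path(config$out, "frequency_report.tsv")
  atsv <- file.path(config$out, "association.tsv")
  write_tsv_plain(report, rtsv)
  write_tsv_plain(tests, atsv)
  c(rtsv, atsv)
}

pipeline_expr <- function(config) {
  if (is.null(config$ct) || is.null(config$calibrator)) {
    abort("usage error: expr requires --ct and --calibrator")
  }
  long <- readr::read_csv(config$ct, show_col_types = FALSE, progress = FALSE)
  records <- ct_records_from_long(long, config$target_gene,
                                  config$reference_gene)
  folds <- delta_delta_ct(records, config$calibrator)
  ftsv <- file.path(config$out, "fold_changes.tsv")
  gtsv <- file.path(config$out, "group_summary.tsv")
  ttsv <- file.path(config$out, "group_test.tsv")
  write_tsv_plain(folds, ftsv)
  write_tsv_plain(expression_summary(folds), gtsv)
  write_tsv_plain(group_test(folds), ttsv)
  c(ftsv, gtsv, ttsv)
}
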
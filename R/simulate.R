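#' Configuration for the two-population simulator
#'
#' Describes a diploid SNP panel for two populations diverged at a planted
#' genomic interval ("sweep"). Outside the sweep both populations share an
#' ancestral alternate-allele frequency drawn per SNP from a Beta
#' distribution; inside the sweep each population has its own fixed
#' frequency, emulating near-fixed opposite alleles between phenotype
#' groups. Genotypes are drawn binomially from the population frequency,
#' i.e. Hardy-Weinberg equilibrium within each population, with free
#' recombination (no background LD) between sites.
#'
#' @param n_pop1,n_pop2 Diploid sample counts per population.
#' @param chrom Chromosome name used for all simulated SNPs.
#' @param chrom_length Chromosome length in bp.
#' @param n_snps Number of SNPs, placed uniformly at random positions.
#' @param sweep_start,sweep_end 1-based inclusive bounds of the planted
#'   divergent interval.
#' @param background_beta Length-2 shape parameters of the Beta distribution
#'   for ancestral alternate-allele frequencies outside the sweep.
#' @param sweep_freqs Length-2 alternate-allele frequencies inside the sweep,
#'   `(p_pop1, p_pop2)`.
#' @param groups Length-2 character labels for the two populations
#'   (population 1 first).
#' @param seed Integer RNG seed; identical configs give identical panels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pop1 = 20, n_pop2 = 20, chrom = "10",
                       chrom_length = 1e6, n_snps = 2000,
                       sweep_start = 400001, sweep_end = 500000,
                       background_beta = c(0.8, 0.8),
                       sweep_freqs = c(0.98, 0.02),
                       groups = c("black", "yellow"), seed = 1L) {
  cfg <- list(
    n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
    chrom = as.character(chrom), chrom_length = as.integer(chrom_length),
    n_snps = as.integer(n_snps),
    sweep_start = as.integer(sweep_start), sweep_end = as.integer(sweep_end),
    background_beta = as.numeric(background_beta),
    sweep_freqs = as.numeric(sweep_freqs),
    groups = as.character(groups), seed = as.integer(seed)
  )
  if (cfg$n_snps < 1) abort("`n_snps` must be >= 1")
  if (cfg$n_pop1 < 1 || cfg$n_pop2 < 1) abort("population sizes must be >= 1")
  if (any(cfg$sweep_freqs < 0 | cfg$sweep_freqs > 1)) {
    abort("`sweep_freqs` must lie in [0, 1]")
  }
  if (cfg$sweep_start < 1 || cfg$sweep_end > cfg$chrom_length ||
      cfg$sweep_start > cfg$sweep_end) {
    abort("sweep interval must lie within the chromosome")
  }
  if (length(cfg$background_beta) != 2 || any(cfg$background_beta <= 0)) {
    abort("`background_beta` must be two positive shape parameters")
  }
  if (length(cfg$groups) != 2 || anyDuplicated(cfg$groups)) {
    abort("`groups` must be two distinct labels")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-population genotype panel with a planted sweep
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()]. The planted interval is attached as attribute
#'   `"sweep"` (a one-row tibble `chrom`, `start`, `end`), retrievable with
#'   [sweep_truth()]. Per-variant `qual` and `site_depth` are drawn inside
#'   the default filter-passing ranges so the simulated panel survives
#'   [filter_variants()] unchanged.
#' @examples
#' m <- simulate_two_pop(sim_config(n_snps = 200, seed = 7))
#' sweep_truth(m)
#' @export
simulate_two_pop <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  pos <- sort(sample.int(config$chrom_length, config$n_snps, replace = FALSE))
  in_sweep <- pos >= config$sweep_start & pos <= config$sweep_end

  p_bg <- rbeta(config$n_snps, config$background_beta[1],
                config$background_beta[2])
  p1 <- ifelse(in_sweep, config$sweep_freqs[1], p_bg)
  p2 <- ifelse(in_sweep, config$sweep_freqs[2], p_bg)

  draw <- function(n, p) {
    matrix(rbinom(n * length(p), size = 2, prob = rep(p, each = n)),
           nrow = n, ncol = length(p))
  }
  calls <- rbind(draw(config$n_pop1, p1), draw(config$n_pop2, p2))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  samples <- tibble(
    sample_id = c(sprintf("%s_%02d", config$groups[1],
                          seq_len(config$n_pop1)),
                  sprintf("%s_%02d", config$groups[2],
                          seq_len(config$n_pop2))),
    group = rep(config$groups, c(config$n_pop1, config$n_pop2))
  )
  m <- geno_matrix(
    calls = calls,
    variants = tibble(
      chrom = config$chrom, pos = pos, ref = ref, alt = unname(alt),
      qual = round(runif(config$n_snps, 40, 60), 1),
      site_depth = round(runif(config$n_snps, 8, 15), 2)
    ),
    samples = samples
  )
  attr(m, "sweep") <- tibble(chrom = config$chrom,
                             start = config$sweep_start,
                             end = config$sweep_end)
  attr(m, "config") <- config
  m
}

#' Planted sweep interval of a simulated panel
#' @param m A matrix produced by [simulate_two_pop()].
#' @return One-row tibble (`chrom`, `start`, `end`), or `NULL` if `m` was
#'   not simulated.
#' @export
sweep_truth <- function(m) attr(m, "sweep", exact = TRUE)

#' Simulate paired two-locus haplotypes and their diploid genotypes
#'
#' Draws two haplotypes per individual from the four two-locus haplotype
#' classes and records both the true phase and the collapsed unphased
#' genotypes, providing ground truth for the EM haplotype-frequency
#' estimator.
#'
#' @param n Number of diploid individuals (0 allowed: empty output).
#' @param hap_freqs Length-4 frequencies of haplotypes
#'   `(alt-alt, alt-ref, ref-alt, ref-ref)`, i.e. alleles at
#'   (locus 1, locus 2); must be non-negative and sum to 1 within 1e-9.
#' @param seed Integer RNG seed.
#' @return A tibble with one row per individual: `sample_id`, `hap_a`,
#'   `hap_b` (haplotype codes `"11"`, `"10"`, `"01"`, `"00"`; 1 = alternate
#'   allele), and alt dosages `g1`, `g2` at the two loci.
#' @export
simulate_haplotype_pairs <- function(n, hap_freqs, seed = 1L) {
  if (any(hap_freqs < 0)) abort("haplotype frequencies must be non-negative")
  if (abs(sum(hap_freqs) - 1) > 1e-9) {
    abort("haplotype frequencies must sum to 1")
  }
  codes <- c("11", "10", "01", "00")
  if (n == 0) {
    return(tibble(sample_id = character(), hap_a = character(),
                  hap_b = character(), g1 = integer(), g2 = integer()))
  }
  set.seed(seed)
  idx <- sample.int(4, 2 * n, replace = TRUE, prob = hap_freqs)
  a <- codes[idx[seq_len(n)]]
  b <- codes[idx[n + seq_len(n)]]
  first <- function(h) as.integer(substr(h, 1, 1))
  second <- function(h) as.integer(substr(h, 2, 2))
  tibble(
    sample_id = sprintf("ind_%04d", seq_len(n)),
    hap_a = a, hap_b = b,
    g1 = first(a) + first(b),
    g2 = second(a) + second(b)
  )
}

#' Two-locus genotype count table
#'
#' Cross-tabulates alt dosages at two loci into the 3x3 table consumed by
#' [em_hap_freqs()]. Individuals missing at either locus are excluded
#' (pairwise deletion).
#'
#' @param g1,g2 Integer vectors of alt dosages (0/1/2, `NA` = missing).
#' @return A 3x3 integer matrix; rows index dosage at locus 1 (0,1,2),
#'   columns dosage at locus 2.
#' @export
two_locus_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  mat <- matrix(as.integer(tab), nrow = 3, ncol = 3,
                dimnames = list(locus1 = 0:2, locus2 = 0:2))
  mat
}

#' Packaged genotype-count tables for the MITF beak-colour marker
#'
#' Returns transcriptions of the observed genotype counts for the duck
#' beak-colour candidate region on chromosome 10 of the ASM874695v1
#' assembly: the 41 extreme-difference intronic loci of *MITF* in the
#' resequenced discovery birds (20 yellow-beaked, 40 black-beaked), and the
#' marker SNP 10:g.17814522T>A genotyped in the discovery pools, an F2
#' validation population (20 vs 20), three yellow-beaked breeds
#' (Cherry Valley, Jingding, Ji'an Red) and two black-beaked breeds
#' (Gaoyou, Liancheng White).
#'
#' @return A named list of tibbles:
#' \describe{
#'   \item{extreme_loci}{one row per locus x group: `chrom`, `pos`, `ref`,
#'     `alt`, `group`, `n_ref_ref`, `n_het`, `n_alt_alt`.}
#'   \item{marker_genotypes}{one row per genotyped population: `cohort`
#'     (`discovery`, `f2`, `breeds`), `population`, `beak_color`, locus
#'     columns, and the three genotype counts.}
#' }
#' @export
mitf_fixture_tables <- function() {
  ext <- system.file("extdata", package = "beakscan")
  list(
    extreme_loci = readr::read_csv(
      file.path(ext, "mitf_extreme_loci.csv"),
      col_types = "ciccciii", progress = FALSE),
    marker_genotypes = readr::read_csv(
      file.path(ext, "mitf_marker_genotypes.csv"),
      col_types = "ccccicciii", progress = FALSE)
  )
}
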
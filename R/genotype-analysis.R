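#' Per-locus genotype counts by group
#'
#' Tallies ref/ref, heterozygote and alt/alt calls per variant within each
#' group, excluding missing calls, and derives the group alternate-allele
#' frequency `(n_het + 2 n_alt_alt) / (2 n_called)`.
#'
#' @param m A [geno_matrix()].
#' @return A tibble with one row per locus x group: `chrom`, `pos`, `ref`,
#'   `alt`, `group`, `n_ref_ref`, `n_het`, `n_alt_alt`, `n_called`,
#'   `alt_freq` (`NaN` where no calls).
#' @export
counts_by_group <- function(m) {
  stopifnot(inherits(m, "geno_matrix"))
  grps <- group_levels(m)
  v <- m$variants
  rows <- lapply(grps, function(g) {
    sub <- m$calls[m$samples$group == g, , drop = FALSE]
    n_rr <- colSums(sub == 0L, na.rm = TRUE)
    n_ra <- colSums(sub == 1L, na.rm = TRUE)
    n_aa <- colSums(sub == 2L, na.rm = TRUE)
    n <- n_rr + n_ra + n_aa
    tibble(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, group = g,
      n_ref_ref = as.integer(n_rr), n_het = as.integer(n_ra),
      n_alt_alt = as.integer(n_aa), n_called = as.integer(n),
      alt_freq = (n_ra + 2 * n_aa) / (2 * n)
    )
  })
  bind_rows(rows) |> arrange(.data$chrom, .data$pos, .data$group)
}

# Accept either counts_by_group() output or a raw count tibble; ensures the
# derived columns exist.
normalise_locus_counts <- function(loci) {
  loci <- as_tibble(loci)
  if (!"group" %in% names(loci) && "population" %in% names(loci)) {
    loci$group <- loci$population
  }
  need <- c("group", "n_ref_ref", "n_het", "n_alt_alt")
  if (!all(need %in% names(loci))) {
    abort(paste0("locus counts need columns: ", paste(need, collapse = ", ")))
  }
  if (!"pos" %in% names(loci)) loci$pos <- 1L
  if (!"chrom" %in% names(loci)) loci$chrom <- "."
  if (!"ref" %in% names(loci)) loci$ref <- NA_character_
  if (!"alt" %in% names(loci)) loci$alt <- NA_character_
  loci$n_called <- loci$n_ref_ref + loci$n_het + loci$n_alt_alt
  loci$alt_freq <- (loci$n_het + 2 * loci$n_alt_alt) / (2 * loci$n_called)
  loci
}

#' Extreme-difference locus filter
#'
#' Retains loci at which the alternate allele is near-fixed in one group
#' (frequency `>= min_freq`) and near-absent in the other
#' (`<= 1 - min_freq`), in either orientation — i.e. loci where the ref
#' sequence is essentially private to one phenotype group and the alt
#' sequence to the other. Loci with no counted birds in either group are
#' not considered. Raising `min_freq` can only shrink the retained set.
#'
#' @param loci Per-locus group counts ([counts_by_group()] output, or any
#'   tibble with `chrom`, `pos`, `group`, `n_ref_ref`, `n_het`,
#'   `n_alt_alt`, exactly two groups per locus).
#' @param min_freq Near-fixation threshold (default 0.95).
#' @return A tibble with one row per retained locus: locus id columns plus
#'   `group_high`/`freq_high` (the near-fixed group) and
#'   `group_low`/`freq_low`.
#' @export
extreme_diff_filter <- function(loci, min_freq = 0.95) {
  stopifnot(min_freq > 0.5, min_freq <= 1)
  loci <- normalise_locus_counts(loci)
  wide <- loci |>
    group_by(.data$chrom, .data$pos) |>
    filter(n() == 2, all(.data$n_called > 0)) |>
    summarise(
      ref = .data$ref[1], alt = .data$alt[1],
      g1 = .data$group[1], g2 = .data$group[2],
      f1 = .data$alt_freq[1], f2 = .data$alt_freq[2],
      .groups = "drop"
    )
  hit1 <- wide$f1 >= min_freq & wide$f2 <= 1 - min_freq
  hit2 <- wide$f2 >= min_freq & wide$f1 <= 1 - min_freq
  out <- wide[hit1 | hit2, , drop = FALSE]
  high_is_1 <- out$f1 >= out$f2
  tibble(
    chrom = out$chrom, pos = out$pos, ref = out$ref, alt = out$alt,
    group_high = ifelse(high_is_1, out$g1, out$g2),
    freq_high = ifelse(high_is_1, out$f1, out$f2),
    group_low = ifelse(high_is_1, out$g2, out$g1),
    freq_low = ifelse(high_is_1, out$f2, out$f1)
  ) |> arrange(.data$chrom, .data$pos)
}

#' Group-by-allele contingency table
#'
#' Collapses genotype counts to allele counts per group: ref alleles
#' `2 n_ref_ref + n_het`, alt alleles `n_het + 2 n_alt_alt`. Total alleles
#' equal twice the birds counted.
#'
#' @param lc Tibble of genotype counts for one locus, one row per group
#'   (columns `group`, `n_ref_ref`, `n_het`, `n_alt_alt`).
#' @return Integer matrix, groups x (ref, alt); column names use the `ref`
#'   and `alt` allele strings when present.
#' @export
allele_table <- function(lc) {
  lc <- normalise_locus_counts(lc)
  refs <- 2L * lc$n_ref_ref + lc$n_het
  alts <- lc$n_het + 2L * lc$n_alt_alt
  cn <- c(lc$ref[1], lc$alt[1])
  if (anyNA(cn)) cn <- c("ref", "alt")
  matrix(c(refs, alts), ncol = 2,
         dimnames = list(lc$group, cn))
}

#' Group-by-genotype contingency table
#'
#' Rows are groups, columns the three genotype classes; columns with zero
#' counts in every group are dropped so the chi-square degrees of freedom
#' adjust automatically.
#'
#' @inheritParams allele_table
#' @return Integer matrix, groups x (up to 3) genotype classes.
#' @export
genotype_table <- function(lc) {
  lc <- normalise_locus_counts(lc)
  tab <- matrix(c(lc$n_ref_ref, lc$n_het, lc$n_alt_alt), ncol = 3,
                dimnames = list(lc$group, c("ref_ref", "het", "alt_alt")))
  tab[, colSums(tab) > 0, drop = FALSE]
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson test without continuity correction:
#' `X2 = sum((O - E)^2 / E)` with expectations from the row/column margins
#' and `df = (rows - 1)(cols - 1)`. All-zero rows and columns are pruned
#' first; a table that cannot form a valid test afterwards is an error.
#'
#' @param tab Matrix of non-negative counts (>= 2 rows and columns after
#'   pruning).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' pearson_chi2(matrix(c(2, 30, 38, 10), nrow = 2)) # X2 = 40.833
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) {
    abort("counts must be non-negative with positive grand total")
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("need at least 2 rows and 2 columns with counts")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Marker association test between two groups at one locus
#'
#' Builds the allele-level 2x2 table (default; matches how validation
#' chi-squares for this marker are reported) or the genotype-level table,
#' and runs [pearson_chi2()].
#'
#' @inheritParams allele_table
#' @param level `"allele"` (default) or `"genotype"`.
#' @return One-row tibble: `level`, `statistic`, `df`, `p_value`.
#' @export
assoc_test <- function(lc, level = c("allele", "genotype")) {
  level <- match.arg(level)
  tab <- if (level == "allele") allele_table(lc) else genotype_table(lc)
  bind_cols(tibble(level = level), pearson_chi2(tab))
}

# Half-up decimal rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-12) / 10^digits
}

#' Genotype and allele frequency report
#'
#' Per-group genotype frequencies (count over group total) and allele
#' frequencies, rounded half-up at the presentation layer.
#'
#' @param loci Tibble of genotype counts (any number of loci/groups;
#'   columns as in [counts_by_group()]).
#' @param digits Decimal places for the rounded presentation columns
#'   (default 2).
#' @return A tibble echoing the counts plus `freq_ref_ref`, `freq_het`,
#'   `freq_alt_alt`, `freq_ref`, `freq_alt` (all rounded half-up).
#' @export
frequency_report <- function(loci, digits = 2) {
  lc <- normalise_locus_counts(loci)
  ref_alleles <- 2 * lc$n_ref_ref + lc$n_het
  tot <- 2 * lc$n_called
  mutate(
    lc,
    freq_ref_ref = round_half_up(.data$n_ref_ref / .data$n_called, digits),
    freq_het = round_half_up(.data$n_het / .data$n_called, digits),
    freq_alt_alt = round_half_up(.data$n_alt_alt / .data$n_called, digits),
    freq_ref = round_half_up(ref_alleles / tot, digits),
    freq_alt = round_half_up(1 - ref_alleles / tot, digits)
  )
}
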
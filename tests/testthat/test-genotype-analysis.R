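test_that("counts_by_group matches an independent tally loop and skips missing calls", {
  m <- simulate_two_pop(sim_config(n_pop1 = 8, n_pop2 = 6, n_snps = 40,
                                   chrom_length = 1e5, sweep_start = 4e4,
                                   sweep_end = 5e4, seed = 13))
  m$calls[cbind(sample.int(14, 10, replace = TRUE),
                sample.int(40, 10, replace = TRUE))] <- NA_integer_
  counts <- counts_by_group(m)

  # brute-force oracle: explicit loops over samples and variants
  for (row in sample.int(nrow(counts), 20)) {
    lc <- counts[row, ]
    j <- which(m$variants$pos == lc$pos)
    tallies <- c(0L, 0L, 0L)
    for (i in seq_len(n_samples(m))) {
      if (m$samples$group[i] != lc$group) next
      g <- m$calls[i, j]
      if (is.na(g)) next
      tallies[g + 1L] <- tallies[g + 1L] + 1L
    }
    expect_equal(c(lc$n_ref_ref, lc$n_het, lc$n_alt_alt), tallies)
  }

  # an all-missing locus yields zero counts in both groups
  m$calls[, 5] <- NA_integer_
  counts2 <- counts_by_group(m)
  at5 <- counts2[counts2$pos == m$variants$pos[5], ]
  expect_equal(at5$n_called, c(0L, 0L))
})

test_that("the discovery pools show fully opposite marker genotypes", {
  fx <- mitf_fixture_tables()
  disc <- dplyr::filter(fx$marker_genotypes, cohort == "discovery")
  yellow <- dplyr::filter(disc, beak_color == "yellow")
  black <- dplyr::filter(disc, beak_color == "black")
  expect_equal(c(yellow$n_ref_ref, yellow$n_het, yellow$n_alt_alt),
               c(0L, 0L, 20L))
  expect_equal(c(black$n_ref_ref, black$n_het, black$n_alt_alt),
               c(40L, 0L, 0L))
})

test_that("extreme-difference filter retains the 41 packaged loci at 0.95 and is monotone", {
  fx <- mitf_fixture_tables()
  expect_equal(nrow(extreme_diff_filter(fx$extreme_loci, 0.95)), 41)
  # the 0.975/0.025 loci drop out at a stricter threshold
  strict <- extreme_diff_filter(fx$extreme_loci, 0.99)
  expect_lt(nrow(strict), 41)
  expect_false(17827159 %in% strict$pos)
  # a 0.975-vs-0 locus is retained at the default
  default <- extreme_diff_filter(fx$extreme_loci, 0.95)
  expect_true(17827159 %in% default$pos)

  # monotone in min_freq
  sizes <- vapply(c(0.8, 0.9, 0.95, 0.975, 0.99, 1),
                  function(t) nrow(extreme_diff_filter(fx$extreme_loci, t)),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a balanced locus is rejected by the extreme-difference filter", {
  lc <- tibble::tibble(
    chrom = "1", pos = 1L, ref = "A", alt = "G",
    group = c("g1", "g2"),
    n_ref_ref = c(5L, 5L), n_het = c(10L, 10L), n_alt_alt = c(5L, 5L)
  )
  expect_equal(nrow(extreme_diff_filter(lc, 0.95)), 0)
})

test_that("allele tables conserve alleles and match hand arithmetic", {
  fx <- mitf_fixture_tables()
  f2 <- dplyr::filter(fx$marker_genotypes, cohort == "f2")
  tab <- allele_table(f2)
  expect_equal(unname(tab),
               matrix(c(2L, 30L, 38L, 10L), nrow = 2)) # [[2,38],[30,10]]
  expect_equal(colnames(tab), c("T", "A"))
  # total alleles = 2 x birds counted
  expect_equal(sum(tab), 2 * sum(f2$n_ref_ref + f2$n_het + f2$n_alt_alt))

  gaoyou <- dplyr::filter(fx$marker_genotypes, population == "Gaoyou Duck")
  expect_equal(unname(allele_table(gaoyou)[1, ]), c(53L, 5L))

  het_only <- tibble::tibble(group = c("a", "b"), n_ref_ref = 0L,
                             n_het = c(10L, 4L), n_alt_alt = 0L)
  ht <- allele_table(het_only)
  expect_equal(ht[, 1], ht[, 2])
})

test_that("genotype tables drop empty classes so df adjusts", {
  fx <- mitf_fixture_tables()
  f2 <- dplyr::filter(fx$marker_genotypes, cohort == "f2")
  gt <- genotype_table(f2)
  expect_equal(unname(gt), matrix(c(0L, 10L, 2L, 10L, 18L, 0L), nrow = 2))

  no_het <- tibble::tibble(group = c("a", "b"), n_ref_ref = c(5L, 1L),
                           n_het = 0L, n_alt_alt = c(2L, 6L))
  expect_equal(ncol(genotype_table(no_het)), 2)
  expect_equal(pearson_chi2(genotype_table(no_het))$df, 1)
})

test_that("Pearson chi-square reproduces the published marker statistic", {
  fx <- mitf_fixture_tables()
  f2 <- dplyr::filter(fx$marker_genotypes, cohort == "f2")
  res <- pearson_chi2(allele_table(f2))
  expect_equal(res$statistic, 40.833, tolerance = 0.001 / 40.833)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$df, 1)
})

test_that("chi-square basics: independence, permutation invariance, margin-formula agreement", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- pearson_chi2(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(41)
  for (i in 1:50) {
    nr <- sample(2:3, 1)
    nc <- sample(2:3, 1)
    tab <- matrix(rpois(nr * nc, lambda = 15) + 1, nr, nc)
    got <- pearson_chi2(tab)
    want <- chi2_margin_oracle(tab)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    # invariant under row/column permutation
    perm <- tab[sample(nr), sample(nc), drop = FALSE]
    expect_equal(pearson_chi2(perm)$statistic, got$statistic,
                 tolerance = 1e-12)
  }

  expect_error(pearson_chi2(matrix(c(0, 0, 5, 7), 2)), "at least 2")
  expect_error(pearson_chi2(matrix(0, 2, 2)), "grand total")
})

test_that("assoc_test offers allele (default) and genotype forms", {
  fx <- mitf_fixture_tables()
  f2 <- dplyr::filter(fx$marker_genotypes, cohort == "f2")
  al <- assoc_test(f2)
  expect_equal(al$level, "allele")
  expect_equal(al$df, 1)
  gt <- assoc_test(f2, level = "genotype")
  expect_equal(gt$df, 2)
  expect_lt(gt$p_value, 0.001)
})

test_that("frequency report reproduces printed allele frequencies with half-up rounding", {
  fx <- mitf_fixture_tables()
  f2 <- frequency_report(dplyr::filter(fx$marker_genotypes, cohort == "f2"))
  yellow <- f2[f2$population == "F2 yellow", ]
  black <- f2[f2$population == "F2 black", ]
  expect_equal(c(yellow$freq_ref, yellow$freq_alt), c(0.05, 0.95))
  expect_equal(c(black$freq_ref, black$freq_alt), c(0.75, 0.25))
  expect_equal(c(yellow$freq_het, yellow$freq_alt_alt), c(0.10, 0.90))

  breeds <- frequency_report(
    dplyr::filter(fx$marker_genotypes, cohort == "breeds"))
  expect_equal(breeds$freq_ref[breeds$population == "Gaoyou Duck"], 0.91)
  expect_equal(breeds$freq_ref[breeds$population == "Liancheng White Duck"],
               0.78)
})

test_that("exact frequencies sum to one before any rounding", {
  set.seed(59)
  lc <- tibble::tibble(
    chrom = "1", pos = rep(1:10, each = 2), ref = "A", alt = "G",
    group = rep(c("g1", "g2"), 10),
    n_ref_ref = rpois(20, 5), n_het = rpois(20, 5), n_alt_alt = rpois(20, 5)
  )
  n <- lc$n_ref_ref + lc$n_het + lc$n_alt_alt
  geno_sum <- (lc$n_ref_ref + lc$n_het + lc$n_alt_alt) / n
  allele_sum <- (2 * lc$n_ref_ref + lc$n_het) / (2 * n) +
    (lc$n_het + 2 * lc$n_alt_alt) / (2 * n)
  expect_equal(geno_sum, rep(1, 20))
  expect_equal(allele_sum, rep(1, 20))
  # high-precision report columns agree with the exact ratios
  rep10 <- frequency_report(lc, digits = 10)
  expect_equal(rep10$freq_ref + rep10$freq_alt, rep(1, 20), tolerance = 1e-9)
})
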
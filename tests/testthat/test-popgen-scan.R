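test_that("site_pi equals brute-force pairwise counting", {
  expect_equal(site_pi(0, 40), 0)
  expect_equal(site_pi(20, 40), 400 / 780) # 0.5128...
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))

  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    alt <- sample(0:n, 1)
    expect_equal(site_pi(alt, n), brute_pi(alt, n))
  }
})

test_that("Weir-Cockerham components match an independent transcription of the 1984 formulas", {
  set.seed(17)
  for (i in 1:100) {
    ni <- sample(5:40, 2, replace = TRUE)
    alt <- c(sample(0:(2 * ni[1]), 1), sample(0:(2 * ni[2]), 1))
    # heterozygote count consistent with the allele count
    het <- vapply(1:2, function(k) {
      hmax <- min(alt[k], 2 * ni[k] - alt[k])
      if (hmax < 1) return(0)
      cand <- seq(alt[k] %% 2, hmax, by = 2)
      cand[sample.int(length(cand), 1)]
    }, numeric(1))
    got <- wc_fst_components(alt[1], 2 * ni[1], het[1],
                             alt[2], 2 * ni[2], het[2])
    want <- wc_oracle(p = alt / (2 * ni), n_ind = ni, h = het / ni)
    expect_equal(c(got$a, got$b, got$c), unname(want), tolerance = 1e-12)
  }
})

test_that("per-site theta is 1 for a fixed difference and near 0 without differentiation", {
  comp <- wc_fst_components(0, 40, 0, 40, 40, 0)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
  # unequal sample sizes too
  comp2 <- wc_fst_components(0, 40, 0, 80, 80, 0)
  expect_equal(comp2$a / (comp2$a + comp2$b + comp2$c), 1)

  # equal frequencies, HWE heterozygosity: average theta near zero
  set.seed(23)
  thetas <- replicate(300, {
    n <- 30
    p <- runif(1, 0.2, 0.8)
    g1 <- rbinom(n, 2, p)
    g2 <- rbinom(n, 2, p)
    comp <- wc_fst_components(sum(g1), 2 * n, sum(g1 == 1),
                              sum(g2), 2 * n, sum(g2 == 1))
    den <- comp$a + comp$b + comp$c
    if (den > 0) comp$a / den else NA_real_
  })
  expect_lt(abs(mean(thetas, na.rm = TRUE)), 0.05)
})

test_that("windows tile from position 1 with the step; trailing partials are flagged", {
  m <- geno_matrix(
    matrix(c(0L, 2L), 2, 4),
    tibble::tibble(chrom = "1", pos = c(1000L, 8000L, 13000L, 20000L),
                   ref = "A", alt = "C"),
    tibble::tibble(sample_id = c("x", "y"), group = c("g1", "g2"))
  )
  w <- windowed_stats(m, size = 10000, step = 5000, numerator = "g1")
  full <- w[!w$partial, ]
  expect_equal(full$start, c(1L, 5001L, 10001L))
  expect_equal(full$end, full$start + 9999L)
  expect_true(all(w$partial[w$start > 10001]))
  # SNP membership: pos 8000 in windows [1,10000] and [5001,15000]
  expect_equal(full$n_snps, c(2L, 2L, 2L))
})

test_that("an all-fixed-difference window has weighted F_ST exactly 1 and ratio undefined", {
  m <- fixed_diff_matrix(n1 = 20, n2 = 40, n_snps = 20)
  w <- windowed_stats(m, numerator = "black")
  full <- w[!w$partial & w$n_snps > 0, ]
  expect_true(nrow(full) >= 1)
  expect_equal(full$fst, rep(1, nrow(full)), tolerance = 1e-12)
  # both populations monomorphic -> zero diversity -> undefined log2 ratio
  expect_true(all(is.na(full$log2_ratio)))
})

test_that("equal nonzero diversity in both groups gives a log2 ratio of 0", {
  calls <- rbind(matrix(c(0L, 1L, 2L, 1L), 4, 10),
                 matrix(c(1L, 2L, 0L, 1L), 4, 10))
  m <- geno_matrix(
    calls,
    tibble::tibble(chrom = "1", pos = seq(100L, 1000L, by = 100L),
                   ref = "A", alt = "C"),
    tibble::tibble(sample_id = sprintf("s%d", 1:8),
                   group = rep(c("g1", "g2"), each = 4))
  )
  w <- windowed_stats(m, size = 1000, step = 1000, numerator = "g1")
  expect_equal(w$pi_pop1[1], w$pi_pop2[1])
  expect_equal(w$log2_ratio[1], 0)
})

test_that("tail thresholds are empirical quantiles excluding undefined windows", {
  grid <- tibble::tibble(
    chrom = "1", start = seq(1L, by = 10000L, length.out = 100),
    end = seq(10000L, by = 10000L, length.out = 100),
    n_snps = 5L, pi_pop1 = 1e-3, pi_pop2 = 1e-3,
    fst = seq(0, 0.99, by = 0.01),
    log2_ratio = seq(-2, 1.96, by = 0.04),
    partial = FALSE
  )
  th <- tail_thresholds(grid, q = 0.05)
  expect_gte(th$fst_cut, 0.94)
  sel <- select_windows(grid, th)
  expect_equal(sum(grid$fst >= th$fst_cut), 5)

  # symmetric ratios give symmetric cuts
  sym <- grid
  sym$log2_ratio <- c(seq(-1, 1, length.out = 100))
  th2 <- tail_thresholds(sym, q = 0.05)
  expect_equal(th2$ratio_low_cut, -th2$ratio_high_cut)

  # undefined entries are excluded from the quantile computation
  with_na <- grid
  with_na$fst[1:50] <- NA
  th3 <- tail_thresholds(with_na, q = 0.05)
  expect_equal(th3$fst_cut,
               unname(quantile(grid$fst[51:100], 0.95, type = 7)))

  expect_error(tail_thresholds(grid, q = 0.5), "strictly between")
  expect_error(tail_thresholds(grid, q = 0), "strictly between")
  all_na <- grid
  all_na$fst <- NA_real_
  expect_error(tail_thresholds(all_na), "no windows")
})

test_that("selection requires both the F_ST tail and a ratio tail, and ignores input order", {
  w <- tibble::tibble(
    chrom = "1", start = c(1L, 10001L, 20001L), end = c(10000L, 20000L, 30000L),
    n_snps = 5L, pi_pop1 = 1e-3, pi_pop2 = 1e-3,
    fst = c(0.95, 0.96, 0.2),
    log2_ratio = c(0.0, 1.5, 1.5), # window 1: high fst, median ratio
    partial = FALSE
  )
  th <- tibble::tibble(fst_cut = 0.9, ratio_low_cut = -1, ratio_high_cut = 1,
                       q = 0.05)
  sel <- select_windows(w, th)
  expect_equal(sel$start, 10001L)
  # ties at the cut are included
  th_tie <- tibble::tibble(fst_cut = 0.96, ratio_low_cut = -1.5,
                           ratio_high_cut = 1.5, q = 0.05)
  expect_equal(select_windows(w, th_tie)$start, 10001L)
  # order invariance
  sel_rev <- select_windows(w[3:1, ], th)
  expect_equal(sel_rev, sel)
})

test_that("overlapping and adjacent windows merge; genes annotate by 1-bp overlap", {
  sel <- tibble::tibble(
    chrom = "1", start = c(1L, 5001L, 45001L), end = c(10000L, 15000L, 55000L),
    n_snps = 1L, pi_pop1 = 1, pi_pop2 = 1, fst = 1, log2_ratio = 2,
    partial = FALSE
  )
  genes <- tibble::tibble(
    chrom = "1", start = c(2000L, 14000L, 30000L),
    end = c(3000L, 20000L, 40000L),
    name = c("GENE_A", "GENE_B", "GENE_C")
  )
  reg <- merge_and_annotate(sel, genes)
  expect_equal(nrow(reg), 2) # 30-kb gap keeps two regions
  expect_equal(reg$start, c(1L, 45001L))
  expect_equal(reg$end, c(15000L, 55000L))
  expect_equal(sort(reg$genes[[1]]), c("GENE_A", "GENE_B"))
  expect_equal(reg$genes[[2]], character())
  expect_equal(reg$n_windows, c(2L, 1L))

  expect_equal(nrow(merge_and_annotate(sel[0, ], genes)), 0)
})

test_that("gene profiles rank a swept gene above a neutral one", {
  m <- simulate_two_pop(sim_config(n_snps = 2000, seed = 7))
  genes <- tibble::tibble(
    chrom = "10", start = c(420001L, 800001L), end = c(470000L, 850000L),
    name = c("SWEPT", "NEUTRAL")
  )
  prof_in <- gene_fst_profile(m, genes[1, ], numerator = "black")
  prof_out <- gene_fst_profile(m, genes[2, ], numerator = "black")
  all_w <- windowed_stats(m, numerator = "black")
  expect_gt(max(prof_in$fst, na.rm = TRUE),
            median(all_w$fst, na.rm = TRUE))
  expect_gt(max(prof_in$fst, na.rm = TRUE),
            max(prof_out$fst, na.rm = TRUE))
  expect_error(gene_fst_profile(m, tibble::tibble(chrom = "99", start = 1L,
                                                  end = 2L, name = "X")),
               "not present")
})

test_that("PCA separates the simulated populations on PC1", {
  m <- simulate_two_pop(sim_config(n_snps = 2000, seed = 7))
  pc <- pca_components(m, k = 2)
  black <- pc$PC1[pc$group == "black"]
  yellow <- pc$PC1[pc$group == "yellow"]
  # zero overlap between the groups' PC1 ranges
  expect_true(max(black) < min(yellow) || max(yellow) < min(black))
  expect_gt(mean_silhouette(pc$PC1, pc$group), 0.8)
  expect_error(pca_components(m, k = 100), "exceeds")
})

test_that("a duplicated sample lands on identical PCA coordinates", {
  m <- simulate_two_pop(sim_config(n_pop1 = 6, n_pop2 = 6, n_snps = 200,
                                   seed = 3))
  m2 <- m[c(1, 1, 2:12), ]
  m2$samples$sample_id <- make.unique(m2$samples$sample_id)
  pc <- pca_components(m2, k = 2)
  expect_equal(unlist(pc[1, c("PC1", "PC2")]),
               unlist(pc[2, c("PC1", "PC2")]), tolerance = 1e-9)
})

test_that("scan_selection recovers the planted sweep and exposes tidy/glance/autoplot", {
  m <- simulate_two_pop(sim_config(n_snps = 2000, seed = 7))
  genes <- tibble::tibble(chrom = "10", start = 420001L, end = 470000L,
                          name = "SWEPT")
  sc <- scan_selection(m, genes = genes, numerator = "black")
  tr <- sweep_truth(m)
  overlaps <- sc$regions$start <= tr$end & sc$regions$end >= tr$start
  expect_true(any(overlaps))
  expect_true("SWEPT" %in% unlist(sc$regions$genes))

  td <- tidy(sc)
  expect_equal(sum(td$selected), nrow(sc$selected))
  gl <- glance(sc)
  expect_equal(gl$n_selected, nrow(sc$selected))
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_pca(pca_components(m, 2)), "ggplot")
})

test_that("windowed scans demand exactly two groups", {
  m <- simulate_two_pop(sim_config(n_pop1 = 4, n_pop2 = 4, n_snps = 50,
                                   seed = 1))
  m$samples$group[1:2] <- "third"
  m3 <- geno_matrix(m$calls, m$variants, m$samples)
  expect_error(windowed_stats(m3), "exactly 2 groups")
})
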
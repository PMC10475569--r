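# Independent oracles: brute-force / textbook re-derivations kept separate
# from the package's implementation paths.

# Per-site diversity by literally counting differing allele pairs.
brute_pi <- function(alt, n) {
  alleles <- c(rep(1L, alt), rep(0L, n - alt))
  if (n < 2) return(NA_real_)
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Scalar transcription of the Weir & Cockerham (1984) two-population
# variance components, coded directly from the published equations in
# their notation (p_i allele freqs, n_i diploid counts, h_i observed
# heterozygote proportions).
wc_oracle <- function(p, n_ind, h) {
  r <- 2
  nbar <- sum(n_ind) / r
  nc <- (r * nbar - sum(n_ind^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_ind * p) / (r * nbar)
  s2 <- sum(n_ind * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_ind * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Pearson chi-square recomputed from the margin formula.
chi2_margin_oracle <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Multinomial log-likelihood of a 3x3 two-locus genotype table given
# haplotype frequencies (f11, f10, f01, f00), written with explicit loops
# over compatible ordered gamete pairs -- independent of the package's
# vectorised class-probability code.
ll_oracle <- function(counts, f) {
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  p_class <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      g1 <- hap[i, 1] + hap[j, 1]
      g2 <- hap[i, 2] + hap[j, 2]
      p_class[g1 + 1, g2 + 1] <- p_class[g1 + 1, g2 + 1] + f[i] * f[j]
    }
  }
  p_class[p_class < 0] <- 0 # guard the feasibility boundary (f ~ -1e-17)
  if (any(counts[p_class <= 0] > 0)) return(-Inf)
  sum(counts[p_class > 0] * log(p_class[p_class > 0]))
}

# Maximum log-likelihood over a fine grid of f11 with allele-frequency
# margins fixed at their observed values (the EM solution must match it).
grid_max_loglik <- function(counts, n_grid = 2001) {
  n <- sum(counts)
  p_a <- sum(c(0, 1, 2) * rowSums(counts)) / (2 * n)
  p_b <- sum(c(0, 1, 2) * colSums(counts)) / (2 * n)
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  f11 <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(f11, function(x) {
    ll_oracle(counts, c(x, p_a - x, p_b - x, 1 - p_a - p_b + x))
  }, 0)
  max(ll)
}

mean_silhouette <- function(values, labels) {
  s <- cluster::silhouette(as.integer(factor(labels)), stats::dist(values))
  mean(s[, 3])
}
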
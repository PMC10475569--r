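#' Per-site nucleotide diversity
#'
#' Unbiased mean pairwise difference at one biallelic site:
#' `2 * alt * (n - alt) / (n * (n - 1))` for `alt` alternate alleles among
#' `n` called alleles. Equals the fraction of differing allele pairs among
#' all `choose(n, 2)` pairs. Vectorised.
#'
#' @param alt_count Alternate-allele counts.
#' @param total_called Total called alleles (2 x called diploids).
#' @return Numeric vector; `NA` where fewer than 2 alleles were called.
#' @examples
#' site_pi(20, 40) # 400 differing pairs / 780 pairs
#' @export
site_pi <- function(alt_count, total_called) {
  stopifnot(all(alt_count >= 0, na.rm = TRUE),
            all(alt_count <= total_called, na.rm = TRUE))
  out <- 2 * alt_count * (total_called - alt_count) /
    (total_called * (total_called - 1))
  out[total_called < 2] <- NA_real_
  out
}

#' Weir-Cockerham (1984) variance components for two populations
#'
#' Computes the among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) variance components of the Weir & Cockerham
#' F-statistics estimator for a biallelic site observed in two populations.
#' The per-site estimate is `a / (a + b + c)`; windowed ("weighted") F_ST
#' aggregates as `sum(a) / sum(a + b + c)` over sites. A site monomorphic
#' for the same allele in both populations yields components `(0, 0, 0)`
#' and contributes nothing. Vectorised over sites.
#'
#' @param alt1,alt2 Alternate-allele counts per population.
#' @param n1,n2 Called-allele totals per population (2 x called diploids;
#'   must be >= 2).
#' @param het1,het2 Heterozygous-individual counts per population.
#' @return Tibble with numeric columns `a`, `b`, `c`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst_components <- function(alt1, n1, het1, alt2, n2, het2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  r <- 2
  ni1 <- n1 / 2 # diploid individuals
  ni2 <- n2 / 2
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  h1 <- het1 / ni1
  h2 <- het2 / ni2

  nbar <- (ni1 + ni2) / r
  nc <- (r * nbar - (ni1^2 + ni2^2) / (r * nbar)) / (r - 1)
  pbar <- (ni1 * p1 + ni2 * p2) / (r * nbar)
  s2 <- (ni1 * (p1 - pbar)^2 + ni2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (ni1 * h1 + ni2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  # same-allele monomorphic sites carry no information
  mono <- (pbar == 0 | pbar == 1) & s2 == 0 & hbar == 0
  a[mono] <- 0
  b[mono] <- 0
  cc[mono] <- 0
  tibble(a = a, b = b, c = cc)
}

#' Hudson-estimator F_ST components for two populations
#'
#' Numerator/denominator of the Hudson (1992) estimator in the
#' Bhatia et al. (2013) formulation, for sensitivity checks against the
#' default Weir-Cockerham scan. Window F_ST aggregates as
#' `sum(num) / sum(den)`.
#'
#' @inheritParams wc_fst_components
#' @return Tibble with columns `num` and `den`.
#' @export
hudson_fst_components <- function(alt1, n1, alt2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble(num = num, den = den)
}

#' Sliding-window diversity and differentiation scan
#'
#' Tiles each chromosome with windows of `size` bp starting at position 1
#' and advancing by `step` bp, and computes per window: SNP count,
#' per-population nucleotide diversity per bp (theta-pi, summed site
#' diversity divided by the window span), weighted F_ST (ratio of summed
#' variance components), and the log2 ratio of numerator-group over
#' denominator-group diversity. A SNP at position p belongs to every window
#' whose span covers p. Windows extending past the chromosome end are
#' emitted with `partial = TRUE`; windows with no SNPs (or an undefined
#' ratio) carry `NA` statistics.
#'
#' @param m A [geno_matrix()] with exactly two groups.
#' @param size Window size in bp (default 10,000).
#' @param step Step between window starts in bp (default 5,000).
#' @param numerator Group label used as the numerator of the pi ratio.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @param chrom_lengths Optional named vector of chromosome lengths; by
#'   default the largest observed position per chromosome.
#' @return A tibble of class `window_stats`: `chrom`, `start`, `end`,
#'   `n_snps`, `pi_pop1` (numerator group), `pi_pop2`, `fst`, `log2_ratio`,
#'   `partial`. Attributes record `size`, `step`, `numerator`,
#'   `denominator` and `estimator`.
#' @export
windowed_stats <- function(m, size = 10000, step = 5000, numerator = NULL,
                           estimator = c("wc", "hudson"),
                           chrom_lengths = NULL) {
  estimator <- match.arg(estimator)
  grps <- two_groups(m, numerator)
  t1 <- group_site_tallies(m, grps[1])
  t2 <- group_site_tallies(m, grps[2])

  pi1 <- site_pi(t1$alt, t1$called)
  pi2 <- site_pi(t2$alt, t2$called)
  usable <- t1$called >= 2 & t2$called >= 2
  if (estimator == "wc") {
    comp <- wc_fst_components(t1$alt[usable], t1$called[usable],
                              t1$het[usable],
                              t2$alt[usable], t2$called[usable],
                              t2$het[usable])
    fnum <- fden <- rep(0, n_variants(m))
    fnum[usable] <- comp$a
    fden[usable] <- comp$a + comp$b + comp$c
  } else {
    comp <- hudson_fst_components(t1$alt[usable], t1$called[usable],
                                  t2$alt[usable], t2$called[usable])
    fnum <- fden <- rep(0, n_variants(m))
    fnum[usable] <- comp$num
    fden[usable] <- comp$den
  }
  pi1[is.na(pi1)] <- 0
  pi2[is.na(pi2)] <- 0

  v <- m$variants
  res <- lapply(unique(v$chrom), function(chr) {
    idx <- which(v$chrom == chr)
    pos <- v$pos[idx]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths)) {
      as.integer(chrom_lengths[[chr]])
    } else max(pos)
    starts <- seq.int(1L, len, by = step)
    ends <- starts + as.integer(size) - 1L
    lo <- findInterval(starts - 1L, pos) + 1L
    hi <- findInterval(ends, pos)
    nsnp <- pmax(hi - lo + 1L, 0L)
    agg <- function(x) {
      cs <- c(0, cumsum(x[idx]))
      ifelse(nsnp > 0, cs[hi + 1L] - cs[lo], 0)
    }
    w_pi1 <- agg(pi1) / size
    w_pi2 <- agg(pi2) / size
    w_fn <- agg(fnum)
    w_fd <- agg(fden)
    fst <- ifelse(nsnp > 0 & w_fd > 0, w_fn / w_fd, NA_real_)
    lr <- ifelse(nsnp > 0 & w_pi1 > 0 & w_pi2 > 0,
                 log2(w_pi1 / w_pi2), NA_real_)
    tibble(
      chrom = chr, start = starts, end = ends, n_snps = nsnp,
      pi_pop1 = ifelse(nsnp > 0, w_pi1, NA_real_),
      pi_pop2 = ifelse(nsnp > 0, w_pi2, NA_real_),
      fst = fst, log2_ratio = lr,
      partial = ends > len
    )
  })
  out <- bind_rows(res)
  attr(out, "size") <- size
  attr(out, "step") <- step
  attr(out, "numerator") <- grps[1]
  attr(out, "denominator") <- grps[2]
  attr(out, "estimator") <- estimator
  class(out) <- c("window_stats", class(out))
  out
}

#' Empirical tail thresholds for the sweep-selection rule
#'
#' Computes the `(1 - q)` quantile of window F_ST (right tail) and the `q`
#' and `(1 - q)` quantiles of the log2 pi-ratio (both tails), using the
#' type-7 empirical quantile. Windows with undefined statistics, and
#' partial trailing windows, are excluded from the quantile computation.
#'
#' @param stats A [windowed_stats()] tibble.
#' @param q Tail fraction, strictly between 0 and 0.5 (default 0.05).
#' @return One-row tibble: `fst_cut`, `ratio_low_cut`, `ratio_high_cut`, `q`.
#' @export
tail_thresholds <- function(stats, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q <= 0 || q >= 0.5) {
    abort("`q` must lie strictly between 0 and 0.5")
  }
  full <- stats[!stats$partial, , drop = FALSE]
  fst <- full$fst[!is.na(full$fst)]
  lr <- full$log2_ratio[!is.na(full$log2_ratio)]
  if (length(fst) == 0 || length(lr) == 0) {
    abort("no windows with defined statistics")
  }
  tibble(
    fst_cut = unname(quantile(fst, 1 - q, type = 7)),
    ratio_low_cut = unname(quantile(lr, q, type = 7)),
    ratio_high_cut = unname(quantile(lr, 1 - q, type = 7)),
    q = q
  )
}

#' Select sweep-signal windows by tail intersection
#'
#' Retains full windows lying simultaneously in the F_ST right tail
#' (`fst >= fst_cut`) and in either pi-ratio tail
#' (`log2_ratio <= ratio_low_cut` or `>= ratio_high_cut`). Ties at a cut
#' are included; windows with undefined statistics are never selected.
#'
#' @param stats A [windowed_stats()] tibble.
#' @param thresholds Output of [tail_thresholds()].
#' @return The selected subset of `stats` (attributes preserved).
#' @export
select_windows <- function(stats, thresholds) {
  keep <- !is.na(stats$fst) & !is.na(stats$log2_ratio) & !stats$partial &
    stats$fst >= thresholds$fst_cut &
    (stats$log2_ratio <= thresholds$ratio_low_cut |
       stats$log2_ratio >= thresholds$ratio_high_cut)
  out <- stats[keep, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Merge selected windows into regions and annotate genes
#'
#' Overlapping or book-ended selected windows are merged into maximal
#' regions (via \pkg{GenomicRanges}); a gene is assigned to a region when
#' their intervals overlap by at least 1 bp. Gene names are deduplicated.
#'
#' @param selected Selected windows ([select_windows()] output).
#' @param genes Optional gene intervals ([read_intervals()] tibble:
#'   `chrom`, `start`, `end`, `name`).
#' @return Tibble with one row per merged region: `chrom`, `start`, `end`,
#'   `n_windows`, and a list-column `genes` of overlapping gene names.
#' @export
merge_and_annotate <- function(selected, genes = NULL) {
  if (nrow(selected) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), genes = list()))
  }
  win <- GenomicRanges::GRanges(
    selected$chrom, IRanges::IRanges(selected$start, selected$end))
  reg <- GenomicRanges::reduce(win)
  n_win <- GenomicRanges::countOverlaps(reg, win)
  gene_names <- rep(list(character()), length(reg))
  if (!is.null(genes) && nrow(genes) > 0) {
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(reg, gr_genes, minoverlap = 1L)
    for (i in unique(S4Vectors::queryHits(hits))) {
      nm <- genes$name[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
      gene_names[[i]] <- unique(nm[!is.na(nm)])
    }
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(reg)),
    start = GenomicRanges::start(reg),
    end = GenomicRanges::end(reg),
    n_windows = as.integer(n_win),
    genes = gene_names
  )
}

#' Per-window F_ST profile across a gene
#'
#' Recomputes the sliding-window scan and restricts it to windows
#' overlapping the gene span padded by one window on each side, for
#' plotting selective-sweep profiles or ranking candidate genes by maximum
#' or mean F_ST.
#'
#' @param m A [geno_matrix()] with exactly two groups.
#' @param gene One-row data frame (`chrom`, `start`, `end`, `name`).
#' @param size,step Window size and step in bp.
#' @param numerator Numerator group for the pi ratio.
#' @param pad Padding in bp on each side of the gene (default one window).
#' @return A `window_stats` tibble (possibly empty) with an added `gene`
#'   column.
#' @export
gene_fst_profile <- function(m, gene, size = 10000, step = 5000,
                             numerator = NULL, pad = size) {
  stopifnot(nrow(gene) == 1)
  if (!gene$chrom %in% m$variants$chrom) {
    abort(paste0("chromosome ", gene$chrom, " not present in the panel"))
  }
  stats <- windowed_stats(m, size = size, step = step, numerator = numerator)
  hit <- stats$chrom == gene$chrom &
    stats$end >= gene$start - pad & stats$start <= gene$end + pad
  out <- stats[hit, , drop = FALSE]
  out$gene <- if (nrow(out)) gene$name else character()
  out
}

#' Genotype principal components
#'
#' Standard genotype PCA for population structure: each site is centred by
#' its mean dosage and scaled by `sqrt(2 p (1 - p))` with `p` the sample
#' alternate-allele frequency; missing calls are mean-imputed per site;
#' monomorphic sites (`p` of 0 or 1) are dropped. Sample coordinates on the
#' top `k` axes are the principal-component scores (axis signs are
#' arbitrary).
#'
#' @param m A [geno_matrix()] with at least 2 samples and 2 variants.
#' @param k Number of components (<= number of samples).
#' @return Tibble `sample_id`, `group`, `PC1`..`PCk`, with the proportion
#'   of variance explained in attribute `"var_explained"`.
#' @export
pca_components <- function(m, k = 2) {
  if (n_samples(m) < 2 || n_variants(m) < 2) {
    abort("PCA needs at least 2 samples and 2 variants")
  }
  if (k > n_samples(m)) abort("`k` exceeds the number of samples")
  x <- m$calls
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) abort("all sites are monomorphic")
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  sdv <- sqrt(2 * p * (1 - p))
  z <- sweep(x, 2, mu, "-")
  z[is.na(z)] <- 0 # mean imputation after centring
  z <- sweep(z, 2, sdv, "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- bind_cols(m$samples, as_tibble(scores))
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}
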
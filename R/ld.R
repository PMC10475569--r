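#' EM estimation of two-locus haplotype frequencies
#'
#' Estimates the four haplotype frequencies of a pair of biallelic loci
#' from unphased diploid genotype counts by expectation-maximisation. Only
#' the double-heterozygote class is phase-ambiguous; the E-step splits its
#' gametes between the coupling (alt-alt / ref-ref) and repulsion
#' (alt-ref / ref-alt) phases in proportion to their current haplotype
#' products, and the M-step re-counts gametes. Iteration stops when the
#' largest frequency change falls below `tol` or after `max_iter` steps.
#' The multinomial log-likelihood is non-decreasing across iterations
#' (checked at every step). With no double heterozygotes the first M-step
#' equals direct gamete counting and the algorithm stops immediately.
#'
#' Because the likelihood in the one free parameter (the alt-alt haplotype
#' frequency, with allele margins fixed by the data) can be bimodal, EM is
#' run from three starts: uniform (0.25 each) and two margin-preserving
#' starts leaning towards the coupling and repulsion phase. The
#' highest-likelihood fit is returned. When the coupling and repulsion
#' modes are exactly tied (phase-uninformative data, e.g. a table of pure
#' double heterozygotes) the symmetric uniform-start fit is returned and
#' flagged `saddle = TRUE`.
#'
#' @param counts 3x3 matrix of genotype counts, rows = alt dosage at
#'   locus 1 (0, 1, 2), columns = alt dosage at locus 2
#'   (see [two_locus_counts()]).
#' @param tol Convergence tolerance on haplotype frequencies.
#' @param max_iter Iteration cap.
#' @return List of class `hap_em`: `hap_freqs` (named numeric, order
#'   `alt_alt`, `alt_ref`, `ref_alt`, `ref_ref`), `n` individuals,
#'   `n_iter`, `converged`, `loglik`, `saddle`.
#' @export
em_hap_freqs <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0)) {
    abort("`counts` must be a non-negative 3x3 genotype count matrix")
  }
  n <- sum(counts)
  if (n < 1) abort("no individuals in the genotype table")

  # fixed gamete contributions from phase-unambiguous classes
  # (f11, f10, f01, f00) = (alt_alt, alt_ref, ref_alt, ref_ref)
  n11_amb <- counts[2, 2]
  fixed <- c(
    f11 = counts[2, 3] + counts[3, 2] + 2 * counts[3, 3],
    f10 = counts[2, 1] + 2 * counts[3, 1] + counts[3, 2],
    f01 = counts[1, 2] + 2 * counts[1, 3] + counts[2, 3],
    f00 = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
  )

  loglik_of <- function(f) {
    p <- geno_class_probs(f)
    ll <- sum(counts[p > 0] * log(p[p > 0]))
    if (any(counts[p == 0] > 0)) -Inf else ll
  }

  run_em <- function(f0) {
    f <- f0
    ll_old <- loglik_of(f)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      coup <- f[[1]] * f[[4]]
      rep_ <- f[[2]] * f[[3]]
      pc <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
      gam <- fixed + n11_amb * c(pc, 1 - pc, 1 - pc, pc)
      f_new <- gam / (2 * n)
      ll_new <- loglik_of(f_new)
      if (ll_new < ll_old - 1e-8) {
        abort("internal error: EM log-likelihood decreased")
      }
      delta <- max(abs(f_new - f))
      f <- f_new
      ll_old <- ll_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    list(f = f, loglik = ll_old, n_iter = iter, converged = converged)
  }

  fit_sym <- run_em(rep(0.25, 4))
  # margin-preserving starts towards each phase orientation
  p_a <- sum(c(0, 1, 2) * rowSums(counts)) / (2 * n)
  p_b <- sum(c(0, 1, 2) * colSums(counts)) / (2 * n)
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  phase_start <- function(f11) {
    c(f11, p_a - f11, p_b - f11, 1 - p_a - p_b + f11)
  }
  fit_coup <- run_em(phase_start(lo + 0.9 * (hi - lo)))
  fit_rep <- run_em(phase_start(lo + 0.1 * (hi - lo)))

  saddle <- FALSE
  if (n11_amb > 0 && abs(fit_coup$loglik - fit_rep$loglik) <= 1e-9 &&
      max(abs(fit_coup$f - fit_rep$f)) > tol * 10) {
    # phase-uninformative: both orientations fit equally well; report the
    # symmetric stationary point rather than an arbitrary orientation
    best <- fit_sym
    saddle <- TRUE
  } else {
    fits <- list(fit_sym, fit_coup, fit_rep)
    best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  }
  structure(
    list(hap_freqs = setNames(unname(best$f),
                              c("alt_alt", "alt_ref", "ref_alt", "ref_ref")),
         n = n, n_iter = best$n_iter, converged = best$converged,
         loglik = best$loglik, saddle = saddle),
    class = "hap_em"
  )
}

# P(genotype class) under random union of gametes; f in order
# (f11, f10, f01, f00). Returns 3x3 matrix aligned with the count table.
geno_class_probs <- function(f) {
  f11 <- f[[1]]; f10 <- f[[2]]; f01 <- f[[3]]; f00 <- f[[4]]
  matrix(c(
    f00^2,            2 * f00 * f01,                   f01^2,
    2 * f00 * f10,    2 * f00 * f11 + 2 * f01 * f10,   2 * f01 * f11,
    f10^2,            2 * f10 * f11,                   f11^2
  ), nrow = 3, byrow = TRUE)
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Computes the raw disequilibrium coefficient
#' `D = f_altalt - p1 * p2` (with `p1`, `p2` the alternate-allele
#' frequencies at the two loci), its normalised magnitude
#' `D' = |D| / Dmax`, and the squared allelic correlation
#' `r2 = D^2 / (p1 (1-p1) p2 (1-p2))`. If either locus is monomorphic the
#' statistics are undefined and returned as `NA` (not an error).
#'
#' @param hap_freqs Length-4 frequencies in the order
#'   `(alt_alt, alt_ref, ref_alt, ref_ref)` (as from [em_hap_freqs()],
#'   whose `hap_freqs` element can be passed directly).
#' @return One-row tibble: `D`, `d_prime`, `r2`.
#' @examples
#' ld_stats(c(0.5, 0, 0, 0.5)) # complete coupling: D' = 1, r2 = 1
#' @export
ld_stats <- function(hap_freqs) {
  f <- as.numeric(hap_freqs)
  stopifnot(length(f) == 4, all(f >= -1e-12))
  if (abs(sum(f) - 1) > 1e-6) abort("haplotype frequencies must sum to 1")
  p1 <- f[1] + f[2]
  p2 <- f[1] + f[3]
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    return(tibble(D = NA_real_, d_prime = NA_real_, r2 = NA_real_))
  }
  D <- f[1] - p1 * p2
  dmax <- if (D >= 0) {
    min(p1 * (1 - p2), (1 - p1) * p2)
  } else {
    min(p1 * p2, (1 - p1) * (1 - p2))
  }
  d_prime <- if (dmax > 0) abs(D) / dmax else NA_real_
  r2 <- D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  tibble(D = D, d_prime = d_prime, r2 = r2)
}

#' LD between one pair of loci from unphased genotypes
#'
#' Pairwise-deletes individuals missing at either locus, estimates
#' haplotype frequencies by EM, and returns the LD statistics.
#'
#' @param g1,g2 Alt-dosage vectors (0/1/2/`NA`) at the two loci.
#' @return One-row tibble: `D`, `d_prime`, `r2`, `n`, `n_iter`, `converged`.
#' @export
ld_pair <- function(g1, g2) {
  em <- em_hap_freqs(two_locus_counts(g1, g2))
  bind_cols(ld_stats(em$hap_freqs),
            tibble(n = em$n, n_iter = em$n_iter, converged = em$converged))
}

#' Pairwise LD across a set of loci
#'
#' Computes EM-based D, D' and r2 for every unordered pair of the chosen
#' loci and summarises the fraction of defined pairs in strong LD
#' (`r2 >= r2_threshold`).
#'
#' @param m A [geno_matrix()].
#' @param loci Variant indices into `m` (default: all variants).
#' @param r2_threshold Strong-LD threshold on r2 (default 0.8).
#' @return A tibble of class `ld_scan`, one row per pair: `chrom_i`,
#'   `pos_i`, `chrom_j`, `pos_j`, `D`, `d_prime`, `r2`, `n`, `converged`.
#'   Attribute `"frac_high"` holds the strong-LD fraction and
#'   `"r2_threshold"` the threshold; see [glance.ld_scan()].
#' @export
ld_matrix <- function(m, loci = NULL, r2_threshold = 0.8) {
  stopifnot(inherits(m, "geno_matrix"))
  if (is.null(loci)) loci <- seq_len(n_variants(m))
  if (length(loci) < 2) abort("need at least 2 loci for pairwise LD")
  v <- m$variants[loci, , drop = FALSE]
  idx <- utils::combn(seq_along(loci), 2)
  pairs <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    bind_cols(
      tibble(chrom_i = v$chrom[i], pos_i = v$pos[i],
             chrom_j = v$chrom[j], pos_j = v$pos[j]),
      ld_pair(m$calls[, loci[i]], m$calls[, loci[j]])
    )
  })
  out <- bind_rows(pairs)
  defined <- !is.na(out$r2)
  attr(out, "r2_threshold") <- r2_threshold
  attr(out, "frac_high") <- if (any(defined)) {
    mean(out$r2[defined] >= r2_threshold)
  } else NA_real_
  class(out) <- c("ld_scan", class(out))
  out
}

#' Strong-LD summary of a pairwise LD scan
#'
#' @param x An `ld_scan` tibble from [ld_matrix()].
#' @param ... Unused.
#' @return One-row tibble: `n_pairs`, `n_defined`, `r2_threshold`,
#'   `frac_high` (fraction of defined pairs with r2 at or above the
#'   threshold), `mean_r2`.
#' @method glance ld_scan
#' @export
glance.ld_scan <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_defined = sum(!is.na(x$r2)),
    r2_threshold = attr(x, "r2_threshold"),
    frac_high = attr(x, "frac_high"),
    mean_r2 = mean(x$r2, na.rm = TRUE)
  )
}

#' Square r2 matrix from a pairwise LD scan
#'
#' @param x An `ld_scan` tibble.
#' @return Symmetric numeric matrix of r2 values (1 on the diagonal),
#'   with `chrom:pos` dimnames.
#' @export
r2_matrix <- function(x) {
  ids <- unique(c(paste0(x$chrom_i, ":", x$pos_i),
                  paste0(x$chrom_j, ":", x$pos_j)))
  mat <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
  diag(mat) <- 1
  ii <- match(paste0(x$chrom_i, ":", x$pos_i), ids)
  jj <- match(paste0(x$chrom_j, ":", x$pos_j), ids)
  mat[cbind(ii, jj)] <- x$r2
  mat[cbind(jj, ii)] <- x$r2
  mat
}

#' Plot a pairwise r2 heatmap
#'
#' @param x An `ld_scan` tibble from [ld_matrix()].
#' @return A ggplot heatmap of pairwise r2.
#' @export
plot_ld_heatmap <- function(x) {
  d <- mutate(as_tibble(x),
              locus_i = paste0(.data$chrom_i, ":", .data$pos_i),
              locus_j = paste0(.data$chrom_j, ":", .data$pos_j))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus_i, y = .data$locus_j,
                                  fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
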
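#' Construct a two-population genotype matrix
#'
#' The central container for all downstream statistics: a samples-by-variants
#' matrix of biallelic genotype codes together with per-variant metadata and
#' per-sample group labels. Genotype codes count copies of the alternate
#' allele: `0` = ref/ref, `1` = heterozygous, `2` = alt/alt, `NA` = missing.
#'
#' Variants are stored sorted by `(chrom, pos)`; the constructor reorders the
#' call columns to match, so callers may pass variants in any order.
#'
#' @param calls Integer matrix, samples in rows and variants in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param variants Data frame with one row per variant. Required columns:
#'   `chrom`, `pos` (1-based bp), `ref`, `alt`. Optional columns `qual`
#'   (Phred site quality), `site_depth` (mean per-sample depth) and
#'   `missing_rate` are filled with `NA`/recomputed when absent.
#' @param samples Data frame with columns `sample_id` and `group`, one row
#'   per row of `calls`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `variants` (tibble) and `samples` (tibble).
#' @examples
#' gm <- geno_matrix(
#'   calls = rbind(a = c(0L, 2L), b = c(1L, 2L)),
#'   variants = data.frame(chrom = "10", pos = c(100, 200),
#'                         ref = "T", alt = "A"),
#'   samples = data.frame(sample_id = c("a", "b"),
#'                        group = c("black", "yellow"))
#' )
#' n_variants(gm)
#' @export
geno_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)

  for (col in c("chrom", "pos", "ref", "alt")) {
    if (!col %in% names(variants)) {
      abort(paste0("`variants` is missing required column `", col, "`"))
    }
  }
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` must have columns `sample_id` and `group`")
  }
  if (nrow(samples) != nrow(calls)) {
    abort("`calls` must have one row per sample")
  }
  if (nrow(variants) != ncol(calls)) {
    abort("`calls` must have one column per variant")
  }
  if (any(!is.na(calls) & !(calls %in% 0:2))) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  if (any(is.na(samples$group))) {
    abort("every sample must carry a group label")
  }
  if (any(variants$pos < 1)) {
    abort("variant positions are 1-based and must be >= 1")
  }
  bad <- !nzchar(variants$ref) | !nzchar(variants$alt) |
    variants$ref == variants$alt
  if (any(bad)) {
    abort("ref and alt alleles must be non-empty and distinct")
  }

  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  for (col in c("qual", "site_depth")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples$sample_id, NULL)
  variants$missing_rate <- unname(colMeans(is.na(calls)))
  for (col in c("qual", "site_depth")) {
    variants[[col]] <- unname(variants[[col]])
  }

  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @rdname geno_matrix
#' @param m A `geno_matrix`.
#' @export
n_samples <- function(m) nrow(m$calls)

#' @rdname geno_matrix
#' @export
n_variants <- function(m) ncol(m$calls)

#' @rdname geno_matrix
#' @export
group_levels <- function(m) unique(m$samples$group)

#' @export
print.geno_matrix <- function(x, ...) {
  grp <- table(x$samples$group)
  cat("<geno_matrix> ", n_samples(x), " samples x ", n_variants(x),
      " biallelic SNPs\n", sep = "")
  cat("  groups: ",
      paste0(names(grp), " (n=", as.integer(grp), ")", collapse = ", "),
      "\n", sep = "")
  chroms <- unique(x$variants$chrom)
  cat("  chromosomes: ", paste(head(chroms, 5), collapse = ", "),
      if (length(chroms) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' `m[i, j]` subsets samples (`i`) and variants (`j`) simultaneously,
#' keeping calls, variant metadata and sample labels in register.
#' `missing_rate` is recomputed for the retained samples.
#'
#' @param x A `geno_matrix`.
#' @param i Sample index (integer, logical or sample id character vector).
#' @param j Variant index (integer or logical).
#' @param ... Unused.
#' @return A `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  geno_matrix(
    calls = x$calls[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE]
  )
}

#' Long-format view of genotype calls
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per sample-variant pair: `sample_id`,
#'   `group`, `chrom`, `pos`, `ref`, `alt`, `genotype`.
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  nv <- n_variants(x)
  ns <- n_samples(x)
  tibble(
    sample_id = rep(x$samples$sample_id, times = nv),
    group = rep(x$samples$group, times = nv),
    chrom = rep(x$variants$chrom, each = ns),
    pos = rep(x$variants$pos, each = ns),
    ref = rep(x$variants$ref, each = ns),
    alt = rep(x$variants$alt, each = ns),
    genotype = as.integer(x$calls)
  )
}

# Per-variant allele/genotype tallies for one group of samples.
# Returns alt allele count, called allele total, and heterozygote count.
group_site_tallies <- function(m, group) {
  rows <- m$samples$group == group
  g <- m$calls[rows, , drop = FALSE]
  list(
    alt = colSums(g, na.rm = TRUE),
    called = 2L * colSums(!is.na(g)),
    het = colSums(g == 1L, na.rm = TRUE)
  )
}

# Require exactly two groups; returns their labels with the numerator first
# when `numerator` is given.
two_groups <- function(m, numerator = NULL) {
  grps <- group_levels(m)
  if (length(grps) != 2) {
    abort(paste0("exactly 2 groups are required, found ", length(grps), ": ",
                 paste(grps, collapse = ", ")))
  }
  if (is.null(numerator)) return(grps)
  if (!numerator %in% grps) {
    abort(paste0("`numerator` group '", numerator, "' not present"))
  }
  c(numerator, setdiff(grps, numerator))
}
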
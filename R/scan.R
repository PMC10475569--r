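#' Run the full sweep-selection scan
#'
#' Convenience wrapper chaining [windowed_stats()], [tail_thresholds()],
#' [select_windows()] and [merge_and_annotate()] into a single fitted-scan
#' object with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param m A [geno_matrix()] with exactly two groups.
#' @param genes Optional gene intervals tibble for region annotation.
#' @param size,step Window size and step in bp.
#' @param q Tail fraction for both the F_ST and pi-ratio tails.
#' @param numerator Numerator group for the log2 pi ratio.
#' @param estimator F_ST estimator, `"wc"` or `"hudson"`.
#' @return Object of class `sweep_scan`: list with `windows`, `thresholds`,
#'   `selected`, `regions` and `params`.
#' @examples
#' m <- simulate_two_pop(sim_config(n_snps = 500, seed = 7))
#' sc <- scan_selection(m, numerator = "black")
#' glance(sc)
#' @export
scan_selection <- function(m, genes = NULL, size = 10000, step = 5000,
                           q = 0.05, numerator = NULL,
                           estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  windows <- windowed_stats(m, size = size, step = step,
                            numerator = numerator, estimator = estimator)
  thresholds <- tail_thresholds(windows, q = q)
  selected <- select_windows(windows, thresholds)
  regions <- merge_and_annotate(selected, genes)
  structure(
    list(windows = windows, thresholds = thresholds, selected = selected,
         regions = regions,
         params = list(size = size, step = step, q = q,
                       numerator = attr(windows, "numerator"),
                       denominator = attr(windows, "denominator"),
                       estimator = estimator)),
    class = "sweep_scan"
  )
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("<sweep_scan> ", nrow(x$windows), " windows (",
      x$params$size, " bp / ", x$params$step, " bp step), ",
      nrow(x$selected), " selected, ", nrow(x$regions),
      " merged regions\n", sep = "")
  cat(sprintf("  cuts: fst >= %.4g, log2 ratio <= %.4g or >= %.4g (q = %g)\n",
              x$thresholds$fst_cut, x$thresholds$ratio_low_cut,
              x$thresholds$ratio_high_cut, x$thresholds$q))
  cat("  pi ratio numerator: ", x$params$numerator, " / ",
      x$params$denominator, "\n", sep = "")
  invisible(x)
}

#' Tidy a sweep scan into its per-window table
#'
#' @param x A `sweep_scan`.
#' @param ... Unused.
#' @return The window tibble with a logical `selected` column appended.
#' @method tidy sweep_scan
#' @export
tidy.sweep_scan <- function(x, ...) {
  w <- x$windows
  key <- paste(w$chrom, w$start)
  w$selected <- key %in% paste(x$selected$chrom, x$selected$start)
  w
}

#' One-row summary of a sweep scan
#'
#' @param x A `sweep_scan`.
#' @param ... Unused.
#' @return One-row tibble: window/selection counts, thresholds, gene count.
#' @method glance sweep_scan
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_defined = sum(!is.na(x$windows$fst) & !x$windows$partial),
    n_selected = nrow(x$selected),
    n_regions = nrow(x$regions),
    n_genes = length(unique(unlist(x$regions$genes))),
    fst_cut = x$thresholds$fst_cut,
    ratio_low_cut = x$thresholds$ratio_low_cut,
    ratio_high_cut = x$thresholds$ratio_high_cut,
    q = x$thresholds$q
  )
}

#' Plot a sweep scan
#'
#' F_ST along the genome with the tail threshold and the selected windows
#' highlighted; one facet per chromosome.
#'
#' @param object A `sweep_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_scan
#' @export
autoplot.sweep_scan <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$fst), , drop = FALSE]
  d$mid <- (d$start + d$end) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid / 1e6, y = .data$fst)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 0.8) +
    ggplot2::geom_hline(yintercept = object$thresholds$fst_cut,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST]),
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Plot a per-gene F_ST profile
#'
#' @param profile Output of [gene_fst_profile()].
#' @return A ggplot of window F_ST across the gene span.
#' @export
plot_gene_profile <- function(profile) {
  d <- profile[!is.na(profile$fst), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = .data$fst)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST]),
                  title = unique(profile$gene)) +
    ggplot2::theme_minimal()
}

#' Plot genotype PCA coordinates
#'
#' @param coords Output of [pca_components()] with at least two components.
#' @return A ggplot of PC1 vs PC2 coloured by group.
#' @export
plot_pca <- function(coords) {
  stopifnot(all(c("PC1", "PC2") %in% names(coords)))
  ggplot2::ggplot(coords, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                       colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "group") +
    ggplot2::theme_minimal()
}
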
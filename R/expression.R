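#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample relative expression from qPCR cycle-threshold (Ct)
#' values: technical replicates are averaged on the Ct scale, then
#' `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt - mean(dCt of the calibrator group)`, and
#' `fold = 2^(-ddCt)`. By construction the calibrator group's mean dCt maps
#' to fold 1. Samples lacking a target or reference Ct are dropped with a
#' warning. Fold changes are invariant to any constant added to all target
#' and reference Cts of a sample (e.g. a plate offset).
#'
#' @param records Tibble of Ct measurements with columns `sample_id`,
#'   `group`, `target_ct`, `reference_ct` (one row per technical
#'   replicate; an optional `replicate` column is ignored).
#' @param calibrator_group Group label used as the ddCt reference; must be
#'   non-empty.
#' @return Tibble, one row per sample: `sample_id`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
delta_delta_ct <- function(records, calibrator_group) {
  records <- as_tibble(records)
  need <- c("sample_id", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(records))) {
    abort(paste0("`records` needs columns: ", paste(need, collapse = ", ")))
  }
  per_sample <- records |>
    group_by(.data$sample_id, .data$group) |>
    summarise(target_ct = mean(.data$target_ct, na.rm = TRUE),
              reference_ct = mean(.data$reference_ct, na.rm = TRUE),
              .groups = "drop")
  bad <- !is.finite(per_sample$target_ct) | !is.finite(per_sample$reference_ct)
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " sample(s) with missing Ct: ",
                paste(per_sample$sample_id[bad], collapse = ", ")))
    per_sample <- per_sample[!bad, , drop = FALSE]
  }
  if (!calibrator_group %in% per_sample$group) {
    abort(paste0("calibrator group '", calibrator_group, "' is empty"))
  }
  per_sample <- mutate(per_sample,
                       delta_ct = .data$target_ct - .data$reference_ct)
  cal_mean <- mean(per_sample$delta_ct[per_sample$group == calibrator_group])
  per_sample |>
    mutate(delta_delta_ct = .data$delta_ct - cal_mean,
           fold = 2^(-.data$delta_delta_ct)) |>
    select("sample_id", "group", "delta_ct", "delta_delta_ct", "fold")
}

#' Test group differences in expression
#'
#' One-way ANOVA on the dCt values (the approximately normal, log2-linear
#' scale; folds themselves are log-normal). With exactly two groups this
#' reduces to the pooled-variance t test: `F = t^2`.
#'
#' @param folds Output of [delta_delta_ct()] (needs `group` and
#'   `delta_ct`), with >= 2 groups of >= 2 samples each.
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `method`. If every group has zero within-group variance
#'   the p-value is `NA` (flagged in `method`).
#' @export
group_test <- function(folds) {
  folds <- as_tibble(folds)
  stopifnot(all(c("group", "delta_ct") %in% names(folds)))
  tab <- table(folds$group)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 groups with >= 2 samples each")
  }
  within_var <- tapply(folds$delta_ct, folds$group, stats::var)
  if (all(within_var == 0)) {
    return(tibble(statistic = NA_real_,
                  df_between = length(tab) - 1L,
                  df_within = nrow(folds) - length(tab),
                  p_value = NA_real_,
                  method = "one-way ANOVA on dCt (zero within-group variance)"))
  }
  fit <- aov(delta_ct ~ group, data = folds)
  an <- anova(fit)
  tibble(
    statistic = an$`F value`[1],
    df_between = an$Df[1],
    df_within = an$Df[2],
    p_value = an$`Pr(>F)`[1],
    method = "one-way ANOVA on dCt"
  )
}

#' Per-group expression summary
#'
#' Geometric-mean fold change per group (the natural summary on the fold
#' scale, equal to `2^(-mean ddCt)`), with sample counts.
#'
#' @param folds Output of [delta_delta_ct()].
#' @return Tibble: `group`, `n`, `geo_mean_fold`, `mean_delta_ct`.
#' @export
expression_summary <- function(folds) {
  folds |>
    group_by(.data$group) |>
    summarise(n = n(),
              geo_mean_fold = 2^(-mean(.data$delta_delta_ct)),
              mean_delta_ct = mean(.data$delta_ct),
              .groups = "drop")
}

#' Reshape long qPCR Ct data to target/reference records
#'
#' Converts the long export format (`sample`, `group`, `gene`, `ct`, one
#' row per well) into the paired-record format of [delta_delta_ct()].
#'
#' @param df Long tibble with columns `sample_id` (or `sample`), `group`,
#'   `gene`, `ct`.
#' @param target_gene,reference_gene Gene names of the target and the
#'   reference (housekeeping) assay.
#' @return Tibble with `sample_id`, `group`, `target_ct`, `reference_ct`.
#' @export
ct_records_from_long <- function(df, target_gene, reference_gene) {
  df <- as_tibble(df)
  if ("sample" %in% names(df) && !"sample_id" %in% names(df)) {
    df <- rename(df, sample_id = "sample")
  }
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(df)))
  tgt <- df |> filter(.data$gene == target_gene) |>
    group_by(.data$sample_id, .data$group) |>
    summarise(target_ct = mean(.data$ct), .groups = "drop")
  ref <- df |> filter(.data$gene == reference_gene) |>
    group_by(.data$sample_id, .data$group) |>
    summarise(reference_ct = mean(.data$ct), .groups = "drop")
  dplyr::full_join(tgt, ref, by = c("sample_id", "group"))
}
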
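#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}), keeps biallelic SNPs only
#' (multi-allelic records and indels are dropped), decodes the `GT` field
#' into alternate-allele dosage codes, and attaches group labels. Phased
#' (`|`) and unphased (`/`) separators are both accepted; any genotype
#' containing `.` becomes missing.
#'
#' Per-variant mean depth (`site_depth`) is taken, in order of preference,
#' from the mean of per-sample `FORMAT/DP` over called samples, a custom
#' `INFO/MDP` field (written by [write_vcf()]), or `INFO/DP` divided by the
#' number of called samples.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param groups Sample-to-group assignment: a data frame with columns
#'   `sample_id` and `group`, or a named character vector
#'   (`c(sample = "group")`). VCF samples absent from the map are dropped
#'   with a warning.
#' @return A [geno_matrix()].
#' @seealso [write_vcf()], [filter_variants()], [read_group_map()]
#' @export
read_vcf <- function(path, groups) {
  if (!file.exists(path)) {
    abort(paste0("cannot read VCF: file not found: ", path))
  }
  groups <- as_group_map(groups)

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    abort("no variant records in VCF")
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!any(snp)) {
    abort("no biallelic SNPs after parsing")
  }

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  vcf_samples <- colnames(gt_raw)
  keep <- vcf_samples %in% groups$sample_id
  if (!all(keep)) {
    warn(paste0(sum(!keep), " VCF sample(s) absent from the group map were ",
                "dropped: ", paste(vcf_samples[!keep], collapse = ", ")))
  }
  if (!any(keep)) {
    abort("no VCF sample carries a group label")
  }
  gt_raw <- gt_raw[, keep, drop = FALSE]
  vcf_samples <- vcf_samples[keep]

  codes <- decode_gt(gt_raw) # variants x samples

  # site depth: FORMAT/DP preferred, then INFO/MDP, then INFO/DP per sample
  n_called <- rowSums(!is.na(codes))
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  site_depth <- rep(NA_real_, nrow(fix))
  if (!is.null(dp) && !all(is.na(dp))) {
    dp <- dp[snp, keep, drop = FALSE]
    site_depth <- rowMeans(dp, na.rm = TRUE)
    site_depth[is.nan(site_depth)] <- NA_real_
  }
  if (all(is.na(site_depth))) {
    info <- fix[, "INFO"]
    mdp <- info_field(info, "MDP")
    if (any(!is.na(mdp))) {
      site_depth <- mdp
    } else {
      tot <- info_field(info, "DP")
      site_depth <- ifelse(n_called > 0, tot / n_called, NA_real_)
    }
  }

  geno_matrix(
    calls = t(codes),
    variants = tibble(
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = ref[snp],
      alt = alt[snp],
      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
      site_depth = site_depth
    ),
    samples = tibble(
      sample_id = vcf_samples,
      group = groups$group[match(vcf_samples, groups$sample_id)]
    )
  )
}

# "0/1", "0|1", "./." ... -> alt dosage 0/1/2 or NA. Matrix in, matrix out.
decode_gt <- function(gt) {
  x <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow = nrow(x), ncol = ncol(x))
  out[x %in% c("0/0")] <- 0L
  out[x %in% c("0/1", "1/0")] <- 1L
  out[x %in% c("1/1")] <- 2L
  dimnames(out) <- dimnames(x)
  out
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_real_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- suppressWarnings(as.numeric(sub(pat, "\\1",
    regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)))
  out
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits an uncompressed VCF v4.2 with `GT`-only sample columns. Missing
#' genotypes are written `./.`. Site quality is written to `QUAL` and mean
#' per-sample depth to the declared `INFO/MDP` field (plus an integer
#' `INFO/DP` total), so `read_vcf(write_vcf(m))` reproduces positions,
#' alleles, calls, quality and depth.
#'
#' @param m A non-empty [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  stopifnot(inherits(m, "geno_matrix"))
  if (n_variants(m) == 0 || n_samples(m) == 0) {
    abort("refusing to write an empty genotype matrix")
  }
  v <- m$variants
  gt <- t(m$calls) # variants x samples
  gt_str <- matrix("./.", nrow = nrow(gt), ncol = ncol(gt))
  gt_str[gt == 0L] <- "0/0"
  gt_str[gt == 1L] <- "0/1"
  gt_str[gt == 2L] <- "1/1"

  n_called <- rowSums(!is.na(gt))
  info <- ifelse(
    is.na(v$site_depth), ".",
    paste0("DP=", round(v$site_depth * n_called), ";MDP=",
           formatC(v$site_depth, format = "g", digits = 15))
  )
  qual <- ifelse(is.na(v$qual), ".",
                 formatC(v$qual, format = "g", digits = 15))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=beakscan",
    paste0("##INFO=<ID=DP,Number=1,Type=Integer,Description=",
           "\"Approximate total read depth\">"),
    paste0("##INFO=<ID=MDP,Number=1,Type=Float,Description=",
           "\"Mean per-sample read depth\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples$sample_id), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", info, "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open for writing: ", path))
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Apply site-level variant filters
#'
#' Retains variants passing all of: `qual > qual_min`,
#' `dp_low < site_depth < dp_high`, and `missing_rate < miss_max` (all
#' strict inequalities). The defaults reproduce a standard resequencing
#' filter set: QUAL > 30, mean depth strictly between 5x and 18x, missing
#' (deletion) rate below 0.1. A variant whose quality or depth annotation
#' is absent (`NA`) passes that criterion. Order is preserved and retained
#' records are unaltered, so the filter is idempotent.
#'
#' @param m A [geno_matrix()].
#' @param qual_min,dp_low,dp_high,miss_max Numeric thresholds.
#' @return A `geno_matrix` containing the retained variants (possibly none).
#' @export
filter_variants <- function(m, qual_min = 30, dp_low = 5, dp_high = 18,
                            miss_max = 0.1) {
  stopifnot(inherits(m, "geno_matrix"),
            is.finite(qual_min), is.finite(dp_low), is.finite(dp_high),
            is.finite(miss_max))
  if (dp_low >= dp_high) abort("`dp_low` must be below `dp_high`")
  v <- m$variants
  pass_na <- function(ok) ifelse(is.na(ok), TRUE, ok)
  keep <- pass_na(v$qual > qual_min) &
    pass_na(v$site_depth > dp_low & v$site_depth < dp_high) &
    v$missing_rate < miss_max
  out <- m
  out$variants <- v[keep, , drop = FALSE]
  out$calls <- m$calls[, keep, drop = FALSE]
  out
}

#' Read gene intervals from BED or 1-based TSV
#'
#' BED input (0-based, half-open) is converted to the package-wide 1-based
#' inclusive convention; a TSV with columns `chrom`, `start`, `end`, `name`
#' is taken as already 1-based inclusive. Intervals are sorted by
#' `(chrom, start)`; overlapping intervals are preserved, never merged.
#'
#' @param path Path to the interval file.
#' @param format `"auto"` (by file extension: `.bed` means BED), `"bed"`,
#'   or `"tsv"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`
#'   (1-based inclusive); zero rows for an empty file.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t| +")
  if (any(lengths(fields) < 3)) {
    abort("interval lines must have at least 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.integer(vapply(fields, `[[`, "", 2))
  end <- as.integer(vapply(fields, `[[`, "", 3))
  name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (format == "bed") start <- start + 1L
  if (any(is.na(start) | is.na(end))) abort("non-numeric interval bounds")
  if (any(start > end)) {
    abort("interval with start > end after coordinate conversion")
  }
  tibble(chrom = chrom, start = start, end = end, name = name) |>
    arrange(.data$chrom, .data$start)
}

#' Write intervals as BED
#'
#' Converts 1-based inclusive intervals back to BED's 0-based half-open
#' convention. Any additional `name`-like column given by `name_col` is
#' written as the fourth field.
#'
#' @param x Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @param name_col Optional column to use as the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_col = "name") {
  nm <- if (name_col %in% names(x)) {
    vapply(x[[name_col]], function(v) paste(unlist(v), collapse = ","), "")
  } else rep(".", nrow(x))
  nm[!nzchar(nm) | is.na(nm)] <- "."
  writeLines(paste(x$chrom, x$start - 1L, x$end, nm, sep = "\t"), path)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' Two-column TSV (`sample_id`, `group`); a header row with those names is
#' detected and skipped.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `sample_id` and `group`.
#' @export
read_group_map <- function(path) {
  df <- readr::read_tsv(path, col_names = c("sample_id", "group"),
                        col_types = "cc", progress = FALSE)
  if (nrow(df) > 0 && identical(tolower(df$sample_id[1]), "sample_id")) {
    df <- df[-1, , drop = FALSE]
  }
  df
}

#' Write a sample-to-group map
#' @param samples Tibble with `sample_id` and `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(samples, path) {
  writeLines(paste(samples$sample_id, samples$group, sep = "\t"), path)
  invisible(path)
}

as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    return(as_tibble(groups[c("sample_id", "group")]))
  }
  if (!is.null(names(groups))) {
    return(tibble(sample_id = names(groups), group = unname(groups)))
  }
  abort("`groups` must be a data frame (sample_id, group) or a named vector")
}
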
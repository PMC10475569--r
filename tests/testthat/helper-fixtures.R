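# Small in-code fixtures shared across test files.

# A window of SNPs fixed ref in group 1 and fixed alt in group 2.
fixed_diff_matrix <- function(n1 = 20, n2 = 40, n_snps = 20,
                              pos = seq(500, by = 500,
                                        length.out = n_snps)) {
  geno_matrix(
    calls = rbind(matrix(0L, n1, n_snps), matrix(2L, n2, n_snps)),
    variants = tibble::tibble(chrom = "10", pos = pos, ref = "T", alt = "A"),
    samples = tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n1 + n2)),
      group = rep(c("black", "yellow"), c(n1, n2))
    )
  )
}

# Tiny hand-written VCF with the quirks read_vcf() must handle.
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "10\t100\t.\tT\tA\t50\tPASS\tDP=30\tGT:DP\t0/0:9\t0/1:11\t1/1:10",
    "10\t200\t.\tC\tA,T\t50\tPASS\tDP=30\tGT:DP\t0/0:10\t0/1:10\t1/1:10",
    "10\t300\t.\tG\tC\t50\tPASS\tDP=30\tGT:DP\t0|1:10\t./.:.\t1|1:10",
    "10\t400\t.\tGA\tG\t50\tPASS\tDP=30\tGT:DP\t0/0:10\t0/0:10\t0/0:10"
  )
  writeLines(lines, path)
  path
}

test_groups <- tibble::tibble(
  sample_id = c("s1", "s2", "s3"),
  group = c("black", "black", "yellow")
)
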
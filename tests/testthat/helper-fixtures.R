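# Small in-code fixtures shared across test files.

# random frequency quartets for property tests
random_freqs <- function(n, haploid = FALSE, seed = 1) {
  set.seed(seed)
  m <- if (haploid) {
    matrix(sample(0:1, 4 * n, replace = TRUE), ncol = 4)
  } else {
    matrix(stats::runif(4 * n), ncol = 4)
  }
  colnames(m) <- c("p1", "p2", "p3", "p4")
  m
}

# Write a quartet VCF by hand from 0/1 haplotype matrices (one haploid sample
# per column). REF is the ancestral allele so truth is known independently of
# the polarization code under test.
write_quartet_vcf <- function(geno, pos, path, pop_map_path,
                              pops = sub("_.*", "", colnames(geno)),
                              chrom = "chrT", aa = TRUE) {
  samples <- colnames(geno)
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- if (aa) "AA=A" else "."
  rows <- paste(chrom, pos, ".", "A", "T", ".", "PASS", info, "GT",
                apply(geno, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path)
  writeLines(paste(samples, pops, sep = "\t"), pop_map_path)
  invisible(path)
}

# cluster (replicate-level) bootstrap standard error of a pooled
# confusion-matrix metric
boot_se_metric <- function(per_rep_counts, metric, n_boot = 200, seed = 99) {
  set.seed(seed)
  reps <- nrow(per_rep_counts)
  ests <- replicate(n_boot, {
    idx <- sample.int(reps, replace = TRUE)
    cc <- colSums(per_rep_counts[idx, , drop = FALSE])
    metric(cc)
  })
  stats::sd(ests, na.rm = TRUE)
}
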
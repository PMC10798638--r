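test_that("polarize_sites applies the outgroup-fixed-else-major rule", {
  # one site per scenario, counts are (P1, P2, P3, P4)
  alt <- rbind(c(1, 2, 0, 0),   # outgroup fixed REF -> derived = ALT
               c(1, 2, 0, 4),   # outgroup fixed ALT -> derived = REF
               c(3, 4, 4, 1),   # outgroup polymorphic, ALT major -> anc = ALT
               c(1, 0, 0, 1),   # outgroup polymorphic, REF major -> anc = REF
               c(2, 2, 2, 2))   # exact tie -> skipped
  called <- rbind(c(4, 4, 4, 4), c(4, 4, 4, 4), c(4, 4, 4, 4),
                  c(2, 2, 2, 2), c(4, 4, 4, 4))
  pol <- polarize_sites(alt, called, "outgroup-fixed-else-major")
  expect_equal(pol$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(pol$skipped[["unpolarized"]]), 1L)
  expect_equal(unname(pol$freq[1, ]), c(0.25, 0.5, 0, 0))
  expect_equal(unname(pol$freq[2, ]), c(0.75, 0.5, 1, 0))  # polarity flipped
  expect_equal(unname(pol$freq[3, ]), c(0.25, 0, 0, 0.75)) # ALT ancestral
  expect_equal(unname(pol$freq[4, ]), c(0.5, 0, 0, 0.5))
})

test_that("polarize_sites annotation mode flips polarity and skips mismatches", {
  alt <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0), c(1, 1, 1, 0))
  called <- matrix(2, 3, 4)
  pol <- polarize_sites(alt, called, "annotation",
                        ref = c("A", "A", "A"), alt = c("T", "T", "T"),
                        ancestral = c("A", "T", "G"))
  expect_equal(pol$keep, c(TRUE, TRUE, FALSE))
  expect_equal(unname(pol$skipped[["annotation_mismatch"]]), 1L)
  expect_equal(unname(pol$freq[1, ]), c(0.5, 0.5, 0.5, 0))
  expect_equal(unname(pol$freq[2, ]), c(0.5, 0.5, 0.5, 1))  # ALT ancestral
  # a site with no calls in one population is always skipped
  called0 <- called; called0[1, 2] <- 0
  pol0 <- polarize_sites(alt, called0, "annotation",
                         ref = rep("A", 3), alt = rep("T", 3),
                         ancestral = rep("A", 3))
  expect_false(pol0$keep[1])
  expect_equal(unname(pol0$skipped[["uncalled"]]), 1L)
})

test_that("window_scan cuts 0-based half-open windows and drops partials", {
  set.seed(8)
  pos <- sort(runif(5000, 0, 20e6))
  freqs <- random_freqs(5000, haploid = TRUE, seed = 8)
  sc <- window_scan(pos, freqs, width = 50000L, chrom_length = 20e6)
  expect_equal(nrow(sc), 400L)
  expect_equal(sc$start[1], 0)
  expect_equal(sc$end[400], 20e6)
  # trailing partial window is dropped
  sc2 <- window_scan(pos, freqs, width = 50000L, chrom_length = 20e6 + 30e3)
  expect_equal(nrow(sc2), 400L)
  # empirical convention drops first and last windows
  sc3 <- window_scan(pos, freqs, width = 50000L, chrom_length = 20e6,
                     drop_edges = TRUE)
  expect_equal(nrow(sc3), 398L)
  expect_equal(sc3$start[1], 50000)
  expect_error(window_scan(rev(pos), freqs), "sorted")
})

test_that("windows without informative sites get undefined statistics", {
  # two windows: one ABBA site in the first, nothing informative in the second
  pos <- c(100, 1500)
  freqs <- rbind(c(0, 1, 1, 0), c(1, 1, 1, 0))  # second site is BBBA-like
  sc <- window_scan(pos, freqs, width = 1000L, chrom_length = 2000)
  expect_equal(sc$d[1], 1)
  expect_true(is.na(sc$d[2]))
  expect_true(is.na(sc$d_plus[2]))
  expect_equal(sc$n_informative[2], 0)
  # fd-hat is NA when D <= 0
  sc_neg <- window_scan(100, rbind(c(1, 0, 1, 0)), width = 1000L,
                        chrom_length = 1000)
  expect_equal(sc_neg$d[1], -1)
  expect_true(is.na(sc_neg$f_hat_d[1]))
})

test_that("a hand-built VCF scans identically to the in-memory path", {
  set.seed(21)
  n <- 400
  geno <- cbind(P1_1 = sample(0:1, n, TRUE), P2_1 = sample(0:1, n, TRUE),
                P2_2 = sample(0:1, n, TRUE), P3_1 = sample(0:1, n, TRUE),
                P4_1 = 0L, P4_2 = 0L)
  pos <- sort(sample(1:100000, n))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_quartet_vcf(geno, pos, vcf, pm)

  sites <- read_vcf_quartet(vcf, pm, ancestral = "outgroup")
  expect_s3_class(sites, "dplus_sites")
  expect_equal(sites$n_hap[["P2"]], 2L)
  # with the outgroup fixed ancestral, frequencies are plain means
  keep <- sites$pos
  expect_equal(sites$freq[, "p1"], geno[match(keep, pos), "P1_1"] + 0)
  expect_equal(sites$freq[, "p2"],
               rowMeans(geno[match(keep, pos), c("P2_1", "P2_2")]))

  sc_vcf <- scan_vcf(sites, width = 10000L, drop_edges = FALSE)
  sc_mem <- window_scan(sites$pos, sites$freq, width = 10000L,
                        chrom_length = max(sites$pos), n_hap_p2 = 2L)
  expect_equal(sc_vcf$d_plus, sc_mem$d_plus)
  expect_equal(sc_vcf$pi_p2, sc_mem$pi_p2)

  # annotation mode on the same file gives the same polarization (AA=REF)
  sites_aa <- read_vcf_quartet(vcf, pm, ancestral = "info:AA")
  expect_equal(sites_aa$freq[, "p2"], sites$freq[, "p2"])

  # unknown samples in the population map are an error
  writeLines(c("P1_1\tP1", "nosuch\tP2"), pm)
  expect_error(read_vcf_quartet(vcf, pm), "not in the VCF")
})

test_that("empirical thresholds interpolate and keep ties significant", {
  expect_equal(empirical_threshold(1:1000, 0.05), 975.025)
  expect_equal(sum(is_significant(1:1000, empirical_threshold(1:1000, 0.05))),
               25L)
  expect_equal(empirical_threshold(rep(0, 1000), 0.05), 0)
  expect_error(empirical_threshold(NA_real_, 0.05), "no defined values")
  expect_error(empirical_threshold(1:10, 1.5), "p must lie")
  # undefined values are never significant
  expect_equal(is_significant(c(NA, 0.3), 0.2), c(FALSE, TRUE))
})

test_that("significance is monotone in the nominal p-value", {
  set.seed(31)
  null <- rnorm(2000)
  obs <- rnorm(500)
  sig_prev <- rep(TRUE, length(obs))
  for (p in c(0.2, 0.1, 0.05, 0.01)) {
    sig <- is_significant(obs, empirical_threshold(null, p))
    expect_true(all(!sig | sig_prev))  # sig subset of previous (larger p)
    sig_prev <- sig
  }
})

test_that("max_over_haplotypes ignores undefined values", {
  expect_equal(max_over_haplotypes(0.2, 0.7), 0.7)
  expect_equal(max_over_haplotypes(NA_real_, 0.3), 0.3)
  expect_true(is.na(max_over_haplotypes(NA_real_, NA_real_)))
  expect_equal(max_over_haplotypes(c(0.1, NA), c(-0.5, 0.2)), c(0.1, 0.2))
})

test_that("random haplotype collapse is seeded and unbiased", {
  n <- 10000
  a1 <- matrix(0L, n, 2); a2 <- matrix(1L, n, 2)
  hom1 <- random_haplotype_collapse(a1, a1, seed = 1)
  expect_true(all(hom1 == 0L))
  x <- random_haplotype_collapse(a1, a2, seed = 5)
  y <- random_haplotype_collapse(a1, a2, seed = 5)
  expect_identical(x, y)
  # heterozygous sites pick each allele about half the time
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / (2 * n)))
})

test_that("scan output negates when P1 and P2 labels are swapped", {
  freqs <- random_freqs(1000, seed = 13)
  pos <- sort(runif(1000, 0, 1e5))
  a <- window_scan(pos, freqs, width = 20000L, chrom_length = 1e5)
  b <- window_scan(pos, freqs[, c(2, 1, 3, 4)], width = 20000L,
                   chrom_length = 1e5)
  expect_equal(b$d, -a$d)
  expect_equal(b$d_plus, -a$d_plus)
  expect_equal(b$d_ancestral, -a$d_ancestral)
})
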
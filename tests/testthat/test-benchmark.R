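test_that("single-haplotype truth labels follow the 10% overlap rule", {
  width <- 50000
  tr <- data.frame(left = c(10000, 260000), right = c(15000, 264000))
  lab <- label_windows_n1(tr, n_windows = 10, width = width)
  expect_equal(lab[1], "introgressed")      # 5 kb of 50 kb
  expect_equal(lab[6], "dropped")           # 4 kb of 50 kb
  expect_equal(lab[2], "not_introgressed")  # zero overlap
  expect_equal(label_windows_n1(tr[0, ], 10, width),
               rep("not_introgressed", 10))

  # tracts spanning a window boundary are split correctly
  tr2 <- data.frame(left = 45000, right = 60000)
  lab2 <- label_windows_n1(tr2, 2, width)
  expect_equal(lab2, c("introgressed", "introgressed")) # 5 kb + 10 kb

  # overlapping tract records are not double counted
  tr3 <- data.frame(left = c(0, 2000), right = c(4000, 5000))
  expect_equal(label_windows_n1(tr3, 1, width)[1], "introgressed")
})

test_that("raising the overlap fraction never adds introgressed windows", {
  set.seed(77)
  tr <- data.frame(left = sort(runif(30, 0, 5e5)))
  tr$right <- tr$left + runif(30, 100, 40000)
  prev <- label_windows_n1(tr, 10, 50000, overlap_fraction = 0.05)
  for (frac in c(0.10, 0.25, 0.5)) {
    cur <- label_windows_n1(tr, 10, 50000, overlap_fraction = frac)
    expect_true(all(which(cur == "introgressed") %in%
                      which(prev == "introgressed")))
    prev <- cur
  }
})

test_that("frequency-mode truth labels need both carrier and length conditions", {
  width <- 50000
  # 12 chromosomes; three tracts each carried by >= 2 chromosomes, summing to
  # 15 kb inside the window -> introgressed
  tr <- data.table::data.table(
    left = c(5000, 20000, 40000), right = c(10000, 26000, 44000),
    n_carriers = c(2L, 3L, 2L))
  expect_equal(label_windows_freq(tr, 1, width, n_chromosomes = 12)[1],
               "introgressed")
  # a single tract in 1 of 200 chromosomes fails the carrier condition
  tr2 <- data.table::data.table(left = 0, right = 50000, n_carriers = 1L)
  expect_equal(label_windows_freq(tr2, 1, width, n_chromosomes = 200)[1],
               "not_introgressed")
  # carriers can be given as a list column
  tr3 <- data.table::data.table(left = 0, right = 6000,
                                carriers = list(c(1L, 5L)))
  expect_equal(label_windows_freq(tr3, 1, width, n_chromosomes = 12)[1],
               "introgressed")
  expect_equal(label_windows_freq(tr[0, ], 1, width, n_chromosomes = 12)[1],
               "not_introgressed")
})

test_that("performance computes the confusion-matrix metrics", {
  calls <- c(rep(TRUE, 4), rep(FALSE, 96))
  truth <- c(rep("introgressed", 3), "not_introgressed",
             rep("introgressed", 9), rep("not_introgressed", 87))
  perf <- performance(calls, truth)
  expect_equal(perf$precision, 0.75)
  expect_equal(perf$recall, 0.25)
  expect_equal(perf$fpr, 1 / 88, tolerance = 1e-9)
  # precision = 1 - FDR by construction
  expect_equal(perf$precision, 1 - perf$fp / (perf$tp + perf$fp))

  none <- performance(rep(FALSE, 10), rep(c("introgressed",
                                            "not_introgressed"), 5))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  all_sig <- performance(rep(TRUE, 5), rep("introgressed", 5))
  expect_equal(all_sig$precision, 1)
  expect_equal(all_sig$recall, 1)
  expect_true(is.na(all_sig$fpr))

  expect_error(performance(TRUE, rep("introgressed", 2)), "same windows")
})

test_that("dropped windows are excluded from every confusion cell", {
  calls <- c(TRUE, TRUE, FALSE, FALSE)
  truth <- c("introgressed", "dropped", "dropped", "not_introgressed")
  perf <- performance(calls, truth)
  expect_equal(perf$tp + perf$fp + perf$fn + perf$tn, 2L)
  expect_equal(perf$precision, 1)
})

test_that("clock-violation construction shifts times and sampling ages", {
  base <- iua_benchmark_demography(0.03)
  cl2 <- clock_violation_demography(base, "P1", 2)
  gen <- event_times(cl2, "generations")
  expect_equal(unname(gen), c(1600 + 4000, 8000, 20000, 804000))
  expect_equal(cl2$sample_times, c(0, 4000, 5600, 0))
  # terminal branches: P1 spans 2 x T_P2, P2 spans T_P2
  expect_equal((gen[["t_p2"]] - cl2$sample_times[1]) /
                 (gen[["t_p2"]] - cl2$sample_times[2]), 2)

  cl10 <- clock_violation_demography(base, "P1", 10)
  gen10 <- event_times(cl10, "generations")
  expect_equal(cl10$sample_times[2], 9 * 4000)
  expect_equal((gen10[["t_p2"]] - cl10$sample_times[1]) /
                 (gen10[["t_p2"]] - cl10$sample_times[2]), 10)

  # mirrored construction elongates P2 instead
  m2 <- clock_violation_demography(base, "P2", 2)
  expect_equal(m2$sample_times[1], 4000)
  expect_equal(m2$sample_times[2], 0)

  expect_error(clock_violation_demography(base, "P1", 1), "factor")
})

test_that("error injection is seeded with the right marginal rate", {
  haps <- matrix(0L, 50000, 1)
  expect_identical(inject_errors(haps, 0, seed = 1), haps)
  a <- inject_errors(haps, 0.001, seed = 9)
  b <- inject_errors(haps, 0.001, seed = 9)
  expect_identical(a, b)
  flips <- sum(a != haps)
  expect_lt(abs(flips - 50), 4 * sqrt(50))  # binomial mean 50, sd ~7.1
})

test_that("the coalescent engine adapter is deterministic and tracks tracts", {
  sim <- small_sim()  # f = 0.5, 2 reps of 5 Mb, 2 P2 haplotypes
  sim2 <- simulate_iua_replicates(iua_benchmark_demography(0.5), 2L, 5e6,
                                  samples = c(P1 = 1, P2 = 2, P3 = 1, P4 = 1),
                                  seed = 2025L)
  expect_identical(sim$replicates[[1]]$pos, sim2$replicates[[1]]$pos)
  expect_identical(sim$replicates[[2]]$tracts, sim2$replicates[[2]]$tracts)

  # with f = 0.5 around half of each P2 haplotype traces to the donor
  tr <- sim$replicates[[1]]$tracts
  expect_true(all(tr$right > tr$left))
  for (h in 1:2) {
    frac <- sum(tr$right[tr$hap == h] - tr$left[tr$hap == h]) / 5e6
    expect_gt(frac, 0.15)
    expect_lt(frac, 0.85)
  }

  # no admixture, no tracts
  sim0 <- simulate_iua_replicates(iua_benchmark_demography(0), 1L, 1e6,
                                  seed = 7L)
  expect_equal(nrow(sim0$replicates[[1]]$tracts), 0L)
})

test_that("simulated VCF export scans identically to the in-memory path", {
  sim <- small_sim()
  rep1 <- sim$replicates[[1]]
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_sim_vcf(rep1, vcf, pm)
  # restrict to one haplotype per population so the comparison below is exact
  writeLines(c("P1_1\tP1", "P2_1\tP2", "P3_1\tP3", "P4_1\tP4"), pm)
  sc_vcf <- scan_vcf(vcf, pm, ancestral = "info:AA", width = 500000L,
                     drop_edges = FALSE)
  # direct computation on the same sites the VCF holds (integer positions,
  # collided duplicates dropped)
  pos_int <- floor(rep1$pos) + 1
  keep <- !duplicated(pos_int)
  geno <- rep1$geno[keep, ]
  freq <- cbind(geno[, "P1_1"], geno[, "P2_1"], geno[, "P3_1"],
                geno[, "P4_1"])
  mem <- window_scan(pos_int[keep], freq, width = 500000L,
                     chrom_length = max(pos_int[keep]))
  expect_equal(nrow(sc_vcf), nrow(mem))
  expect_equal(sc_vcf$d_plus, mem$d_plus, tolerance = 1e-12)
  expect_equal(sc_vcf$abba, mem$abba)
  expect_equal(sc_vcf$d, mem$d)
})
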
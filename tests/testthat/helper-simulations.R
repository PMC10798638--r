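# Memoised simulation cohorts shared between the benchmark and acceptance
# tests, so each heavy msprime run happens at most once per test session.
# Scales follow the package's benchmark defaults: 30 replicates of 20 Mb.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

BENCH_REPS <- 30L
BENCH_LEN <- 20e6
BENCH_WIDTH <- 50000L

bench_null <- function() cached("null", {
  null_distribution(iua_benchmark_demography(f = 0), BENCH_REPS,
                    length = BENCH_LEN, width = BENCH_WIDTH, seed = 104729L)
})

bench_admix <- function() cached("admix", {
  sim <- simulate_iua_replicates(iua_benchmark_demography(0.03), BENCH_REPS,
                                 BENCH_LEN, seed = 104730L)
  windows <- scan_sim_windows(sim, BENCH_WIDTH)
  truth <- truth_labels_sim(sim, BENCH_WIDTH)
  list(sim = sim, windows = windows, truth = truth)
})

bench_max2 <- function() cached("max2", {
  run_max2_benchmark(iua_benchmark_demography(0.03), BENCH_REPS,
                     length = BENCH_LEN, width = BENCH_WIDTH, seed = 104731L,
                     stats = "d_plus")
})

bench_clock <- function(population) cached(paste0("clock_", population), {
  demog <- clock_violation_demography(iua_benchmark_demography(0.03),
                                      population, 2)
  run_benchmark(demog, BENCH_REPS, length = BENCH_LEN, width = BENCH_WIDTH,
                seed = if (population == "P1") 104732L else 104733L,
                stats = "d_plus", p_grid = 0.05)
})

# tiny cohort for fast unit tests of the simulation plumbing
small_sim <- function() cached("small", {
  simulate_iua_replicates(iua_benchmark_demography(0.5), 2L, 5e6,
                          samples = c(P1 = 1, P2 = 2, P3 = 1, P4 = 1),
                          seed = 2025L)
})

# per-replicate confusion counts for cluster-bootstrap standard errors
per_rep_confusion <- function(windows, truth, stat, threshold) {
  merged <- merge(windows, truth, by = c("rep_id", "win"))
  merged <- merged[!is.na(merged[[stat]]) & merged$label != "dropped"]
  sig <- is_significant(merged[[stat]], threshold)
  pos <- merged$label == "introgressed"
  agg <- merged[, .(tp = sum(sig[.I] & pos[.I]), fp = sum(sig[.I] & !pos[.I]),
                    fn = sum(!sig[.I] & pos[.I]), tn = sum(!sig[.I] & !pos[.I])),
                by = rep_id]
  as.matrix(agg[, c("tp", "fp", "fn", "tn")])
}
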
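#' Truth labels for windows from introgressed tracts (single haplotype)
#'
#' A window is `introgressed` when at least `overlap_fraction` of its bases
#' overlap introgressed tracts of the sampled P2 haplotype (5 kb of a 50 kb
#' window at the default 10%); windows with some overlap below that fraction
#' are `dropped` (excluded from all performance denominators); windows with no
#' overlap are `not_introgressed`.
#'
#' @param tracts A data.frame/data.table with `left`, `right` (bp, half-open).
#' @param n_windows Number of windows.
#' @param width Window width in bp.
#' @param overlap_fraction Minimum introgressed fraction (default 0.10).
#' @return Character vector of labels, one per window.
#' @export
label_windows_n1 <- function(tracts, n_windows, width, overlap_fraction = 0.10) {
  ov <- window_tract_overlap(tracts, n_windows, width)
  ifelse(ov >= overlap_fraction * width, "introgressed",
         ifelse(ov > 0, "dropped", "not_introgressed"))
}

# total introgressed bases per window from a set of (left, right) intervals
window_tract_overlap <- function(tracts, n_windows, width) {
  ov <- numeric(n_windows)
  if (is.null(tracts) || nrow(tracts) == 0L) return(ov)
  # merge intervals first so overlapping tracts are not double counted
  o <- order(tracts$left)
  lefts <- tracts$left[o]; rights <- tracts$right[o]
  ml <- mr <- numeric(0)
  for (i in seq_along(lefts)) {
    if (length(ml) && lefts[i] <= mr[length(mr)]) {
      mr[length(mr)] <- max(mr[length(mr)], rights[i])
    } else {
      ml <- c(ml, lefts[i]); mr <- c(mr, rights[i])
    }
  }
  for (i in seq_along(ml)) {
    w0 <- max(1L, floor(ml[i] / width) + 1L)
    w1 <- min(n_windows, floor((mr[i] - 1e-9) / width) + 1L)
    if (w1 < w0) next
    for (w in w0:w1) {
      lo <- max(ml[i], (w - 1) * width)
      hi <- min(mr[i], w * width)
      ov[w] <- ov[w] + max(0, hi - lo)
    }
  }
  ov
}

#' Truth labels for windows when many P2 chromosomes are sampled
#'
#' A window is `introgressed` when (1) it contains at least one tract carried
#' by at least `carrier_fraction` of the `n_chromosomes` sampled P2
#' chromosomes, and (2) the within-window length of that tract (or the summed
#' lengths of all tracts passing condition 1) is at least `overlap_fraction`
#' of the window. Tracts failing the carrier test contribute nothing.
#'
#' @param tracts A data.table with `left`, `right` and either `carriers`
#'   (list column of haplotype ids) or `n_carriers`.
#' @param n_windows,width Window grid.
#' @param carrier_fraction Minimum tract frequency among P2 chromosomes.
#' @param overlap_fraction Minimum summed within-window tract length as a
#'   fraction of the window.
#' @param n_chromosomes Number of sampled P2 chromosomes.
#' @return Character vector of `introgressed` / `not_introgressed` labels.
#' @export
label_windows_freq <- function(tracts, n_windows, width,
                               carrier_fraction = 0.10,
                               overlap_fraction = 0.10, n_chromosomes) {
  stopifnot(n_chromosomes > 1)
  if (is.null(tracts) || nrow(tracts) == 0L) {
    return(rep("not_introgressed", n_windows))
  }
  nc <- if ("n_carriers" %in% names(tracts)) {
    tracts$n_carriers
  } else {
    vapply(tracts$carriers, function(x) length(unique(x)), 1L)
  }
  keep <- nc >= carrier_fraction * n_chromosomes
  ov <- window_tract_overlap(tracts[keep, , drop = FALSE], n_windows, width)
  ifelse(ov >= overlap_fraction * width, "introgressed", "not_introgressed")
}

#' Confusion-matrix performance of significance calls against truth
#'
#' Dropped windows are excluded from every cell. Precision is TP / (TP + FP)
#' (equivalently 1 - FDR), recall TP / (TP + FN), and the false positive rate
#' FP / (FP + TN); a component whose denominator is zero is `NA`.
#'
#' @param calls Logical vector of significance calls per window.
#' @param truth Character labels from [label_windows_n1()] /
#'   [label_windows_freq()].
#' @return A one-row `data.table` with the four confusion counts and
#'   `precision`, `recall`, `fpr`.
#' @export
performance <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth must cover the same windows")
  }
  use <- truth != "dropped" & !is.na(calls)
  calls <- calls[use]; truth <- truth[use]
  pos <- truth == "introgressed"
  tp <- sum(calls & pos); fp <- sum(calls & !pos)
  fn <- sum(!calls & pos); tn <- sum(!calls & !pos)
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  data.table::data.table(tp = tp, fp = fp, fn = fn, tn = tn,
                         precision = rat(tp, tp + fp),
                         recall = rat(tp, tp + fn),
                         fpr = rat(fp, fp + tn))
}

#' Null distribution of windowed statistics under no gene flow
#'
#' Simulates replicate genomes with the admixture proportion forced to zero,
#' scans them, pools the defined per-window values of each statistic, and
#' summarizes the pooled null (mean, SD, and the point mass at exactly +-1
#' that makes D unusable in small windows).
#'
#' @param demog An [iua_demography()]; must have `f = 0`.
#' @param n_reps Number of replicate genomes.
#' @param length Genome length in bp per replicate.
#' @param width Window width in bp.
#' @param seed Integer seed.
#' @param python Optional python interpreter path.
#' @return A list with `windows` (pooled window table with `rep_id`),
#'   `values` (named list of defined value vectors per statistic) and
#'   `summary` (a `data.table` with mean, sd and tail mass per statistic).
#' @export
null_distribution <- function(demog, n_reps, length = 20e6, width = 50000L,
                              seed, python = NULL) {
  if (demog$f != 0) stop("the null distribution requires f = 0")
  sim <- simulate_iua_replicates(demog, n_reps, length, seed = seed,
                                 python = python)
  windows <- scan_sim_windows(sim, width)
  stats_cols <- c("d", "d_plus", "d_ancestral")
  values <- lapply(stats_cols, function(s) windows[[s]][!is.na(windows[[s]])])
  names(values) <- stats_cols
  summary <- data.table::rbindlist(lapply(stats_cols, function(s) {
    v <- values[[s]]
    data.table::data.table(stat = s, n_defined = length(v), mean = mean(v),
                           sd = stats::sd(v),
                           tail_mass = mean(abs(v) == 1))
  }))
  list(windows = windows, values = values, summary = summary, sim = sim)
}

#' Scan simulated replicates into pooled window tables
#'
#' Computes the windowed statistics for every replicate of a simulation, once
#' per requested P2 haplotype (all against the same P1 and P3 haplotypes), with
#' the simulation's known ancestral states (outgroup frequency 0 unless P4
#' haplotypes were sampled).
#'
#' @param sim An `iua_sim` from [simulate_iua_replicates()].
#' @param width Window width in bp.
#' @param p2_haps Indices of P2 haplotypes to scan (default all sampled).
#' @param p1_hap,p3_hap Which P1 and P3 haplotype to use; the same one is
#'   reused against every scanned P2 haplotype.
#' @return A `data.table` of windows with `rep_id` and `hap` columns.
#' @export
scan_sim_windows <- function(sim, width = 50000L, p2_haps = NULL,
                             p1_hap = 1L, p3_hap = 1L) {
  labels <- colnames(sim$replicates[[1]]$geno)
  pops <- sub("_.*$", "", labels)
  i_p1 <- which(pops == "P1")[p1_hap]
  i_p3 <- which(pops == "P3")[p3_hap]
  i_p2 <- which(pops == "P2")
  i_p4 <- which(pops == "P4")
  if (is.null(p2_haps)) p2_haps <- seq_along(i_p2)
  data.table::rbindlist(lapply(seq_along(sim$replicates), function(r) {
    rep <- sim$replicates[[r]]
    p4 <- if (length(i_p4)) rowMeans(rep$geno[, i_p4, drop = FALSE]) else 0
    data.table::rbindlist(lapply(p2_haps, function(h) {
      freq <- cbind(rep$geno[, i_p1], rep$geno[, i_p2[h]],
                    rep$geno[, i_p3], p4)
      sc <- window_scan(rep$pos, freq, width = width,
                        chrom_length = sim$length, chrom = "sim")
      sc[, `:=`(rep_id = r, hap = h)]
    }))
  }))
}

#' Per-replicate truth labels for simulated windows
#'
#' @param sim An `iua_sim`.
#' @param width Window width in bp.
#' @param overlap_fraction Minimum introgressed fraction of a window.
#' @param p2_haps P2 haplotypes whose tracts define the truth; with more than
#'   one, the union of their tracts is used.
#' @return A `data.table` with `rep_id`, `win`, `label`.
#' @export
truth_labels_sim <- function(sim, width = 50000L, overlap_fraction = 0.10,
                             p2_haps = NULL) {
  n_win <- floor(sim$length / width)
  data.table::rbindlist(lapply(seq_along(sim$replicates), function(r) {
    tr <- sim$replicates[[r]]$tracts
    if (!is.null(p2_haps)) tr <- tr[tr$hap %in% p2_haps, ]
    lab <- label_windows_n1(tr, n_win, width, overlap_fraction)
    data.table::data.table(rep_id = r, win = seq_len(n_win), label = lab)
  }))
}

#' Precision / recall / FPR curve against an empirical null
#'
#' For each nominal p-value, takes the upper-tail threshold from the null
#' values, calls windows with a defined statistic at or above it significant,
#' and scores the calls against the truth labels (dropped windows and windows
#' with an undefined statistic are excluded).
#'
#' @param windows Window table (e.g. from [scan_sim_windows()]) with `rep_id`,
#'   `win` and the statistic column.
#' @param truth Truth table from [truth_labels_sim()].
#' @param null_values Defined null values of the same statistic.
#' @param stat Statistic column name (`"d"`, `"d_plus"`, ...).
#' @param p_grid Nominal p-values (default 0.01-1 in steps of 0.01).
#' @return A `data.table` with one row per p: threshold, confusion counts,
#'   precision, recall, fpr.
#' @export
performance_curve <- function(windows, truth, null_values, stat = "d_plus",
                              p_grid = seq(0.01, 1, by = 0.01)) {
  merged <- merge(windows, truth, by = c("rep_id", "win"))
  if (nrow(merged) != nrow(windows)) {
    stop("window set and truth labels do not match")
  }
  vals <- merged[[stat]]
  data.table::rbindlist(lapply(p_grid, function(p) {
    thr <- empirical_threshold(null_values, min(p, 0.999))
    perf <- performance(is_significant(vals, thr)[!is.na(vals)],
                        merged$label[!is.na(vals)])
    data.table::data.table(p = p, threshold = thr, perf)
  }))
}

#' Clock-violation demography: unequal mutation input on P1 vs P2
#'
#' Emulates a `factor`-fold higher mutation rate on one of the ingroup terminal
#' branches by elongating it: all event times are shifted by
#' `(factor - 1) * t_p2` and the *other* ingroup population is sampled at the
#' shift, so the target population's terminal branch is `factor` times longer
#' than its sister's. P3, an archaic donor, is sampled just after the shifted
#' gene-flow time; P4 stays at the present.
#'
#' @param demog An [iua_demography()] with sampling at the present.
#' @param population Which terminal branch to elongate: `"P1"` or `"P2"`.
#' @param factor Branch-length (equivalently mutation-rate) ratio; must be > 1.
#' @return A new `iua_demography` with shifted event times and per-population
#'   `sample_times` (generations).
#' @export
clock_violation_demography <- function(demog, population = c("P1", "P2"),
                                       factor) {
  population <- match.arg(population)
  if (!(factor > 1)) stop("factor must be > 1 (the identity is not a violation)")
  shift <- (factor - 1) * demog$t_p2
  gen <- 2 * demog$n_e
  st <- c(0, 0, (demog$t_gf + shift) * gen, 0)
  if (population == "P1") {
    st[2] <- shift * gen   # P2 sampled later => its branch is shorter
  } else {
    st[1] <- shift * gen
  }
  iua_demography(f = demog$f, t_gf = demog$t_gf + shift,
                 t_p2 = demog$t_p2 + shift, t_p3 = demog$t_p3 + shift,
                 t_p4 = demog$t_p4 + shift, n_e = demog$n_e, mu = demog$mu,
                 rec = demog$rec, units = "2N", sample_times = st)
}

#' Inject sequencing errors into simulated haplotypes
#'
#' Flips each 0/1 allele independently with the given probability;
#' deterministic given the seed. Apply to the columns of the population(s)
#' whose error process is being emulated.
#'
#' @param haps 0/1 matrix (sites x haplotypes).
#' @param rate Per-site error probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The perturbed matrix.
#' @export
inject_errors <- function(haps, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  haps <- as.matrix(haps)
  if (rate == 0) return(haps)
  set.seed(seed)
  flip <- matrix(stats::runif(length(haps)) < rate, nrow(haps))
  haps[flip] <- 1L - haps[flip]
  haps
}

#' Run the full simulation benchmark
#'
#' The end-to-end pipeline of the simulation study at configurable scale:
#' simulate a null cohort (f forced to 0) and an admixed cohort under the same
#' demography, scan both in non-overlapping windows, label truth from the
#' admixed cohort's introgressed tracts, and score precision, recall and FPR
#' over the p-value grid for each requested statistic.
#'
#' @param demog An [iua_demography()] with the admixture proportion of the
#'   alternative model (`f > 0`).
#' @param n_reps Replicates per cohort.
#' @param length,width Genome and window size in bp.
#' @param seed Integer seed (expanded internally into engine seeds for the two
#'   cohorts).
#' @param stats Statistic columns to score.
#' @param p_grid Nominal p-values.
#' @param overlap_fraction Truth-labeling overlap fraction.
#' @param python Optional python interpreter path.
#' @return A list with `null` (see [null_distribution()]), `windows`, `truth`
#'   and `curves` (named list of performance curves per statistic).
#' @export
run_benchmark <- function(demog, n_reps, length = 20e6, width = 50000L, seed,
                          stats = c("d", "d_plus"),
                          p_grid = seq(0.01, 1, by = 0.01),
                          overlap_fraction = 0.10, python = NULL) {
  if (demog$f <= 0) stop("benchmark demography must have f > 0")
  null_demog <- demog
  null_demog$f <- 0
  null <- null_distribution(null_demog, n_reps, length, width,
                            seed = seed + 1L, python = python)
  sim <- simulate_iua_replicates(demog, n_reps, length, seed = seed + 2L,
                                 python = python)
  windows <- scan_sim_windows(sim, width)
  truth <- truth_labels_sim(sim, width, overlap_fraction)
  curves <- lapply(stats, function(s) {
    performance_curve(windows, truth, null$values[[s]], s, p_grid)
  })
  names(curves) <- stats
  list(null = null, sim = sim, windows = windows, truth = truth,
       curves = curves)
}

#' Max-of-two-chromosomes benchmark (diploid P2 individual)
#'
#' Emulates the scan of one phased diploid P2 individual: two P2 haplotypes
#' are sampled and scanned against the same P1 and P3 haplotypes, the
#' per-window statistic is the maximum of the two values, and significance is
#' assessed against the pooled empirical distribution of all per-haplotype
#' values (two per window), as in the empirical-data convention. Truth labels
#' use the union of the two haplotypes' introgressed tracts.
#'
#' @inheritParams run_benchmark
#' @param p Nominal p-value for the significance threshold.
#' @return A list with `windows`, `truth`, and per-statistic one-row
#'   performance tables in `perf`.
#' @export
run_max2_benchmark <- function(demog, n_reps, length = 20e6, width = 50000L,
                               seed, stats = c("d", "d_plus"), p = 0.05,
                               overlap_fraction = 0.10, python = NULL) {
  sim <- simulate_iua_replicates(demog, n_reps, length,
                                 samples = c(P1 = 1, P2 = 2, P3 = 1, P4 = 0),
                                 seed = seed, python = python)
  windows <- scan_sim_windows(sim, width)
  truth <- truth_labels_sim(sim, width, overlap_fraction)
  perf <- lapply(stats, function(s) {
    null_vals <- windows[[s]][!is.na(windows[[s]])]
    thr <- empirical_threshold(null_vals, p)
    wide <- data.table::dcast(windows, rep_id + win ~ hap, value.var = s)
    wide[, value := max_over_haplotypes(`1`, `2`)]
    merged <- merge(wide, truth, by = c("rep_id", "win"))
    ok <- !is.na(merged$value)
    data.table::data.table(p = p, threshold = thr,
                           performance(is_significant(merged$value[ok], thr),
                                       merged$label[ok]))
  })
  names(perf) <- stats
  list(sim = sim, windows = windows, truth = truth, perf = perf)
}
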
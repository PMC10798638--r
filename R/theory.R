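#' Instantaneous unidirectional admixture (IUA) demography
#'
#' The four-population model used throughout: sister populations P1 and P2
#' diverged at `t_p2`, their ancestor split from the donor P3 at `t_p3`, and
#' the outgroup P4 split at `t_p4`. A single pulse of admixture moves a
#' fraction `f` of P2's ancestry from P3 at `t_gf`. All populations have
#' constant diploid effective size `n_e`. Event times are stored internally in
#' coalescent units of 2N generations; the constructor accepts generations,
#' 2N units, or the ms-style 4N units.
#'
#' @param f Admixture proportion of the P3 -> P2 pulse, in `[0, 1]`.
#' @param t_gf,t_p2,t_p3,t_p4 Event times (pulse, P1/P2 split, P12/P3 split,
#'   outgroup split), in `units`. Must satisfy `0 <= t_gf < t_p2 < t_p3 < t_p4`.
#' @param n_e Diploid effective population size.
#' @param mu Mutation rate per bp per generation.
#' @param rec Recombination rate per bp per generation.
#' @param units Units of the supplied times: `"generations"`, `"2N"` or `"4N"`.
#' @param sample_times Optional sampling times for P1..P4 in generations
#'   (default all zero); used by the clock-violation constructions.
#' @return An object of class `iua_demography` with times in 2N units.
#' @examples
#' # the human/Neanderthal-style parameterization used for the benchmarks
#' iua_demography(f = 0.03, t_gf = 1600, t_p2 = 4000, t_p3 = 16000,
#'                t_p4 = 8e5, n_e = 1e4)
#' @export
iua_demography <- function(f, t_gf, t_p2, t_p3, t_p4, n_e = 1e4,
                           mu = 1.5e-8, rec = 1e-8,
                           units = c("generations", "2N", "4N"),
                           sample_times = c(0, 0, 0, 0)) {
  units <- match.arg(units)
  scale <- switch(units, generations = 1 / (2 * n_e), "2N" = 1, "4N" = 2)
  tt <- c(t_gf = t_gf, t_p2 = t_p2, t_p3 = t_p3, t_p4 = t_p4) * scale
  if (anyNA(tt) || any(tt < 0)) stop("event times must be nonnegative")
  if (!(tt[1] < tt[2] && tt[2] < tt[3] && tt[3] < tt[4])) {
    stop("event times must satisfy t_gf < t_p2 < t_p3 < t_p4")
  }
  if (is.na(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (n_e <= 0 || mu < 0 || rec < 0) stop("invalid n_e, mu or rec")
  if (length(sample_times) != 4 || any(sample_times < 0)) {
    stop("sample_times must be four nonnegative times in generations")
  }
  structure(list(f = f, t_gf = unname(tt[1]), t_p2 = unname(tt[2]),
                 t_p3 = unname(tt[3]), t_p4 = unname(tt[4]),
                 n_e = n_e, mu = mu, rec = rec,
                 sample_times = as.numeric(sample_times)),
            class = "iua_demography")
}

#' The benchmark demography (human/Neanderthal-style parameters)
#'
#' Convenience constructor for the parameterization used by the simulation
#' study: Ne = 10,000, T_GF = 1,600, T_P2 = 4,000, T_P3 = 16,000 generations,
#' outgroup split at 800,000 generations, mu = 1.5e-8, r = 1e-8.
#'
#' @param f Admixture proportion (default 0.03).
#' @return An `iua_demography`.
#' @export
iua_benchmark_demography <- function(f = 0.03) {
  iua_demography(f = f, t_gf = 1600, t_p2 = 4000, t_p3 = 16000, t_p4 = 8e5,
                 n_e = 1e4, mu = 1.5e-8, rec = 1e-8, units = "generations")
}

#' Convert the event times of a demography between time units
#'
#' @param demog An `iua_demography`.
#' @param units Target units: `"generations"`, `"2N"` or `"4N"`.
#' @return Named numeric vector `c(t_gf, t_p2, t_p3, t_p4)` in the target units.
#' @export
event_times <- function(demog, units = c("generations", "2N", "4N")) {
  units <- match.arg(units)
  scale <- switch(units, generations = 2 * demog$n_e, "2N" = 1, "4N" = 0.5)
  c(t_gf = demog$t_gf, t_p2 = demog$t_p2,
    t_p3 = demog$t_p3, t_p4 = demog$t_p4) * scale
}

#' @export
print.iua_demography <- function(x, ...) {
  gen <- event_times(x, "generations")
  cat(sprintf("IUA demography: f = %g, Ne = %g, mu = %g, r = %g\n",
              x$f, x$n_e, x$mu, x$rec))
  cat(sprintf("  t_gf = %g, t_p2 = %g, t_p3 = %g, t_p4 = %g generations\n",
              gen[1], gen[2], gen[3], gen[4]))
  if (any(x$sample_times != 0)) {
    cat("  sampling times (gen):", paste(x$sample_times, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Closed-form expected branch lengths under the IUA model
#'
#' Expected lengths of the four branches on which a single mutation yields an
#' ABBA, BABA, BAAA or ABAA site, for one haplotype sampled from each
#' population. The derivation conditions on the admixture pulse (probability
#' `f` the P2 lineage traces through P3 at `t_gf`) and on whether the first
#' available pair coalesces before `t_p3`; after `t_p3` the three surviving
#' lineages form an exchangeable coalescent block. T_ABBA (T_BABA) is the
#' lifetime of the lineage ancestral to exactly P2 and P3 (P1 and P3); T_BAAA
#' and T_ABAA are the terminal branches of P1 and P2. The outgroup split is
#' assumed distant (`t_p4 >> t_p3`), so coalescence with the outgroup lineage
#' is neglected; the error is of order `exp(-(t_p4 - t_p3))` in 2N units.
#'
#' At `f = 0`, `E[T_ABBA] = E[T_BABA]` and `E[T_BAAA] = E[T_ABAA]` (incomplete
#' lineage sorting alone), and the identity
#' `E[T_ABBA - T_BABA] = E[T_BAAA - T_ABAA] = f (t_p3 - t_gf)` holds exactly.
#'
#' @param demog An `iua_demography`.
#' @param units Time units of the returned lengths (default 2N generations).
#' @return Named numeric vector
#'   `c(e_t_abba, e_t_baba, e_t_baaa, e_t_abaa)`.
#' @export
expected_branch_lengths <- function(demog, units = c("2N", "4N", "generations")) {
  units <- match.arg(units)
  f <- demog$f
  tau1 <- demog$t_gf; tau2 <- demog$t_p2; tau3 <- demog$t_p3
  d23 <- tau3 - tau2
  d13 <- tau3 - tau1
  q <- exp(-d23)   # P(P1,P2 lineages do not coalesce in P12 | no pulse)
  g <- exp(-d13)   # P(P2,P3 lineages do not coalesce in P3 | pulse)

  # mean coalescence time of a pair over (start, tau3), conditional on
  # coalescing, for rate-1 pairwise coalescence
  trunc_mean <- function(start, delta, surv) {
    if (delta <= 0) return(start) # probability-0 branch, value irrelevant
    start + 1 - delta * surv / (1 - surv)
  }
  m23 <- trunc_mean(tau2, d23, q)
  m13 <- trunc_mean(tau1, d13, g)

  # exchangeable 3-lineage block entered at tau3: first coalescence at
  # tau3 + 1/3 on average, each pair first with probability 1/3, second
  # coalescence a further Exp(1) later
  ext3 <- tau3 + 2 / 3   # expected terminal-branch end for any of the three
  pair3 <- 1 / 3         # expected lifetime of a specific 2-lineage clade

  ngf_ext <- (1 - q) * m23 + q * ext3
  e_abba <- (1 - f) * q * pair3 +
    f * ((1 - g) * (tau3 + 1 - m13) + g * pair3)
  e_baba <- (1 - f) * q * pair3 + f * g * pair3
  e_baaa <- (1 - f) * ngf_ext +
    f * ((1 - g) * (tau3 + 1) + g * ext3)
  e_abaa <- (1 - f) * ngf_ext +
    f * ((1 - g) * m13 + g * ext3)

  scale <- switch(units, "2N" = 1, "4N" = 0.5, generations = 2 * demog$n_e)
  c(e_t_abba = e_abba, e_t_baba = e_baba,
    e_t_baaa = e_baaa, e_t_abaa = e_abaa) * scale
}

#' Expected ABBA-BABA (and BAAA-ABAA) branch-length difference
#'
#' The admixture signal in branch-length form: both pattern contrasts have the
#' same expectation, `f * (t_p3 - t_gf)`.
#'
#' @inheritParams expected_branch_lengths
#' @return A single number in the requested units.
#' @export
expected_pattern_difference <- function(demog,
                                        units = c("2N", "4N", "generations")) {
  units <- match.arg(units)
  scale <- switch(units, "2N" = 1, "4N" = 0.5, generations = 2 * demog$n_e)
  demog$f * (demog$t_p3 - demog$t_gf) * scale
}

#' Analytical expectation of D+ (and D) under the IUA model
#'
#' Ratio of expected pattern-count differences to sums; the mutation rate
#' cancels, leaving a function of the expected branch lengths alone. Both
#' expectations are zero at `f = 0` and increase with `f`.
#'
#' @param demog An `iua_demography`.
#' @return A single dimensionless number.
#' @export
expected_d_plus <- function(demog) {
  e <- expected_branch_lengths(demog)
  ((e[["e_t_abba"]] - e[["e_t_baba"]]) + (e[["e_t_baaa"]] - e[["e_t_abaa"]])) /
    ((e[["e_t_abba"]] + e[["e_t_baba"]]) + (e[["e_t_baaa"]] + e[["e_t_abaa"]]))
}

#' @rdname expected_d_plus
#' @export
expected_d <- function(demog) {
  e <- expected_branch_lengths(demog)
  (e[["e_t_abba"]] - e[["e_t_baba"]]) / (e[["e_t_abba"]] + e[["e_t_baba"]])
}

#' Monte-Carlo single-locus sampler under the IUA model
#'
#' Structured-coalescent simulation of one non-recombining locus with one
#' lineage per population: Bernoulli(`f`) relocation of the P2 lineage into P3
#' at `t_gf`, population mergers at `t_p2`, `t_p3` and `t_p4`, and exponential
#' pairwise coalescence within populations. Per replicate it extracts the
#' lifetimes of the branches generating ABBA, BABA, BAAA and ABAA sites and,
#' with a per-locus scaled mutation rate `theta_locus` (ms convention,
#' 4N x mu x locus length), Poisson site counts from which per-locus D and D+
#' are computed. This sampler is the independent oracle for
#' [expected_branch_lengths()]; it shares no code with the closed forms (and,
#' unlike them, includes the outgroup phase after `t_p4`).
#'
#' @param demog An `iua_demography`.
#' @param n_replicates Number of independent loci.
#' @param seed Integer seed (all randomness flows from it).
#' @param theta_locus Per-locus scaled mutation rate for the D/D+ site counts.
#' @param return_samples Keep the per-replicate branch-length matrix?
#' @return A list with `branch_means`, `branch_se` (Monte-Carlo standard
#'   errors), `mean_d`, `mean_d_plus` (averages over loci where defined),
#'   `n_replicates`, and optionally `branches`. Branch lengths are in 2N units.
#' @export
single_locus_sampler <- function(demog, n_replicates, seed, theta_locus = 0.1,
                                 return_samples = FALSE) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  br <- cpp_single_locus_branches(as.integer(n_replicates), demog$f,
                                  demog$t_gf, demog$t_p2, demog$t_p3,
                                  demog$t_p4)
  colnames(br) <- c("t_abba", "t_baba", "t_baaa", "t_abaa")
  counts <- matrix(stats::rpois(length(br), theta_locus / 2 * br), ncol = 4,
                   dimnames = list(NULL, colnames(br)))
  d_num <- counts[, "t_abba"] - counts[, "t_baba"]
  d_den <- counts[, "t_abba"] + counts[, "t_baba"]
  dp_num <- d_num + counts[, "t_baaa"] - counts[, "t_abaa"]
  dp_den <- d_den + counts[, "t_baaa"] + counts[, "t_abaa"]
  out <- list(
    branch_means = colMeans(br),
    branch_se = apply(br, 2, stats::sd) / sqrt(nrow(br)),
    mean_d = mean((d_num / d_den)[d_den > 0]),
    mean_d_plus = mean((dp_num / dp_den)[dp_den > 0]),
    n_replicates = n_replicates
  )
  if (return_samples) out$branches <- br
  out
}

#' Read or write a demography configuration file
#'
#' Flat key-value text format with keys `f, t_gf, t_p2, t_p3, t_p4, n_e, mu,
#' rec, units` (one `key = value` pair per line; `#` comments allowed).
#'
#' @param path File path.
#' @return For `read_demography_config`, an `iua_demography`.
#' @export
read_demography_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  keys <- trimws(kv[, 1]); vals <- trimws(kv[, 2])
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  units <- get("units", "generations")
  num <- function(k, default = NULL) {
    v <- get(k, default); if (is.null(v)) stop("missing key: ", k)
    as.numeric(v)
  }
  iua_demography(f = num("f"), t_gf = num("t_gf"), t_p2 = num("t_p2"),
                 t_p3 = num("t_p3"), t_p4 = num("t_p4"),
                 n_e = num("n_e", "10000"), mu = num("mu", "1.5e-8"),
                 rec = num("rec", "1e-8"), units = units)
}

#' @rdname read_demography_config
#' @param demog An `iua_demography` to serialize.
#' @export
write_demography_config <- function(demog, path) {
  gen <- event_times(demog, "generations")
  writeLines(c(
    sprintf("f = %.17g", demog$f),
    sprintf("t_gf = %.17g", gen[["t_gf"]]),
    sprintf("t_p2 = %.17g", gen[["t_p2"]]),
    sprintf("t_p3 = %.17g", gen[["t_p3"]]),
    sprintf("t_p4 = %.17g", gen[["t_p4"]]),
    sprintf("n_e = %.17g", demog$n_e),
    sprintf("mu = %.17g", demog$mu),
    sprintf("rec = %.17g", demog$rec),
    "units = generations"
  ), path)
  invisible(path)
}
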
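#' @title Window statistics for introgression detection
#' @description
#' The five statistics computed per genomic window. `D` is Patterson's
#' statistic, the normalized excess of ABBA over BABA sites. `D+` adds the
#' shared-ancestral patterns (BAAA, ABAA) to both the numerator and the
#' denominator, and `D_ancestral` uses the ancestral patterns alone. All three
#' lie in `[-1, 1]`; positive values indicate gene flow from P3 into P2,
#' negative values from P3 into P1. `fd-hat` and `df` are window-level
#' estimators of the admixture proportion built from the same frequency
#' weights. A statistic whose denominator is zero is *undefined* and returned
#' as `NA_real_`; downstream consumers drop undefined windows (they are never
#' coerced to zero, which would corrupt null distributions).
#' @name window_statistics
NULL

num_den_ratio <- function(num, den) {
  ifelse(den > 0, num / den, NA_real_)
}

#' Patterson's D from pattern counts
#'
#' @param counts A [site_pattern_counts()] object.
#' @return `(abba - baba) / (abba + baba)`, or `NA_real_` when undefined.
#' @export
compute_d <- function(counts) {
  num_den_ratio(counts$abba - counts$baba, counts$abba + counts$baba)
}

#' D+ from pattern counts
#'
#' @param counts A [site_pattern_counts()] object.
#' @return `((abba - baba) + (baaa - abaa)) / ((abba + baba) + (baaa + abaa))`,
#'   or `NA_real_` when undefined. When the counts are frequency-weighted sums
#'   this is the derived-allele-frequency form of the statistic.
#' @export
compute_d_plus <- function(counts) {
  num_den_ratio((counts$abba - counts$baba) + (counts$baaa - counts$abaa),
                (counts$abba + counts$baba) + (counts$baaa + counts$abaa))
}

#' D_ancestral from pattern counts
#'
#' @param counts A [site_pattern_counts()] object.
#' @return `(baaa - abaa) / (baaa + abaa)`, or `NA_real_` when undefined.
#' @export
compute_d_ancestral <- function(counts) {
  num_den_ratio(counts$baaa - counts$abaa, counts$baaa + counts$abaa)
}

#' fd-hat admixture-proportion estimator for one window
#'
#' The numerator matches D's numerator; the denominator replaces the P2 and P3
#' derived frequencies with their per-site maximum `pD = max(p2, p3)`,
#' emulating a donor fixed for the derived allele. The estimator is only
#' meaningful in windows where D > 0, so calling it on a window with D <= 0 is
#' a policy error and the caller is expected to skip such windows.
#'
#' @param freqs Numeric matrix of derived-allele frequencies (columns P1..P4).
#' @return The fd-hat value, or `NA_real_` when its denominator is zero.
#' @export
compute_f_hat_d <- function(freqs) {
  freqs <- matrix(as.numeric(freqs), ncol = 4)
  w <- pattern_weights(freqs[, 1], freqs[, 2], freqs[, 3], freqs[, 4])
  d <- num_den_ratio(sum(w[, "abba"]) - sum(w[, "baba"]),
                     sum(w[, "abba"]) + sum(w[, "baba"]))
  if (is.na(d) || d <= 0) {
    stop("fd-hat is only defined for windows with D > 0; skip this window")
  }
  p1 <- freqs[, 1]; p4 <- freqs[, 4]
  pd <- pmax(freqs[, 2], freqs[, 3])
  den <- sum((1 - p1) * pd * pd * (1 - p4) - p1 * (1 - pd) * pd * (1 - p4))
  num_den_ratio(sum(w[, "abba"]) - sum(w[, "baba"]), den)
}

#' df admixture-proportion estimator for one window
#'
#' Shares D's numerator but adds the BBAA weight (derived allele shared only by
#' P1 and P2, depleted under introgression) to each of the two denominator
#' groups, so the BBAA term enters the denominator twice.
#'
#' @param freqs Numeric matrix of derived-allele frequencies (columns P1..P4).
#' @return The df value, or `NA_real_` when its denominator is zero.
#' @export
compute_d_f <- function(freqs) {
  freqs <- matrix(as.numeric(freqs), ncol = 4)
  w <- pattern_weights(freqs[, 1], freqs[, 2], freqs[, 3], freqs[, 4])
  num <- sum(w[, "abba"]) - sum(w[, "baba"])
  den <- sum(w[, "abba"] + w[, "bbaa"]) + sum(w[, "baba"] + w[, "bbaa"])
  num_den_ratio(num, den)
}

#' Nucleotide diversity of one population in a window
#'
#' Average pairwise difference per base pair: the per-site unbiased
#' heterozygosity `2 p (1-p) n/(n-1)` summed over segregating sites and divided
#' by the full window length in bp (invariant sites included).
#'
#' @param haps 0/1 matrix of derived alleles, sites in rows, haplotypes in
#'   columns (at least two haplotypes).
#' @param window_length Window width in bp.
#' @return Nonnegative per-site diversity; 0 for a monomorphic window.
#' @export
compute_pi <- function(haps, window_length) {
  if (is.null(haps) || NCOL(haps) < 2L) {
    stop("nucleotide diversity requires at least 2 haplotypes")
  }
  if (window_length <= 0) stop("window_length must be positive")
  haps <- as.matrix(haps)
  if (nrow(haps) == 0L) return(0)
  n <- ncol(haps)
  p <- rowMeans(haps)
  sum(2 * p * (1 - p) * n / (n - 1)) / window_length
}
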
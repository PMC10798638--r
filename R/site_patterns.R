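#' Classify a polarized biallelic site into a four-taxon pattern
#'
#' Assigns one of the five informative site patterns to a site observed in
#' single haplotypes from the ordered quartet (P1, P2, P3, P4), where each
#' allele state is `"A"` (ancestral) or `"B"` (derived). An ABBA site carries
#' the derived allele in P2 and P3, a BABA site in P1 and P3, a BAAA site only
#' in P1, an ABAA site only in P2, and a BBAA site in P1 and P2. Any other
#' configuration (including monomorphic sites and sites where the outgroup
#' carries the derived allele) is `"NONINFORMATIVE"`.
#'
#' @param a1,a2,a3,a4 Allele states in P1..P4; character vectors of `"A"`/`"B"`
#'   (vectors are classified elementwise).
#' @return Character vector of labels in
#'   `c("ABBA","BABA","BAAA","ABAA","BBAA","NONINFORMATIVE")`.
#' @examples
#' classify_site("A", "B", "B", "A") # ABBA
#' classify_site("B", "A", "A", "A") # BAAA
#' @export
classify_site <- function(a1, a2, a3, a4) {
  states <- cbind(a1, a2, a3, a4)
  if (!all(states %in% c("A", "B"))) {
    stop("allele states must be \"A\" (ancestral) or \"B\" (derived)")
  }
  key <- paste0(a1, a2, a3, a4)
  patterns <- c(ABBA = "ABBA", BABA = "BABA", BAAA = "BAAA",
                ABAA = "ABAA", BBAA = "BBAA")
  out <- patterns[key]
  out[is.na(out)] <- "NONINFORMATIVE"
  unname(out)
}

#' Frequency weights of the five site patterns
#'
#' Computes, for each site, the probability weight of drawing each pattern when
#' one haplotype is sampled from every population, given the derived-allele
#' frequencies. For a site with frequencies (p1, p2, p3, p4) the ABBA weight is
#' (1-p1) p2 p3 (1-p4), and similarly for BABA, BAAA, ABAA and BBAA. In the
#' haploid limit (all frequencies 0 or 1) the weights reproduce
#' [classify_site()] as exact 0/1 indicators.
#'
#' @param p1,p2,p3,p4 Numeric vectors of derived-allele frequencies in `[0,1]`.
#' @return Numeric matrix with one row per site and columns
#'   `abba`, `baba`, `baaa`, `abaa`, `bbaa`.
#' @examples
#' pattern_weights(0, 1, 1, 0)            # pure ABBA site
#' pattern_weights(0.5, 0.5, 0.5, 0)      # mixed weights
#' @export
pattern_weights <- function(p1, p2, p3, p4) {
  p <- cbind(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("derived-allele frequencies must lie in [0, 1]")
  }
  q1 <- 1 - p[, 1]; q2 <- 1 - p[, 2]; q3 <- 1 - p[, 3]; q4 <- 1 - p[, 4]
  cbind(
    abba = q1 * p[, 2] * p[, 3] * q4,
    baba = p[, 1] * q2 * p[, 3] * q4,
    baaa = p[, 1] * q2 * q3 * q4,
    abaa = q1 * p[, 2] * q3 * q4,
    bbaa = p[, 1] * p[, 2] * q3 * q4
  )
}

#' Construct a site-pattern count object
#'
#' Container for per-window pattern sums. Accumulators are real-valued: they
#' hold integer tallies for single-haplotype input and frequency-weighted sums
#' otherwise, so one code path serves both cases.
#'
#' @param abba,baba,baaa,abaa,bbaa Nonnegative pattern accumulators.
#' @param n_sites Number of polarized biallelic sites accumulated.
#' @return An object of class `site_pattern_counts`.
#' @export
site_pattern_counts <- function(abba = 0, baba = 0, baaa = 0, abaa = 0,
                                bbaa = 0, n_sites = 0L) {
  x <- list(abba = unname(abba), baba = unname(baba), baaa = unname(baaa),
            abaa = unname(abaa), bbaa = unname(bbaa),
            n_sites = as.integer(n_sites))
  vals <- unlist(x[1:5])
  if (anyNA(vals) || any(vals < 0)) stop("pattern accumulators must be >= 0")
  if (x$n_sites < 0) stop("n_sites must be >= 0")
  structure(x, class = "site_pattern_counts")
}

#' @export
print.site_pattern_counts <- function(x, ...) {
  cat("site pattern counts over", x$n_sites, "sites:\n")
  print(round(unlist(x[1:5]), 4))
  invisible(x)
}

#' Accumulate pattern weights over the sites of a window
#'
#' Sums [pattern_weights()] componentwise over all supplied sites. An empty
#' input yields all-zero counts.
#'
#' @param freqs Numeric matrix with four columns (derived-allele frequencies in
#'   P1..P4), one row per site; `NULL` or zero rows give empty counts.
#' @return A [site_pattern_counts()] object.
#' @export
accumulate_window <- function(freqs) {
  if (is.null(freqs) || NROW(freqs) == 0L) return(site_pattern_counts())
  freqs <- matrix(as.numeric(freqs), ncol = 4)
  w <- pattern_weights(freqs[, 1], freqs[, 2], freqs[, 3], freqs[, 4])
  s <- colSums(w)
  site_pattern_counts(s["abba"], s["baba"], s["baaa"], s["abaa"], s["bbaa"],
                      n_sites = nrow(freqs))
}
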
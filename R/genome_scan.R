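#' Polarize biallelic sites into derived-allele frequencies
#'
#' Turns per-population REF/ALT allele counts into derived-allele frequencies.
#' Two polarization modes are supported. `"annotation"` uses a supplied
#' ancestral-allele vector (e.g. a VCF `AA` INFO field or an ancestral FASTA);
#' sites whose annotated ancestral allele matches neither observed allele are
#' skipped. `"outgroup-fixed-else-major"` assigns the ancestral state from the
#' outgroup when the outgroup is fixed for one allele, and otherwise uses the
#' major allele over all four populations; major-allele ties are skipped.
#' Sites with no called alleles in any population are always skipped.
#'
#' @param alt_counts,called Integer matrices (sites x 4 populations) of ALT
#'   allele counts and total called allele counts.
#' @param mode `"annotation"` or `"outgroup-fixed-else-major"`.
#' @param ref,alt Character vectors of REF and ALT alleles (required for
#'   annotation mode).
#' @param ancestral Character vector of ancestral alleles (annotation mode).
#' @return A list with `freq` (sites x 4 derived-allele frequency matrix),
#'   `keep` (logical vector of retained sites) and `skipped` (named counts by
#'   reason).
#' @export
polarize_sites <- function(alt_counts, called,
                           mode = c("outgroup-fixed-else-major", "annotation"),
                           ref = NULL, alt = NULL, ancestral = NULL) {
  mode <- match.arg(mode)
  alt_counts <- as.matrix(alt_counts); called <- as.matrix(called)
  stopifnot(ncol(alt_counts) == 4, ncol(called) == 4)
  n <- nrow(alt_counts)
  skipped <- c(uncalled = 0L, unpolarized = 0L, annotation_mismatch = 0L)

  ok_called <- rowSums(called == 0) == 0
  skipped["uncalled"] <- sum(!ok_called)

  # TRUE where the ALT allele is ancestral (so derived = REF)
  if (mode == "annotation") {
    if (is.null(ancestral) || is.null(ref) || is.null(alt)) {
      stop("annotation mode requires ref, alt and ancestral alleles")
    }
    anc <- toupper(ancestral)
    anc_is_ref <- anc == toupper(ref)
    anc_is_alt <- anc == toupper(alt)
    mismatch <- !(anc_is_ref | anc_is_alt) | is.na(anc)
    skipped["annotation_mismatch"] <- sum(mismatch & ok_called)
    keep <- ok_called & !mismatch
    alt_is_anc <- anc_is_alt
  } else {
    out_alt <- alt_counts[, 4]; out_n <- called[, 4]
    tot_alt <- rowSums(alt_counts); tot_n <- rowSums(called)
    fixed_ref <- out_alt == 0
    fixed_alt <- out_alt == out_n
    major_tie <- 2 * tot_alt == tot_n
    alt_is_anc <- ifelse(fixed_alt & !fixed_ref, TRUE,
                  ifelse(fixed_ref, FALSE, 2 * tot_alt > tot_n))
    unpolarized <- !fixed_ref & !fixed_alt & major_tie
    skipped["unpolarized"] <- sum(unpolarized & ok_called)
    keep <- ok_called & !unpolarized
  }

  p_alt <- alt_counts / called
  freq <- ifelse(matrix(alt_is_anc, n, 4), 1 - p_alt, p_alt)
  colnames(freq) <- c("p1", "p2", "p3", "p4")
  list(freq = freq[keep, , drop = FALSE], keep = keep, skipped = skipped)
}

#' Read a four-population quartet from a VCF
#'
#' Loads biallelic SNPs, computes per-population derived-allele frequencies
#' with the chosen polarization rule, and returns a polarized site set ready
#' for [window_scan()]. Multiallelic sites and indels are excluded.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped).
#' @param pop_map Either a two-column file (sample id, population in
#'   P1/P2/P3/P4) or a named character vector mapping sample -> population.
#' @param ancestral Polarization source: `"outgroup"` for the
#'   outgroup-fixed-else-major rule, `"info:KEY"` for an INFO ancestral-allele
#'   annotation (e.g. `"info:AA"`), or `"fasta:PATH"` for an ancestral FASTA.
#' @return A list of class `dplus_sites` with `chrom`, `pos`, `freq`
#'   (sites x 4), `n_hap` (haplotypes per population) and `skipped` counters.
#' @export
read_vcf_quartet <- function(vcf_path, pop_map, ancestral = "outgroup") {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (is.character(pop_map) && length(pop_map) == 1L) {
    pm <- utils::read.table(pop_map, header = FALSE, stringsAsFactors = FALSE)
    pop_map <- stats::setNames(pm[[2]], pm[[1]])
  }
  if (!all(pop_map %in% c("P1", "P2", "P3", "P4"))) {
    stop("populations in the map must be P1, P2, P3 or P4")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  missing_samples <- setdiff(names(pop_map), colnames(vcf@gt)[-1])
  if (length(missing_samples)) {
    stop("samples in the population map but not in the VCF: ",
         paste(missing_samples, collapse = ", "))
  }
  bi <- vcfR::is.biallelic(vcf) &
    nchar(vcfR::getREF(vcf)) == 1L & nchar(vcfR::getALT(vcf)) == 1L
  vcf <- vcf[bi, ]
  chrom <- vcfR::getCHROM(vcf)
  pos <- vcfR::getPOS(vcf)
  if (any(unlist(tapply(pos, chrom, is.unsorted)))) {
    stop("VCF positions must be sorted within chromosomes")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, names(pop_map), drop = FALSE]

  # allele dosage and call count per sample (haploid or diploid GT)
  a1 <- substr(gt, 1, 1)
  a2 <- ifelse(nchar(gt) >= 3, substr(gt, 3, 3), "")
  dose1 <- ifelse(a1 == "1", 1L, ifelse(a1 == "0", 0L, NA_integer_))
  dose2 <- ifelse(a2 == "1", 1L, ifelse(a2 == "0", 0L, NA_integer_))
  alt_counts <- called <- matrix(0L, nrow(gt), 4)
  n_hap <- integer(4)
  for (k in 1:4) {
    cols <- which(pop_map == paste0("P", k))
    if (!length(cols)) stop("population P", k, " has no samples in the map")
    d1 <- dose1[, cols, drop = FALSE]; d2 <- dose2[, cols, drop = FALSE]
    alt_counts[, k] <- rowSums(d1, na.rm = TRUE) + rowSums(d2, na.rm = TRUE)
    called[, k] <- rowSums(!is.na(d1)) + rowSums(!is.na(d2))
    n_hap[k] <- max(called[, k])
  }

  if (identical(ancestral, "outgroup")) {
    pol <- polarize_sites(alt_counts, called, "outgroup-fixed-else-major")
  } else if (startsWith(ancestral, "info:")) {
    key <- sub("^info:", "", ancestral)
    aa <- vcfR::extract.info(vcf, element = key)
    pol <- polarize_sites(alt_counts, called, "annotation",
                          ref = vcfR::getREF(vcf), alt = vcfR::getALT(vcf),
                          ancestral = aa)
  } else if (startsWith(ancestral, "fasta:")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("ancestral FASTA polarization requires the Biostrings package")
    }
    fa <- Biostrings::readDNAStringSet(sub("^fasta:", "", ancestral))
    names(fa) <- sub("\\s.*$", "", names(fa))
    aa <- rep(NA_character_, length(pos))
    for (ch in intersect(unique(chrom), names(fa))) {
      idx <- which(chrom == ch)
      aa[idx] <- vapply(pos[idx], function(p)
        as.character(Biostrings::subseq(fa[[ch]], p, p)), "")
    }
    pol <- polarize_sites(alt_counts, called, "annotation",
                          ref = vcfR::getREF(vcf), alt = vcfR::getALT(vcf),
                          ancestral = aa)
  } else {
    stop("ancestral must be \"outgroup\", \"info:KEY\" or \"fasta:PATH\"")
  }

  structure(list(chrom = chrom[pol$keep], pos = pos[pol$keep],
                 freq = pol$freq, n_hap = stats::setNames(n_hap,
                                                          paste0("P", 1:4)),
                 skipped = pol$skipped),
            class = "dplus_sites")
}

#' Windowed introgression statistics over polarized sites
#'
#' Partitions one chromosome into non-overlapping windows of `width` bp
#' (0-based half-open; a trailing partial window is dropped) and computes the
#' site-pattern sums and statistics per window. Windows with a zero denominator
#' get `NA` for the affected statistic; fd-hat is additionally `NA` in windows
#' where D <= 0.
#'
#' @param pos Site positions in bp (0-based or 1-based; windows are cut on
#'   `floor(pos / width)`).
#' @param freq Sites x 4 matrix of derived-allele frequencies.
#' @param width Window width in bp (50,000 in the human-style scan, 5,000 in
#'   the butterfly-style scan).
#' @param chrom_length Chromosome length in bp; defaults to the largest
#'   position seen.
#' @param chrom Chromosome name for the output table.
#' @param drop_edges Discard the first and last window (the convention for
#'   empirical scans); simulated scans keep all windows.
#' @param n_hap_p2 Number of P2 haplotypes (needed for nucleotide diversity;
#'   `pi_p2` is `NA` when fewer than 2).
#' @return A `data.table` with one row per window: `chrom`, `start`, `end`,
#'   `n_sites`, `n_informative`, the five pattern sums, `d`, `d_plus`,
#'   `d_ancestral`, `f_hat_d`, `d_f` and `pi_p2`.
#' @export
window_scan <- function(pos, freq, width = 50000L, chrom_length = NULL,
                        chrom = "chr1", drop_edges = FALSE, n_hap_p2 = 1L) {
  freq <- matrix(as.numeric(freq), ncol = 4)
  stopifnot(length(pos) == nrow(freq))
  if (is.unsorted(pos)) stop("site positions must be sorted")
  if (is.null(chrom_length)) chrom_length <- if (length(pos)) max(pos) else 0
  n_win <- floor(chrom_length / width)
  if (n_win < 1L) stop("chromosome shorter than one window")

  w <- pattern_weights(freq[, 1], freq[, 2], freq[, 3], freq[, 4])
  p1 <- freq[, 1]; p4 <- freq[, 4]
  pd <- pmax(freq[, 2], freq[, 3])
  fd_den <- (1 - p1) * pd * pd * (1 - p4) - p1 * (1 - pd) * pd * (1 - p4)
  p2 <- freq[, 2]
  het_p2 <- if (n_hap_p2 >= 2) {
    2 * p2 * (1 - p2) * n_hap_p2 / (n_hap_p2 - 1)
  } else rep(NA_real_, length(p2))

  dt <- data.table::data.table(
    win = floor(pos / width) + 1L, abba = w[, "abba"], baba = w[, "baba"],
    baaa = w[, "baaa"], abaa = w[, "abaa"], bbaa = w[, "bbaa"],
    informative = rowSums(w) > 0, fd_den = fd_den, het = het_p2
  )
  dt <- dt[win >= 1L & win <= n_win]
  agg <- dt[, .(n_sites = .N, n_informative = sum(informative),
                abba = sum(abba), baba = sum(baba), baaa = sum(baaa),
                abaa = sum(abaa), bbaa = sum(bbaa), fd_den = sum(fd_den),
                het = sum(het)), by = win]
  grid <- data.table::data.table(win = seq_len(n_win))
  out <- agg[grid, on = "win"]
  for (col in c("n_sites", "n_informative", "abba", "baba", "baaa", "abaa",
                "bbaa", "fd_den", "het")) {
    data.table::set(out, which(is.na(out[[col]]) &
                                 col != "het"), col, 0)
  }
  out[is.na(het), het := if (n_hap_p2 >= 2) 0 else NA_real_]

  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out[, d := ratio(abba - baba, abba + baba)]
  out[, d_plus := ratio((abba - baba) + (baaa - abaa),
                        (abba + baba) + (baaa + abaa))]
  out[, d_ancestral := ratio(baaa - abaa, baaa + abaa)]
  out[, f_hat_d := ifelse(!is.na(d) & d > 0, ratio(abba - baba, fd_den),
                          NA_real_)]
  out[, d_f := ratio(abba - baba, abba + baba + 2 * bbaa)]
  out[, pi_p2 := het / width]
  out[, `:=`(chrom = chrom, start = (win - 1L) * width, end = win * width,
             fd_den = NULL, het = NULL)]
  data.table::setcolorder(out, c("chrom", "start", "end", "win", "n_sites",
                                 "n_informative", "abba", "baba", "baaa",
                                 "abaa", "bbaa", "d", "d_plus", "d_ancestral",
                                 "f_hat_d", "d_f", "pi_p2"))
  if (drop_edges && nrow(out) > 2L) out <- out[-c(1L, .N)]
  out[]
}

#' Genome scan over a VCF
#'
#' Runs [window_scan()] per chromosome on a polarized quartet loaded with
#' [read_vcf_quartet()]. In empirical mode the first and last window of every
#' chromosome are discarded.
#'
#' @param sites A `dplus_sites` object (or a VCF path, in which case `pop_map`
#'   and `ancestral` are forwarded to [read_vcf_quartet()]).
#' @param pop_map,ancestral See [read_vcf_quartet()].
#' @param width Window width in bp.
#' @param drop_edges Discard first/last window per chromosome (default TRUE,
#'   the empirical-scan convention).
#' @return A `data.table` of per-window statistics for all chromosomes, with a
#'   `provenance` attribute recording the polarization mode and inputs.
#' @export
scan_vcf <- function(sites, pop_map = NULL, ancestral = "outgroup",
                     width = 50000L, drop_edges = TRUE) {
  if (is.character(sites)) {
    sites <- read_vcf_quartet(sites, pop_map, ancestral)
  }
  stopifnot(inherits(sites, "dplus_sites"))
  chroms <- unique(sites$chrom)
  out <- data.table::rbindlist(lapply(chroms, function(ch) {
    idx <- sites$chrom == ch
    window_scan(sites$pos[idx], sites$freq[idx, , drop = FALSE], width = width,
                chrom = ch, drop_edges = drop_edges,
                n_hap_p2 = sites$n_hap[["P2"]])
  }))
  data.table::setattr(out, "provenance",
                      list(ancestral = ancestral, width = width,
                           n_hap = sites$n_hap, skipped = sites$skipped))
  out
}

#' Empirical significance threshold from a null distribution
#'
#' The `(1 - p/2)` quantile (linear interpolation between order statistics) of
#' the supplied defined statistic values: the upper-tail cutoff such that the
#' top `p/2` fraction of the null signals P3 -> P2 gene flow at nominal
#' p-value `p`. A window is called significant when its value is greater than
#' or equal to the threshold (ties at a discrete threshold such as D = 1 count
#' as significant).
#'
#' @param values Defined statistic values (NAs are dropped).
#' @param p Nominal p-value in (0, 1).
#' @param lower Return the symmetric lower-tail (`p/2` quantile) threshold
#'   instead, for the P3 -> P1 direction.
#' @return The threshold value.
#' @export
empirical_threshold <- function(values, p, lower = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no defined values supplied")
  if (!(p > 0 && p < 1)) stop("p must lie in (0, 1)")
  q <- if (lower) p / 2 else 1 - p / 2
  stats::quantile(values, q, type = 7, names = FALSE)
}

#' Significance calls against a threshold
#'
#' @param values Statistic values (NA = undefined, never significant).
#' @param threshold Threshold from [empirical_threshold()].
#' @return Logical vector; `TRUE` where `values >= threshold`.
#' @export
is_significant <- function(values, threshold) {
  !is.na(values) & values >= threshold
}

#' Two-sided false-positive-rate curve of a null distribution
#'
#' For each nominal p-value, the fraction of null windows called significant
#' in either direction (value at or above the upper `1 - p/2` quantile, or at
#' or below the lower `p/2` quantile). For a well-behaved statistic this
#' tracks the nominal p-value; for a statistic with point masses at the
#' extremes (D at +-1) it plateaus at the total tail mass.
#'
#' @param values Defined null statistic values.
#' @param p_grid Nominal p-values (default 0.01 to 1 in steps of 0.01;
#'   values of exactly 1 are evaluated at 0.999).
#' @return A `data.table` with `p`, `threshold_lo`, `threshold_hi`, `fpr`.
#' @export
fpr_curve <- function(values, p_grid = seq(0.01, 1, by = 0.01)) {
  values <- values[!is.na(values)]
  data.table::rbindlist(lapply(p_grid, function(p) {
    pe <- min(p, 0.999)
    hi <- empirical_threshold(values, pe)
    lo <- empirical_threshold(values, pe, lower = TRUE)
    data.table::data.table(p = p, threshold_lo = lo, threshold_hi = hi,
                           fpr = mean(values >= hi | values <= lo))
  }))
}

#' Combine per-haplotype window values by their maximum
#'
#' For a diploid P2 individual scanned one phased chromosome at a time, the
#' per-window statistic is the maximum of the two values; an undefined value
#' is ignored, and the result is undefined only when both are.
#'
#' @param v1,v2 Numeric vectors of per-window values (NA = undefined).
#' @return Elementwise maximum of the defined values.
#' @export
max_over_haplotypes <- function(v1, v2) {
  out <- pmax(v1, v2, na.rm = TRUE)
  out[is.na(v1) & is.na(v2)] <- NA_real_
  out
}

#' Collapse diploid genotypes to one random haplotype per sample
#'
#' For unphased or phase-uncertain data: at every site, one of the two alleles
#' of each sample is chosen uniformly at random, producing a haploid
#' pseudo-genome per sample (the standard recourse for e.g. archaic samples).
#' Deterministic given the seed.
#'
#' @param allele1,allele2 Matrices (sites x samples) of the two allele dosages.
#' @param seed Integer seed.
#' @return A matrix of the same shape with one allele chosen per entry.
#' @export
random_haplotype_collapse <- function(allele1, allele2, seed) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  stopifnot(identical(dim(allele1), dim(allele2)))
  set.seed(seed)
  pick2 <- matrix(stats::runif(length(allele1)) < 0.5, nrow(allele1))
  out <- allele1
  out[pick2] <- allele2[pick2]
  out
}

#' Write a scan table (TSV) and significant windows (BED)
#'
#' The TSV carries `#`-prefixed provenance lines (configuration and seed) so a
#' run is reproducible from its output alone.
#'
#' @param scan A window table from [scan_vcf()] or [window_scan()].
#' @param path Output TSV path.
#' @param config Optional named list recorded in the header.
#' @export
write_scan_table <- function(scan, path, config = NULL) {
  hdr <- c(sprintf("# dplus scan (%s)", format(Sys.time(), "%Y-%m-%d")),
           if (!is.null(config)) {
             sprintf("# %s = %s", names(config),
                     vapply(config, function(x) paste(x, collapse = ","), ""))
           })
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(scan, path, sep = "\t", append = TRUE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_scan_table
#' @param stat Statistic column to threshold for the BED output.
#' @param threshold Significance threshold.
#' @export
write_significant_bed <- function(scan, stat, threshold, path) {
  sig <- scan[is_significant(scan[[stat]], threshold)]
  lines <- paste(sig$chrom, format(sig$start, scientific = FALSE),
                 format(sig$end, scientific = FALSE),
                 sprintf("%s=%.6g", stat, sig[[stat]]), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
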
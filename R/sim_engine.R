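#' Simulate recombining genomes under the IUA demography
#'
#' Thin adapter around the msprime coalescent engine (run through the `python`
#' interpreter on the PATH): the demography, sample configuration and
#' per-replicate seeds go in; polarized sites (the ancestral state is known
#' from the simulation, so haplotypes are 0/1 derived-allele vectors) and the
#' exact introgressed tracts carried by each sampled P2 haplotype come out.
#' Tracts are recovered from the engine's migration records and merged per
#' haplotype, so truth labels for the benchmark are exact, not inferred.
#'
#' @param demog An [iua_demography()]; `demog$sample_times` (generations) is
#'   forwarded to the engine.
#' @param n_reps Number of independent replicate genomes.
#' @param length Genome length in bp.
#' @param samples Named integer vector of haploid sample counts per population,
#'   e.g. `c(P1 = 1, P2 = 1, P3 = 1, P4 = 0)`.
#' @param seed Integer seed; per-replicate engine seeds are drawn from it and
#'   recorded in the result, so the same seed reproduces every site and tract.
#' @param python Python interpreter to use (default: `python` on the PATH).
#' @return An object of class `iua_sim`: a list with `replicates` (each a list
#'   with `pos`, `geno` 0/1 matrix with population-labelled columns, and
#'   `tracts` with columns `hap`, `left`, `right`), plus `length`, `samples`,
#'   `demog` and the seed table.
#' @export
simulate_iua_replicates <- function(demog, n_reps, length,
                                    samples = c(P1 = 1, P2 = 1, P3 = 1, P4 = 0),
                                    seed, python = NULL) {
  stopifnot(n_reps >= 1, length > 0)
  if (is.null(python)) python <- Sys.which("python")
  if (!nzchar(python)) {
    stop("no 'python' interpreter found on the PATH; the coalescent engine ",
         "(msprime) is required for genome simulation")
  }
  script <- system.file("python", "iua_sim.py", package = "dplus")
  if (!nzchar(script)) stop("bundled engine adapter script not found")

  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_reps),
                  ncol = 2L)
  gen <- event_times(demog, "generations")
  cfg <- list(
    ne = demog$n_e, mu = demog$mu, rec = demog$rec, f = demog$f,
    t_gf = gen[["t_gf"]], t_p2 = gen[["t_p2"]], t_p3 = gen[["t_p3"]],
    t_p4 = gen[["t_p4"]], length = length,
    samples = as.list(samples),
    sample_times = as.list(stats::setNames(demog$sample_times,
                                           c("P1", "P2", "P3", "P4"))),
    replicates = lapply(seq_len(n_reps), function(i) {
      list(id = i, anc_seed = seeds[i, 1], mut_seed = seeds[i, 2])
    })
  )
  dir <- tempfile("iua_sim_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)

  status <- system2(python, c(shQuote(script), shQuote(cfg_path), shQuote(dir)),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop("coalescent engine run failed (exit status ", status, ")")
  }

  reps <- lapply(seq_len(n_reps), function(i) {
    sites <- data.table::fread(file.path(dir, sprintf("sites_%d.tsv", i)))
    tracts <- data.table::fread(file.path(dir, sprintf("tracts_%d.tsv", i)))
    geno <- as.matrix(sites[, -1])
    storage.mode(geno) <- "integer"
    list(pos = sites$pos, geno = geno, tracts = tracts)
  })
  structure(list(replicates = reps, length = length, samples = samples,
                 demog = demog, seed = seed, engine_seeds = seeds),
            class = "iua_sim")
}

#' @rdname simulate_iua_replicates
#' @description `simulate_genome()` is the single-replicate convenience form;
#'   it returns one replicate's sites and tracts directly.
#' @export
simulate_genome <- function(demog, length,
                            samples = c(P1 = 1, P2 = 1, P3 = 1, P4 = 0),
                            seed, python = NULL) {
  sim <- simulate_iua_replicates(demog, 1L, length, samples, seed, python)
  sim$replicates[[1]]
}

#' @export
print.iua_sim <- function(x, ...) {
  cat(sprintf("IUA simulation: %d replicate(s) of %g bp, f = %g, seed = %d\n",
              length(x$replicates), x$length, x$demog$f, x$seed))
  cat("  samples:", paste(names(x$samples), x$samples, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Export a simulated replicate as VCF plus population map
#'
#' Writes a minimal VCF 4.2 file (haploid GT fields, one pseudo-sample per
#' simulated haplotype, REF = ancestral `A`, ALT = derived `T`, and an `AA`
#' INFO ancestral-allele annotation) so that simulated data can exercise the
#' same VCF scan path as empirical data. Infinite-sites float positions are
#' floored to integer bp; the rare collisions are dropped.
#'
#' @param rep One replicate from [simulate_iua_replicates()].
#' @param vcf_path,pop_map_path Output paths.
#' @param chrom Chromosome name to write.
#' @return Invisibly, the VCF path.
#' @export
write_sim_vcf <- function(rep, vcf_path, pop_map_path = NULL, chrom = "sim1") {
  pos <- floor(rep$pos) + 1L  # 1-based integer bp
  keep <- !duplicated(pos)
  pos <- pos[keep]
  geno <- rep$geno[keep, , drop = FALSE]
  samples <- colnames(geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dplus simulated IUA genome (synthetic data)",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(chrom, pos, ".", "A", "T", ".", "PASS", "AA=A", "GT",
                sep = "\t")
  gt <- apply(geno, 1, paste, collapse = "\t")
  writeLines(c(header, paste(body, gt, sep = "\t")), vcf_path)
  if (!is.null(pop_map_path)) {
    writeLines(paste(samples, sub("_.*$", "", samples), sep = "\t"),
               pop_map_path)
  }
  invisible(vcf_path)
}

#' Write introgressed tracts as BED-like text
#'
#' Columns: chrom, start, end, carrier haplotype id(s) (comma separated).
#'
#' @param tracts A data.table with `hap`, `left`, `right` (or `carriers`).
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_tracts_bed <- function(tracts, path, chrom = "sim1") {
  carriers <- if ("carriers" %in% names(tracts)) {
    vapply(tracts$carriers, paste, "", collapse = ",")
  } else {
    as.character(tracts$hap)
  }
  lines <- paste(chrom,
                 trimws(format(floor(tracts$left), scientific = FALSE)),
                 trimws(format(ceiling(tracts$right), scientific = FALSE)),
                 carriers, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
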
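# dplus: windowed D+ statistics for detecting local introgression

`dplus` detects *local* introgression — gene flow confined to particular
genomic windows — between populations arranged as a four-taxon quartet
`(((P1, P2), P3), P4)`: two sister populations, a candidate donor (P3), and an
outgroup (P4) used to orient ancestral vs derived alleles. It is aimed at
population geneticists who already run ABBA–BABA scans and want a statistic
that behaves sensibly in small windows.

## The statistics

Patterson's D measures the excess of ABBA sites (derived allele shared by P2
and P3) over BABA sites (shared by P1 and P3):

    D = Σ (ABBA − BABA) / Σ (ABBA + BABA)

D is reliable genome-wide but erratic in small windows: low-diversity windows
contain one or two informative sites, so D collapses onto ±1 and its
window-level null distribution carries large point masses at the extremes
(≈ 43% of 50 kb windows under a human/Neanderthal-like null). D+ adds the
*ancestral-sharing* patterns — introgressed tracts also re-introduce ancestral
alleles, making BAAA sites (derived private to P1) outnumber ABAA sites under
P3 → P2 flow:

    D+ = Σ (ABBA − BABA) + (BAAA − ABAA) / Σ (ABBA + BABA) + (BAAA + ABAA)

External-branch mutations are 5–6× as common as internal-branch ones, so D+
sees several times more informative sites per window; its null is unimodal
around zero (SD ≈ 0.26 vs ≈ 0.74 for D at 50 kb), which buys much better
precision at similar power. The package also computes `D_ancestral`
(ancestral patterns only), the admixture-proportion estimators `f_hat_d` and
`d_f`, and nucleotide diversity π, all per window, from either single
haplotypes or derived-allele frequencies.

Alongside the scan, the package provides the analytical theory for the
instantaneous-unidirectional-admixture (IUA) model — closed-form expected
branch lengths obeying `E[T_ABBA − T_BABA] = E[T_BAAA − T_ABAA] =
f·(T_P3 − T_GF)`, with a Monte-Carlo single-locus sampler as an independent
check — and a simulation benchmark (precision / recall / false-positive rate
against exact introgressed-tract truth) driven by the msprime coalescent
engine through a bundled Python adapter.

## Worked example

A small simulated quartet VCF ships with the package (synthetic data: 200 kb,
one haplotype for P1–P3, two outgroup haplotypes, an admixture pulse of
f = 0.2, with the true introgressed tracts in the accompanying BED):

```r
library(dplus)
vcf <- system.file("extdata", "sim_quartet.vcf", package = "dplus")
pops <- system.file("extdata", "sim_quartet.pop_map.tsv", package = "dplus")
scan <- scan_vcf(vcf, pops, ancestral = "info:AA", width = 25000L,
                 drop_edges = FALSE)
scan[, .(start, end, n_informative, d, d_plus, d_ancestral)]
#>     start    end n_informative     d     d_plus d_ancestral
#> 1:      0  25000            12    NA -0.2000000  -0.2000000
#> 2:  25000  50000            28     1  0.3191489   0.2380952
#> 3:  50000  75000            15     1  0.4545455   0.3333333
#> 4:  75000 100000            12    NA  0.3333333   0.3333333
#> 5: 100000 125000            15     1  0.3846154   0.3333333
#> 6: 125000 150000            16    NA -0.5000000  -0.5000000
#> 7: 150000 175000            13    NA -0.3333333  -0.3333333
```

The true tract spans 31.9–65.9 kb: windows 2–3 carry it and show strong
positive D+. Note the behaviour of D — undefined (`NA`) in four of seven
windows because no ABBA/BABA site exists there, and pinned to exactly 1 in
window 5, which carries *no* tract: that is the false-positive mode D+ was
designed to avoid. Significance would be assessed against an empirical null
with `empirical_threshold()`; windows at or above the threshold are flagged.

The analytical side, under the benchmark human/Neanderthal-style demography
(Ne = 10,000; splits 4,000 / 16,000 generations; pulse at 1,600 generations):

```r
demog <- iua_benchmark_demography(f = 0.03)
expected_branch_lengths(demog)   # coalescent units of 2N generations
#>  e_t_abba  e_t_baba  e_t_baaa  e_t_abaa
#> 0.2039166 0.1823166 1.0356834 1.0140834
expected_d_plus(demog)
#> [1] 0.01773399
single_locus_sampler(demog, 1e5, seed = 1)$branch_means
#>    t_abba    t_baba    t_baaa    t_abaa
#> 0.2064720 0.1835569 1.0379495 1.0150343
```

Both pattern contrasts equal f·(t_P3 − t_GF) = 0.0216 in 2N units, and the
Monte-Carlo sampler agrees with the closed forms within Monte-Carlo error.

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/dplus.R", package = "dplus"))') \
    scan --vcf data.vcf --pop-map pops.tsv --ancestral info:AA \
    --window 50000 --pvalue 0.05 --out my_scan
```

with `benchmark`, `theory` and `fixtures` subcommands for the simulation
study, the expectation tables, and synthetic test data.

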
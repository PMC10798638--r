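---
title: "Detecting local introgression with D+: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting local introgression with D+}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dplus)
```

## The problem and the statistics

Given four populations arranged as `(((P1, P2), P3), P4)` — two sister
populations, a candidate donor, and an outgroup used to orient alleles —
biallelic sites sampled across the quartet fall into patterns written as
strings over A (ancestral) and B (derived). Incomplete lineage sorting alone
produces, in expectation, as many ABBA sites (derived allele shared by P2 and
P3) as BABA sites (shared by P1 and P3); a pulse of gene flow from P3 into P2
creates an excess of ABBA. Patterson's D measures that excess,

$$D = \frac{\sum_i (\mathrm{ABBA}_i - \mathrm{BABA}_i)}
           {\sum_i (\mathrm{ABBA}_i + \mathrm{BABA}_i)}.$$

D works well genome-wide but is unstable in small windows: windows of low
diversity often contain a single informative site, so D lands exactly on
$\pm 1$ and its window-level null distribution has large point masses at the
extremes. The remedy implemented here is to add the *ancestral-sharing*
patterns. Introgressed chunks carry not only derived alleles that arose in the
donor but also re-introduce ancestral alleles into the recipient, so BAAA
sites (derived allele private to P1; P2 and P3 share the ancestral allele)
become more common than ABAA sites under P3 → P2 flow. D+ uses both contrasts:

$$D^+ = \frac{\sum_i (\mathrm{ABBA}_i - \mathrm{BABA}_i)
            + (\mathrm{BAAA}_i - \mathrm{ABAA}_i)}
            {\sum_i (\mathrm{ABBA}_i + \mathrm{BABA}_i)
            + (\mathrm{BAAA}_i + \mathrm{ABAA}_i)}.$$

Because external-branch mutations are much more common than internal-branch
ones (five- to six-fold under the demography below), D+ has several times more
informative sites per window than D, which removes the $\pm 1$ point masses
and shrinks the null spread while leaving the expected signal intact.
`D_ancestral` is the ancestral-only counterpart `(BAAA−ABAA)/(BAAA+ABAA)`.

With more than one haplotype per population, counts generalize to products of
derived-allele frequencies $p_1 \ldots p_4$: the ABBA weight is
$(1-p_1)p_2p_3(1-p_4)$ and so on (`pattern_weights()`). One code path serves
both cases because 0/1 haplotype "frequencies" reproduce the integer tallies
exactly. Two window-level admixture-proportion estimators from the same
weights are included for completeness: `f_hat_d` (denominator built from
$p_D = \max(p_2, p_3)$, only meaningful where D > 0) and `d_f`. The `d_f`
denominator is implemented exactly as printed in its source, with the BBAA
weight appearing once in each of its two groups — i.e. twice in total; we
deliberately preserve that printed form rather than second-guess it, and flag
it here because readers sometimes expect the BBAA term to enter once.

Sites where the outgroup itself carries the derived allele at frequency
$p_4 > 0$ are *down-weighted* by the factor $(1-p_4)$ rather than
hard-filtered; this follows the frequency form of the statistics literally.

## Polarization and windows

Two ancestral-state rules are implemented (`polarize_sites()`):

* `annotation` — an ancestral-allele annotation (VCF `AA` INFO key or a
  FASTA) decides; sites whose annotation matches neither allele are skipped.
* `outgroup-fixed-else-major` — the outgroup allele is ancestral where the
  outgroup is fixed; otherwise the major allele over all four populations is
  used, and exact ties are skipped.

Frequencies are computed over non-missing calls; a site with no calls in any
population is skipped (a least-surprise choice — the alternative of imputing
zeros would bias the weights).

Windows are non-overlapping, 0-based half-open intervals of fixed width
(50 kb for the human-style scans, 5 kb for the butterfly-style scans). A
trailing partial window is discarded, and in empirical scans the first and
last window of each chromosome are dropped as well. A statistic whose
denominator is zero in a window is **undefined** and is represented as `NA`,
never as zero: pooling zeros into a null distribution would badly distort its
quantiles. Undefined windows are excluded from null distributions and from
every performance denominator.

## Significance against an empirical null

Thresholds come from an empirical null distribution of per-window values
(simulated with the admixture pulse switched off, or the genome-wide
empirical distribution when no simulation is appropriate). For a nominal
p-value $p$ the upper threshold is the $1 - p/2$ quantile (type-7 linear
interpolation, fixed for reproducibility), and a window signals P3 → P2 flow
when its value is **at or above** the threshold. Ties matter here: the null
distribution of D has a point mass at exactly 1, so its upper quantile *is* 1
for every realistic $p$, and treating ties as non-significant would make D
incapable of calling any window — contradicting its published (and correctly
poor) precision. Counting ties as significant reproduces the study's
behaviour; this is deliberately different from a strict-inequality rule. The
symmetric lower-tail threshold (P3 → P1 direction) is available via
`empirical_threshold(..., lower = TRUE)`.

The false-positive-rate curve of a null (`fpr_curve()`) counts a call in
*either* direction as a false positive, which is why the FPR of D+ tracks the
nominal p-value while D's FPR plateaus at its total $\pm 1$ tail mass; the
directional precision/recall calls use the upper tail only.

For a diploid P2 individual scanned per phased chromosome, each window gets
two values and the working value is their maximum (`max_over_haplotypes()`;
an undefined value loses to any defined one). For unphased or ancient
samples, `random_haplotype_collapse()` picks one allele per site per sample,
deterministically given a seed.

## The IUA model and its expectations

All theory and simulation use the instantaneous-unidirectional-admixture
(IUA) model: constant diploid size $N_e$ everywhere, splits at `t_p2 < t_p3 <
t_p4`, and a single pulse moving a fraction `f` of P2's ancestry from P3 at
`t_gf`. The benchmark parameterization (`iua_benchmark_demography()`) mirrors
a human/Neanderthal-like history: $N_e = 10{,}000$, splits at 4,000 and
16,000 generations, pulse at 1,600 generations, $\mu = 1.5\times10^{-8}$ and
$r = 10^{-8}$ per bp per generation. Times are stored in coalescent units of
$2N$ generations with converters for generations and ms-style $4N$ units,
because both conventions are common in practice.

`expected_branch_lengths()` gives closed forms for the expected lengths of
the four branches on which a mutation produces each pattern. The derivation
conditions on the pulse (probability $f$ the P2 lineage is relocated into P3
at `t_gf`) and, within each arm, on whether the available pair coalesces
before `t_p3`; the three lineages that survive to `t_p3` form an
exchangeable block in which each pair is first to coalesce with probability
1/3. The forms satisfy, exactly,

$$E[T_{\mathrm{ABBA}}] - E[T_{\mathrm{BABA}}]
  = E[T_{\mathrm{BAAA}}] - E[T_{\mathrm{ABAA}}] = f\,(t_{P3} - t_{GF}),$$

so the ancestral contrast carries the same admixture signal as the derived
one. One simplification is deliberate: coalescence with the outgroup lineage
above `t_p4` is neglected, which introduces an error of order
$e^{-(t_{P4}-t_{P3})}$ in $2N$ units — about $e^{-39}$ at the benchmark
parameters. The independent check on the algebra is
`single_locus_sampler()`, an event-driven structured-coalescent simulation
(implemented in C++, seeded through R's RNG) that shares no code with the
closed forms and does include the outgroup phase; the test suite requires
agreement within three Monte-Carlo standard errors across
$f \in \{0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1\}$.

## The simulation benchmark

`simulate_iua_replicates()` delegates recombining-genome simulation to the
msprime coalescent engine through a small Python adapter (the engine runs as
a subprocess; all seeds are derived from one R seed and recorded). The
adapter returns infinite-sites positions with 0/1 derived-allele haplotypes —
polarization is exact because the simulation knows the ancestral state — and
the exact introgressed tracts of every sampled P2 haplotype, recovered from
the engine's migration records, intersected with the migrating segments and
merged per haplotype. Merging adjacent segments into maximal tracts matches
the biological notion of a tract; truth is therefore exact rather than
inferred.

Truth labels for windows follow two conventions:

* **Single haplotype** (`label_windows_n1()`): a window is introgressed when
  at least 10% of its bases overlap tracts; windows with positive overlap
  below 10% are *dropped* from all four confusion cells (they are neither
  clean positives nor clean negatives); windows with zero overlap are
  negatives. When two P2 chromosomes are scanned with the max convention, the
  overlap is computed on the union of the two haplotypes' tracts (the
  convention's source is silent on this point; the union is the natural
  reading of "bases of the window that are introgressed").
* **Population sample** (`label_windows_freq()`): a window is introgressed
  when it contains at least one tract carried by at least 10% of the sampled
  P2 chromosomes *and* the within-window lengths of such tracts sum to at
  least 10% of the window.

`performance()` reports precision = TP/(TP+FP) (= 1 − FDR), recall =
TP/(TP+FN) and FPR = FP/(FP+TN), each `NA` when its denominator is empty.
`performance_curve()` sweeps the p-value grid (0.01–1 in steps of 0.01 by
default) against a supplied null.

Molecular-clock violations are emulated by the divergence-shift construction
(`clock_violation_demography()`): to give one ingroup population a
$k$-fold-higher effective mutation input, all event times are shifted by
$(k-1)\,T_{P2}$ and the *sister* population is sampled at the shift, so the
target's terminal branch is $k$ times its sister's. The published
construction states the $k=2$ case; the $(k-1)T_{P2}$ generalization is the
unique linear extension and is verified in the tests by terminal-branch
ratios. P3 is sampled just after the shifted pulse time, as an archaic donor
would be. `inject_errors()` provides the simple per-site allele-flip model of
sequencing error.

## Scales, seeds and what the tests show

The packaged benchmark runs use cohorts of 30–60 replicates of 20 Mb with
50 kb windows (12,000–24,000 windows per cohort): 30 in the test suite, and
larger cohorts in `scripts/acceptance.R` where tighter Monte-Carlo error on
small percentages matters; the single-locus expectations use $10^5$ loci per
admixture proportion. At that scale the no-admixture null reproduces the
published spread of both statistics (SD ≈ 0.74 for D, ≈ 0.26 for D+, D tail
mass ≈ 43%) to within ±0.02, and the precision/recall comparisons are
resolved to a few percentage points (stochastic checks in the test suite use
replicate-level bootstrap standard errors rather than fixed tolerances).
Every stochastic component takes an explicit integer seed, and identical
seeds reproduce sites, tracts, samplers and error injection bit for bit.

The generator emulates neutral, constant-size, panmictic populations with a
single admixture pulse, uniform mutation and recombination rates, and exact
phasing and polarization. Real data violate most of these in some degree —
variable recombination, background selection, reference bias, imperfect
ancestral states — so passing benchmarks here demonstrate correctness of the
statistics and machinery under the stated model, not performance guarantees
on any particular empirical dataset. Expectations under richer demographies
(growth, bottlenecks, multiple pulses) are out of scope; the demography
object is deliberately minimal rather than a general demography DSL.

## Worked micro-example

```{r example}
# a window of three polarized sites observed in single haplotypes
freqs <- rbind(c(0, 1, 1, 0),   # ABBA
               c(1, 0, 0, 0),   # BAAA
               c(1, 0, 0, 0))   # BAAA
counts <- accumulate_window(freqs)
compute_d(counts)        # 1: only one D-informative site
compute_d_plus(counts)   # 1: three informative sites agree
compute_d_ancestral(counts)

# closed-form expectations under the benchmark demography
demog <- iua_benchmark_demography(f = 0.03)
expected_branch_lengths(demog)
expected_d_plus(demog)
```
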
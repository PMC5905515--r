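---
title: "Methods: sliding-window sweep scanning and its validation stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window sweep scanning and its validation stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sweepscan` implements a complete desk-scale pipeline for detecting and
validating selective sweeps from multi-population SNP genotype cohorts, of the
kind produced by whole-genome resequencing of livestock breeds. This vignette
is the package's own account of the statistics it computes, the decisions
taken where the methodology was genuinely open, and what its synthetic-data
validation does and does not demonstrate.

## The scan statistics

The genome is tiled with 30-kb windows advancing in 15-kb steps (both
configurable). Windows are 0-based half-open internally; all reports are
1-based inclusive. Two statistics drive sweep calling, computed per window for
a target population against a reference pool:

**Population differentiation.** Window F~ST~ uses the Weir–Cockerham (1984)
estimator: per-site variance components $a$ (between populations), $b$
(between individuals within populations) and $c$ (within individuals) are
accumulated over all usable sites in the window and
$\hat\theta = \sum a / \sum (a+b+c)$ — the *ratio of averages*, the standard
aggregation for window scans because it weights sites by their information
content. The alternative (averaging per-site ratios) is noisier at low-MAF
sites; sensitivity to this choice is confined to windows dominated by rare
variants. Raw estimates can be slightly negative in undifferentiated data;
the raw value is retained internally (and used for genome means) while the
reported value is clamped to $[0, 1]$.

**Pooled heterozygosity.** For a window,
$$H_P = \frac{2\,\Sigma p\,\Sigma q}{(\Sigma p + \Sigma q)^2},$$
where $\Sigma p$ and $\Sigma q$ sum the major- and minor-allele frequencies of
*all* cohort SNP sites in the window, with major/minor assigned per site
within the population being scored (the statistic is population-specific).
$H_P \in [0, 0.5]$, maximal when $\Sigma p = \Sigma q$. Heterozygosity loss in
the target is measured as $\log_2(H_{P|\mathrm{ref}} / H_{P|\mathrm{target}})$;
positive values mean diversity loss in the target. A zero target $H_P$ yields
an infinite-loss sentinel (`+Inf`) that exceeds any finite threshold rather
than a pseudocount — we prefer an explicit sentinel over inventing a smoothing
constant.

Windows with fewer than 50 cohort variants are *flagged* excluded (never
silently dropped): they do not enter threshold computation and cannot be
called. Truncated terminal windows are tiled like any other and usually fall
to this rule. Diversity statistics (π per bp, Watterson's θ per bp, Tajima's
D with the conventional 1989 constants, SNP density) are computed for the
target population; the chromosome count for θ and D is taken as twice the
population size, with per-site non-missing counts used inside π — exact for
complete genotype matrices (which the simulator emits) and a mild
approximation under missingness.

## Sweep calling, regions and candidate genes

For each statistic independently, the cutoff is the smallest value among the
$\lceil 0.05 N \rceil$ highest-ranked non-excluded windows (top 5% by rank;
the quantile is configurable). A window is called when it meets **both**
cutoffs; "over the threshold" is implemented as `>=` with boundary ties
included, since a rank-based rule with explicit tie handling is reproducible
where a strict `>` on an interpolated quantile is not. The genome-scale
difference is at most the tie set.

Called windows that overlap or book-end are merged into maximal regions;
15-kb flanks are applied to the *merged region* (not to each window) and
clipped to the chromosome. Any annotated gene overlapping a flanked region by
at least 1 bp is a candidate gene. Overlaps of candidate sets across several
target populations are reported as an exact Venn partition, whose counts sum
to the union size by construction.

## Population-structure and linkage utilities

Pairwise genome-wide F~ST~ (negatives clamped to 0) feeds a Saitou–Nei
neighbor-joining tree via `ape::nj`, serialized to Newick. Allele-sharing
distances between samples count allele differences over sites non-missing in
both. Genotype PCA follows the EIGENSOFT convention: per-site mean centering,
scaling by $\sqrt{\hat p (1-\hat p)}$, per-site mean imputation of missing
dosages, then an eigendecomposition of the sample covariance; each
component's sign is fixed by making its largest-magnitude coordinate
positive.

Two-locus haplotype frequencies are estimated from unphased 3×3 genotype
count tables by EM over the double-heterozygote phase ambiguity
(initialization at linkage equilibrium; convergence when the largest
frequency change falls below 1e-10 or after 1000 iterations; the
observed-data log-likelihood is asserted non-decreasing). From the estimated
frequencies, $D = f_{AB} - p_A p_B$, $D' = |D|/D_{\max}$ and
$r^2 = D^2/(p_A q_A p_B q_B)$. $r^2$ between genotype columns is always
derived from EM haplotype frequencies (Haploview semantics); the composite-LD
shortcut was rejected to keep one definition throughout. LD decay averages
$r^2$ within physical-distance bins after MAF ≥ 0.1 and per-site missingness
≤ 0.2 filters, with seeded subsampling of pairs for desk-scale control; empty
bins are reported missing, not zero. LD pruning mimics the 50-SNP/5-SNP/0.2
sliding rule; when a pair exceeds the cutoff the *later-position* member is
removed (the upstream tools leave this unspecified; our rule is deterministic
and makes the pruned set a fixed point).

## Association testing

Genotypes are coded relative to the cohort's major allele A: additive
(AA/Aa/aa → 2/1/0), recessive (1/0/0) and dominant (1/1/0). Ties in the
major-allele count are broken by the reference allele when known. Horn size
(length in cm, polled = 0) is analyzed by ordinary least squares with
optional age (years) and sex (male indicator) covariates, listwise deletion,
and a two-sided t-test on the genotype coefficient. Horn shape contrasts
SHE-type (spiral, horizontally extended) against TCF-type (tightly close to
the face) by maximum-likelihood logistic regression (IRLS, tolerance 1e-8,
at most 50 iterations); polled, scurred and uncertain animals are excluded
from the shape contrast. Complete separation is detected (diverging linear
predictor or the fitter's own numeric warning) and flagged as an error with
no estimate, rather than reporting a meaningless coefficient. The full
SNP × model × outcome grid records per-fit failures — e.g. a dominant coding
with no minor-allele homozygotes is constant and is skipped with a reason —
and appends a Benjamini–Hochberg column per outcome as a clearly optional
extra (primary p-values are raw).

## Relative expression

Technical replicates are averaged first; per sample
$\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{control}$; then
$\Delta\Delta Ct$ subtracts the calibrator's $\Delta Ct$ and
$\mathrm{rel} = 2^{-\Delta\Delta Ct}$. The calibrator may be a single sample
(whose relative expression is then exactly 1) or a group, in which case the
group's *mean* $\Delta Ct$ is used — the group's geometric-mean fold change
becomes 1. Group differences use Welch's unequal-variance t-test on the
$2^{-\Delta\Delta Ct}$ scale (the scale of the reported quantity; both
choices are configurable), and expression–phenotype association uses Pearson
correlation with a two-sided t-test and a least-squares trend line.

## The synthetic cohort generator

Every stage is exercised on seeded synthetic cohorts, so no external download
is needed.

**Genotypes.** The Balding–Nichols model: per site an ancestral frequency
$p_0$ is drawn, each population's frequency comes from
$\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$, and
genotypes are $\mathrm{Binomial}(2, \cdot)$. This model was chosen over a
coalescent simulator because its parameter $F$ *equals* the expected
Weir–Cockerham F~ST~, giving an analytic recovery target, and because the
window frequency statistics need no linkage realism (LD-dependent routines
are tested on explicitly constructed duplicated/shuffled columns instead).
The ancestral spectrum defaults to density $\propto 1/p$ on
$[0.001, 0.999]$: integrated against binomial sampling this reproduces the
neutral $1/i$ sample frequency spectrum exactly, so π ≈ θ and Tajima's D
centers on zero in neutral cohorts — the property the diversity statistics
are validated against. A uniform spectrum is available for stress tests.
Cohort-monomorphic draws are discarded (a variant file contains variants) and
sites are thinned back to the requested count.

**Sweeps.** Injection redraws the target population's derived-allele
frequencies inside the interval tightly around a post-sweep frequency
(default 0.98, Beta with concentration 200), aligned to one haplotype
direction, and resamples its genotypes; other populations are untouched. This
produces the two signatures the scan keys on — excess differentiation and
heterozygosity loss — without modelling haplotype tracts, which only
haplotype-length statistics (out of scope) would need. Recovery guarantees in
the tests assume intervals aligned to the window grid.

**Annotation.** Genes are tiled deterministically, and each sweep spec plants
three markers: one inside the interval, one just downstream within a 15-kb
flank, and one 80 kb downstream — beyond any flank a called region can
acquire — so candidate-gene assignment can be checked for both inclusion and
exclusion.

**Phenotypes.** A cohort of 182 animals (the scale of the field cohort the
association stage is designed for) draws causal-SNP genotypes at a
derived-allele frequency of 0.8 — a mid-range value typical of a field
population segregating for the trait, deliberately *not* the near-fixed
frequency of the swept pool, where the additive code would carry almost no
variance. Horn length is intercept (18 cm) + 11.75 cm per derived allele +
0.8 cm/year of age + 4 cm for males + Normal(0, 8 cm) noise, left-censored at
0 (polled). The intercept was set so that censoring affects about 1% of
animals: the generator keeps the polled category while the additive effect
remains identifiable; consequently polled/scurred animals are rarer here than
in a real cohort. Shape for long-horned animals follows a logistic model on
the derived-homozygote indicator (log-odds 3 over an intercept of −1.2),
mirroring the overrepresentation of derived homozygotes among spiral-horned
animals; categories respect the length bands (polled 0; scurred ≤ 12 cm;
otherwise SHE/TCF with a 2% uncertain rate).

**Ct tables.** The 4 SHE / 4 TCF / 5 scurred design with true group ΔCt of
4 / 2 / 2.3 cycles (target gene lower in SHE), control Ct ~ Normal(20, 0.2),
biological noise 0.3 and replicate noise 0.1 cycles, technical triplicates.
With all noise set to zero the ΔΔCt arithmetic recovers the configured fold
changes exactly — the identity the expression stage is validated against.

## Problem sizes and what the tests show

The validation suite runs at desk scale: the end-to-end scan uses a 15-Mb
two-chromosome genome (about 1000 windows, 45 000 SNPs, 10 target + 25
reference samples) with three planted 90-kb sweeps; differentiation recovery
uses 2000 sites and 50 diploids per population; association properties use
200 effect-recovery seeds and 2000 null replicates at n = 182; EM estimates
are checked against a 0.001-grid likelihood search on 100 random tables.
These sizes were chosen so the full suite completes in well under a minute
while keeping every stochastic band comfortably away from its boundary.

Passing tests demonstrate internal correctness of the estimators and the
calling logic under the generator's assumptions — independent sites, HWE
within populations, frequency-level sweep signatures. They do not demonstrate
robustness to properties of real resequencing data that the generator omits:
linkage blocks (which inflate the variance of window statistics and make
neighboring windows dependent), variant-calling artifacts and depth-dependent
missingness, admixed or related individuals, or ascertainment of the SNP
panel. Thresholds on real cohorts should therefore be read as empirical
genome-wide ranks, exactly as the scan defines them, not as calibrated
significance levels.

## Known limitations

- Window F~ST~ assumes two populations per comparison; multi-way scans are
  run as repeated target-vs-reference comparisons, each with its own
  genome-wide thresholds.
- θ and Tajima's D use the full population chromosome count; under heavy
  missingness they drift from their per-site-count analogues.
- The logistic separation heuristic (|linear predictor| > 20) is
  deliberately conservative; borderline-separated designs are reported as
  errors rather than as unstable estimates.
- The simulator's sweep injection acts on frequencies, not haplotypes, so
  haplotype-based statistics cannot be validated against it.
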
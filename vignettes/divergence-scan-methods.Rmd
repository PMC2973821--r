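---
title: "Methods: scanning divergently selected genomes and simulating the breeding scheme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning divergently selected genomes and simulating the breeding scheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divselscan)
```

`divselscan` analyses the genomic footprint of long-term divergent
selection: two lines bred from one base population, genotyped at many SNPs
at two timepoints per line. This vignette is the package's own account of
the models it implements, the parameters that matter, and the choices made
where the methods literature leaves the design open.

## The experimental setting and its data model

The motivating design is a pedigreed single-trait selection experiment: a
base population formed by crossing seven partially inbred founder lines
(so founder haplotype frequencies are multiples of 1/7), split into a
high and a low line, each propagated by selecting 12 sires and 48 dams per
generation with 6 offspring per dam (census 288). SNP panels are sampled
from both lines at generations 40 (20 + 20 birds) and 50 (49 high +
10 low, the asymmetry reflecting the low line's phenotypic plateau).

Genotypes are stored as dosages of a declared per-SNP reference allele
(`genotype_panel`), with the marker map (`marker_map`) carrying 1-based bp
positions, per-chromosome cM/Mb ratios, and the allele codes. I/O uses the
PLINK-style PED/MAP text dialect plus TSV sidecars for sample labels,
chromosome ratios and allele codes, so files are readable by standard
tools while dosage orientation stays well defined across files. Missing
calls are excluded per SNP from every denominator; a SNP counts as fixed
in a group only if at least one call is non-missing and all non-missing
calls are homozygous for the same allele. The Z chromosome is treated like
the autosomes (no dosage correction), only lacking a cM/Mb ratio, in which
case map lengths are reported as missing.

## Divergence scans

The line-contrast statistic is the 1-df Pearson χ² on the 2×2 table of
allele counts in two groups, **without** Yates continuity correction. The
uncorrected statistic has the property that complete fixation for
alternative alleles gives χ² equal to the table's total allele count
(`allelic_chi2(group_allele_counts(40, 0, 0, 40))` → 80 for 20 vs 20
diploids; 118 for 49 vs 10), which is the natural "ceiling" used to
normalise scans from different sample sizes onto one scale
(`sliding_window_mean(..., normalize = 80)`). A two-sided Fisher exact
test is available for tables with small expected counts; SNPs monomorphic
in the pooled groups carry no information and are excluded both from
testing and from the Bonferroni denominator, which is recomputed per
comparison as the number of testable SNPs. Bonferroni levels default to
0.05 and 0.001.

Within-line change between timepoints uses |Δp| per SNP (same reference
allele at both generations), averaged over non-overlapping blocks of 5
consecutive SNPs. Blocks never span chromosomes and trailing partial
blocks are dropped. A block is an outlier if its mean lies strictly above
the genome-wide empirical 95th percentile (type-7 linear interpolation;
ties at the threshold count as non-outliers, so at most 5% of blocks can
be flagged). Under independence the number of outliers among 20 blocks is
Poisson with mean 1, and a window is called significant when its count
reaches the smallest k with P(Poisson(1) ≥ k) ≤ 10⁻⁵, which is k* = 9
(`poisson_window_threshold`). Windows slide by one block and are bounded
within chromosomes; whether windows should cross chromosome ends is not
prescribed anywhere, and bounding them is the conservative choice since a
sweep cannot span two chromosomes.

Observed heterozygosity H_o per SNP is the fraction of heterozygous
non-missing calls; `heterozygosity_decline` compares the per-locus
decrease between generations across lines with a two-sample two-sided
t-test. If the decreases are constant in both lines the test statistic is
degenerate; the function then warns and returns no test rather than a
fabricated p-value.

## Sweep clusters and haplotype persistence

SNPs fixed for alternative alleles (class `DIFF` from
`classify_fixation`) are clustered per chromosome into maximal runs with
at most 1 Mb (configurable) between subsequent fixed SNPs; clusters
require ≥ 2 SNPs by default, or ≥ 5 under the stringent criterion. Cluster
length is `last_bp − first_bp` (so a 2-SNP cluster has a positive,
marker-delimited length), converted to cM with the chromosome's single
cM/Mb ratio — a deliberate simplification: no local recombination map is
assumed. The "fraction of genome covered" denominator is the
marker-spanned genome (per-chromosome max − min marker position), which is
the only genome the chip can see.

Whether a cluster of a given map length could plausibly have stayed intact
through a sweep is quantified by the persistence probability
$$P = \left((1-r) + r\,(p^2+q^2)\right)^{2Ng},$$
where r is the recombination fraction across the cluster (from Haldane's
map function, r = ½(1 − e^(−2d/100)) with d in cM), p and q = 1 − p the
swept/background haplotype frequencies, N the effective population size
and g the generations to fixation: each of the 2Ng transmitted gametes
must either not recombine, or recombine in a homozygote where the exchange
is invisible. The default N = 36.21 is the through-generation-50
harmonic-mean effective size of the motivating experiment — the value that
reproduces the published persistence probabilities to their printed
precision — and is configurable because it is experiment-specific.

## The forward simulator

`run_replicates` is an individual-based two-locus simulator of one
selected line. Locus A carries the selection (viability-style fitnesses 1,
1 − hs, 1 − s for AA/Aa/aa, additive by default h = 0.5), locus B is a
linked neutral marker at recombination fraction r. Because selection
intensities differ between the sexes, there is a male and a female
selection coefficient. Founders are drawn i.i.d. from a four-digit
sevenths code ("4003" = 4/7 AB, 3/7 ab), sexes i.i.d. Bernoulli(½).

The methods description gives fitnesses but also fixed parent counts, so
some mapping of fitness onto the fixed 12/48 scheme is needed. Parents are
chosen by **fitness-proportionate sampling without replacement within each
sex**; dams are partitioned uniformly among sires at 4 each; every dam
produces exactly 6 offspring. This honours both the fitness model and the
breeding design, and it reproduces the design's published simulation
summaries within Monte-Carlo error (the acceptance script recomputes
them). Fixation means every individual homozygous for the same allele;
replicates stop early once both loci are fixed, since the population can
no longer change. One seeded RNG stream per run, consumed sequentially
across replicates, makes runs exactly reproducible.

A consequence of the equalized family sizes (every dam 6 offspring, every
sire 4 dams) worth knowing: family-size variance is roughly halved
relative to the Poisson variance that the parent-count formula
Ne = 4NmNf/(Nm+Nf) = 38.4 assumes, so the simulator's realized
heterozygosity-decay effective size is near 45 — matching pedigree-based
estimates for such schemes rather than the parent-count value. The test
suite fits the decay rate over 20–25 generations and checks it against the
implied 27–52 range.

## The synthetic data generator

Real chip genotypes from such experiments are generally not deposited, so
the generator produces panels with the statistical features every
downstream stage depends on. What it emulates, and with which defaults:

* **Marker map**: 5 chromosomes with weights 0.35/0.25/0.18/0.12/0.10 and
  cM/Mb ratios 2.8–12, spanning the macro-to-micro chromosome range;
  marker spacing uniform in [0.5, 1.5] × 15 kb. Default 5,000 SNPs for
  fast tests; `n_snps = 57636` gives a full-chip-sized panel.
* **Founder spectrum**: segregating SNPs start at frequencies uniform on
  1/7 ... 6/7 (the seven-founder-line mixture).
* **Drift with linkage**: per-SNP independent drift would destroy the
  clustered-fixation structure the analysis targets, while a genome-scale
  recombination engine is out of proportion. SNPs within 45-kb windows
  (the 30–60 kb LD-block range of such populations) share one per-line
  binomial trajectory (2Ne gametes per generation, Ne = 35), plus a fixed
  per-SNP offset drawn as 2 generations of independent drift. Block
  trajectories are genuine martingales, so the spectrum drifts, spreads
  and fixes at the Wright–Fisher rate; the offsets keep within-block SNPs
  correlated but not identical (soft-sweep-like raggedness).
* **Planted sweeps**: inside a sweep the favoured line ramps linearly (in
  generations) to fixation of the reference allele and the other line to
  the alternative allele — divergent selection fixes opposite alleles —
  reaching fixation at `fixation_generation`; `start_generation` delays
  onset, which is how an "ongoing" sweep with large recent Δp between the
  two sampled timepoints is produced. Each member SNP escapes the sweep
  (keeps drifting) with probability `escape_max × distance/half_width`
  (default 0.5 at the edge): the linear edge law is a modelling choice, as
  no quantitative escape law is established.
* **Sampling**: individuals are drawn by Hardy–Weinberg sampling from the
  line frequency at the sampled generation — so sample-level "fixation"
  can arise from high but incomplete population frequencies, exactly the
  ascertainment effect real panels show. The ground-truth table records
  the true frequencies, sweep membership and escape flags, so detection
  sensitivity and specificity are always scorable.

What it does **not** emulate: mutation, genotyping error, coalescent
structure in the base population, selection on the neutral background,
and within-block recombination during the experiment. Passing tests on
synthetic data therefore validate the statistical machinery —
frequencies, tests, percentiles, clustering, thresholds — not the
population-genetic realism of any particular dataset.

## Quantitative-genetic estimators

* `selection_intensity(p)` = φ(z)/p with z the upper-p standard-normal
  quantile — the analytic form of the tabulated truncation-selection
  intensities (differences to the printed tables are < 0.01).
* `selection_coefficient(a, sigma, i)` = i·2a/σ, capped at 1 with a
  warning (fitness 1 − s cannot go negative).
* `ne_from_parents(12, 48)` = 4·12·48/60 = 38.4;
  `harmonic_ne` takes the numerator (total generations) explicitly, since
  epoch tables are sometimes quoted with a numerator that does not equal
  the sum of the epoch lengths.
* `otto_jones`: detection threshold T ≈ (a_min·n_d − M)/(n_d − 1), loci
  number n = D/(M − T) with D half the parental-line difference. The
  estimator is undefined when M ≤ T (all detected effects equal), which
  the function reports as an error. Reported counts round half away from
  zero; the raw value is kept alongside.
* `drift_attribution`: under drift a locus fixes for different alleles in
  two independent lines with probability 2·P_fix(A)·P_fix(a); the excess
  of observed DIFF SNPs over n_snps times that probability is the
  fraction attributable to selection. `uniform_start_expectation`
  averages per-starting-pair probabilities over the three symmetric
  founder pairs, each standing for two of the six equally likely
  configurations.

## Numerical choices and problem sizes

Tolerances in stochastic tests are 3 Monte-Carlo standard errors computed
from the replication actually run, never fixed percentages. The test
suite uses 150–400 simulator replicates for distributional properties,
1,000 replicates for the three headline fixation summaries (binomial SE
≈ 1.5 points), 1,000 random instances for the clustering brute-force
comparison, and 1,500–5,000-SNP synthetic panels; the full suite runs in
about two minutes. The acceptance script uses 1,000 replicates per
simulation target. Ties in the block-scan percentile resolve downward
(non-outlier); cluster coordinates are 1-based inclusive; the Bonferroni
denominator never counts untestable SNPs.

## Known limitations

* The simulator is two-locus: it quantifies fixation times and linked
  hitch-hiking, not multi-locus interference along a chromosome.
* The generator's LD model is block-wise exchangeable; it reproduces
  clustered fixation but not a realistic decay-with-distance LD curve.
* Persistence probabilities treat the swept region as a single
  non-recombining unit with one r; they are a screening statistic, not a
  likelihood.
* Truncation selection on the latent trait is represented only through
  per-locus selection coefficients; co-selection of unlinked loci
  (Bulmer-type effects) is outside scope.
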
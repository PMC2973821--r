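Package: divselscan
Title: Genome Scans and Forward Simulation for Divergent Selection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide divergence between lines from
    long-term divergent selection experiments on standing genetic variation.
    Provides an individual-based two-locus Wright-Fisher forward simulator of
    a pedigreed breeding scheme with sex-specific selection coefficients,
    per-SNP allelic chi-square divergence scans with Bonferroni correction,
    detection of clusters of SNPs fixed for alternative alleles (candidate
    selective sweeps) with physical and map lengths, block-based allele
    frequency change scans with a Poisson outlier-count threshold,
    heterozygosity accounting, and quantitative-genetic estimators (selection
    intensity and coefficients, effective population size, Otto-Jones
    estimation of the number of trait loci, drift-versus-selection fixation
    attribution). A synthetic genotype generator produces two-line,
    two-timepoint SNP panels with drift and planted sweeps so that every
    stage can be exercised and validated without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
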
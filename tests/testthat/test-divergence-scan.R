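test_that("complete fixation gives chi-square equal to the total allele count", {
  expect_equal(allelic_chi2(group_allele_counts(40, 0, 0, 40))$chi2, 80)
  expect_equal(allelic_chi2(group_allele_counts(98, 0, 0, 20))$chi2, 118)
  # the identity holds for arbitrary group sizes
  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(2:120, 1); n2 <- sample(2:120, 1)
    res <- allelic_chi2(group_allele_counts(n1, 0, 0, n2))
    expect_equal(res$chi2, n1 + n2)
  }
})

test_that("chi-square is zero without divergence and NA when monomorphic", {
  expect_equal(allelic_chi2(group_allele_counts(10, 10, 10, 10))$chi2, 0)
  mono <- allelic_chi2(group_allele_counts(10, 0, 12, 0))
  expect_false(mono$defined)
  expect_true(is.na(mono$chi2))
  expect_error(allelic_chi2(group_allele_counts(0, 0, 5, 5)), "positive")
})

test_that("chi-square matches the textbook statistic and is label-invariant", {
  set.seed(2)
  for (i in 1:30) {
    m <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ours <- allelic_chi2(m)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
    # invariant to swapping allele labels and to swapping groups
    expect_equal(allelic_chi2(m[, 2:1])$chi2, ours$chi2)
    expect_equal(allelic_chi2(m[2:1, ])$chi2, ours$chi2)
  }
})

test_that("Fisher exact p agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact(group_allele_counts(2, 0, 0, 2))$p, 1 / 3)
  expect_equal(fisher_exact(group_allele_counts(7, 3, 7, 3))$p, 1)
  set.seed(3)
  for (i in 1:30) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p, fisher_enum_p(m), tolerance = 1e-10)
  }
})

test_that("scan flags a planted sweep and honours the chi2 = N identity", {
  ds <- generate_dataset(synth_config(
    n_snps = 800L, seed = 71,
    sweeps = list(sweep_spec("1", 2e6, 2.5e5, "HIGH", 30))))
  res <- scan_divergence(ds$panel,
                         list(line = "HIGH", generation = 40),
                         list(line = "LOW", generation = 40))
  core <- ds$truth$expected_diff_40
  expect_true(all(res$sig_0.001[core]))
  expect_true(all(res$chi2[core] == 80))  # 20 vs 20 birds, no missing calls
  # Bonferroni flags are monotone across levels
  expect_true(all(res$sig_0.05[res$sig_0.001]))
  expect_true(attr(res, "m") <= nrow(res))
})

test_that("identical groups yield no flagged SNPs", {
  g <- matrix(sample(0:2, 20 * 40, replace = TRUE), nrow = 20)
  panel <- genotype_panel(rbind(g, g), sprintf("s%02d", 1:40),
                          sprintf("m%02d", 1:40),
                          rep(c("HIGH", "LOW"), each = 20), rep(40L, 40))
  res <- scan_divergence(panel, list(line = "HIGH"), list(line = "LOW"))
  expect_equal(res$chi2[res$defined], rep(0, sum(res$defined)))
  expect_false(any(res$sig_0.05))
  expect_error(scan_divergence(panel, list(line = "HIGH"),
                               list(generation = 40)), "disjoint")
})

test_that("chi-square and exact p-values rank SNPs alike when counts are large", {
  ds <- generate_dataset(synth_config(n_snps = 600L, seed = 81))
  res <- scan_divergence(ds$panel,
                         list(line = "HIGH", generation = 50),
                         list(line = "LOW", generation = 50), fisher = TRUE)
  keep <- res$defined
  # restrict to tables with all cells >= 5 via the frequencies
  fh <- allele_frequencies(ds$panel, "HIGH", 50)
  fl <- allele_frequencies(ds$panel, "LOW", 50)
  big <- keep & pmin(fh, 1 - fh) * 98 >= 5 & pmin(fl, 1 - fl) * 20 >= 5
  sub <- res[big, ]
  k <- ceiling(nrow(sub) / 10)
  top_chi <- order(sub$p)[seq_len(k)]
  top_fis <- order(sub$p_fisher)[seq_len(k)]
  expect_gte(length(intersect(top_chi, top_fis)) / k, 0.9)
})

test_that("sliding window mean matches direct re-summation", {
  expect_equal(sliding_window_mean(rep(3, 50), w = 20), rep(3, 50))
  # a single spike spreads mass 1/w over interior windows
  v <- c(rep(0, 60), 1, rep(0, 60))
  sm <- sliding_window_mean(v, w = 20)
  expect_equal(sm[61], 1 / 20)
  expect_equal(sum(sm > 0), 20)
  # brute force oracle, two chromosomes, odd window
  set.seed(4)
  x <- rnorm(73)
  chr <- rep(c("1", "2"), c(40, 33))
  w <- 7
  got <- sliding_window_mean(x, chr, w = w)
  for (i in seq_along(x)) {
    same <- which(chr == chr[i])
    lo <- max(min(same), i - 3); hi <- min(max(same), i + 3)
    expect_equal(got[i], mean(x[lo:hi]))
  }
  # normalisation rescales by the fixation maximum
  expect_equal(sliding_window_mean(rep(80, 10), w = 3, normalize = 80),
               rep(1, 10))
})

test_that("the Poisson window threshold matches the summed tail", {
  expect_identical(poisson_window_threshold(1, 1e-5), 9L)
  # oracle: direct tail summation for several thresholds
  for (pt in c(0.05, 1e-3, 1e-5, 1e-8)) {
    k <- poisson_window_threshold(1, pt)
    tail_at <- function(k) sum(exp(-1) / factorial(k:60))
    expect_lte(tail_at(k), pt)
    if (k > 0) expect_gt(tail_at(k - 1), pt)
  }
})

test_that("block scan percentile and windows behave as defined", {
  ds <- generate_dataset(synth_config(
    n_snps = 2500L, seed = 91,
    sweeps = list(sweep_spec("1", 6e6, 1e6, "HIGH",
                             fixation_generation = 50,
                             start_generation = 40))))
  bs <- block_change_scan(ds$panel, ds$map, "HIGH", 40, 50)
  expect_equal(bs$k_star, 9L)
  # at most 5% of blocks are outliers (ties resolved downward)
  expect_lte(mean(bs$blocks$outlier), 0.05)
  # blocks never span chromosomes and each holds 5 SNPs
  expect_true(all(bs$blocks$last_bp > bs$blocks$first_bp))
  # significant windows overlap the planted ongoing sweep
  sig <- bs$windows[bs$windows$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$chromosome == "1"))
  # and the flagged windows sit on blocks inside the swept interval
  chr1 <- bs$blocks[bs$blocks$chromosome == "1", ]
  win_first <- chr1$first_bp[sig$window]
  expect_true(all(win_first > 6e6 - 2.5e6 & win_first < 6e6 + 1e6))
})

test_that("constant frequency changes produce no outlier blocks", {
  g40 <- matrix(rep(c(0L, 2L), 50), nrow = 2, byrow = TRUE)
  g50 <- matrix(rep(c(1L, 1L), 50), nrow = 2, byrow = TRUE)
  panel <- genotype_panel(rbind(g40, g40, g50, g50), sprintf("s%d", 1:8),
                          sprintf("m%02d", 1:50),
                          rep(c("HIGH", "LOW", "HIGH", "LOW"), each = 2),
                          rep(c(40L, 50L), each = 4))
  map <- marker_map(sprintf("m%02d", 1:50), "1",
                    seq(1e5, by = 1e5, length.out = 50), 5)
  bs <- suppressWarnings(block_change_scan(panel, map, "HIGH", 40, 50))
  expect_equal(sum(bs$blocks$outlier), 0)  # all means tie at the threshold
})

test_that("heterozygosity accounting matches its definitions", {
  g <- matrix(1L, nrow = 8, ncol = 10)
  panel <- genotype_panel(g, sprintf("s%d", 1:8), sprintf("m%d", 1:10),
                          rep(c("HIGH", "LOW"), 4),
                          rep(c(40L, 40L, 50L, 50L), 2))
  hd <- suppressWarnings(heterozygosity_decline(panel, 40, 50))
  expect_true(all(hd$mean_ho == 1))
  expect_true(all(hd$decrease == 0))
  expect_null(hd$t_test)  # degenerate variance flagged, p undefined
})

test_that("synthetic drift lines lose heterozygosity at the drift rate", {
  ne <- 35
  cfg <- synth_config(n_snps = 4000L, ne = ne, seed = 101)
  ds <- generate_dataset(cfg)
  hd <- heterozygosity_decline(ds$panel, 40, 50)
  expected_ratio <- (1 - 1 / (2 * ne))^10
  for (ln in c("HIGH", "LOW")) {
    ratio <- hd$mean_ho[ln, "50"] / hd$mean_ho[ln, "40"]
    # block-level jackknife SE of the ratio
    tr <- ds$truth
    ho <- function(gen) 2 * tr[[paste0("freq_", ln, "_", gen)]] *
      (1 - tr[[paste0("freq_", ln, "_", gen)]])
    b40 <- tapply(ho(40), tr$block, mean)
    b50 <- tapply(ho(50), tr$block, mean)
    se <- sd(b50 - expected_ratio * b40) / sqrt(length(b40)) / mean(b40)
    expect_lt(abs(ratio - expected_ratio), 3 * se + 0.01)
  }
})
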
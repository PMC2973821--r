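# Per-SNP divergence scans between lines/generations, sliding-window
# summaries, the 5-SNP-block allele-frequency-change analysis with a
# Poisson outlier-count threshold, and heterozygosity accounting.

#' Allelic chi-square test on a 2x2 allele-count table
#'
#' Standard 1-df Pearson chi-square on the table of allele counts in two
#' groups, without continuity correction. When the two groups are completely
#' fixed for alternative alleles the statistic equals the total allele count
#' of the table (e.g. 80 for 20 vs 20 diploids, 118 for 49 vs 10).
#'
#' @param counts a [group_allele_counts()] object or any 2x2 matrix of
#'   non-negative counts (rows = groups, columns = alleles).
#' @return list with `chi2` and `p` (upper chi-square tail, 1 df). A SNP that
#'   is monomorphic in both groups (a zero allele-column margin) has no
#'   defined statistic: `chi2` and `p` are NA and `defined` is FALSE.
#' @examples
#' allelic_chi2(group_allele_counts(40, 0, 0, 40))$chi2  # 80
#' @export
allelic_chi2 <- function(counts) {
  m <- unclass(as.matrix(counts))
  if (!all(dim(m) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(m < 0)) stop("counts must be non-negative")
  N <- sum(m)
  if (N == 0) stop("all-zero table")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) stop("both groups must have a positive allele total")
  if (any(cs == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, defined = FALSE))
  }
  chi2 <- N * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (rs[1] * rs[2] * cs[1] * cs[2])
  chi2 <- unname(chi2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Fisher exact test on a 2x2 allele-count table
#'
#' Two-sided hypergeometric test, as an exact alternative to
#' [allelic_chi2()] for tables with small expected counts.
#'
#' @inheritParams allelic_chi2
#' @return list with `p` and `defined` (FALSE for a zero column margin,
#'   where the test carries no information).
#' @export
fisher_exact <- function(counts) {
  m <- unclass(as.matrix(counts))
  if (!all(dim(m) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) == 0) stop("all-zero table")
  if (any(rowSums(m) == 0)) stop("both groups must have a positive allele total")
  if (any(colSums(m) == 0)) {
    return(list(p = NA_real_, defined = FALSE))
  }
  list(p = stats::fisher.test(m)$p.value, defined = TRUE)
}

panel_allele_counts <- function(panel, keep) {
  g <- panel$genotypes[keep, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  n1 <- colSums(g, na.rm = TRUE)
  cbind(allele1 = n1, allele2 = 2L * n_called - n1)
}

#' Per-SNP association scan between two sample groups
#'
#' Computes the allelic chi-square (and optionally Fisher exact) statistic
#' at every SNP between two disjoint groups of samples, with Bonferroni
#' significance flags. The Bonferroni denominator `m` is the number of SNPs
#' with a defined statistic in this comparison (polymorphic in the pooled
#' groups).
#'
#' @param panel a `genotype_panel`.
#' @param group_a,group_b lists with elements `line` and/or `generation`
#'   passed to [panel_select()]; the groups must be disjoint and non-empty.
#' @param alpha significance levels to Bonferroni-correct
#'   (default `c(0.05, 0.001)`).
#' @param fisher also compute Fisher exact p-values (default FALSE).
#' @return data.frame of class `scan_result`: `snp_id`, `chi2`, `p`,
#'   optionally `p_fisher`, `defined`, and one logical column
#'   `sig_<alpha>` per level (test at `alpha / m`). Attribute `m` holds the
#'   Bonferroni denominator.
#' @export
scan_divergence <- function(panel, group_a, group_b,
                            alpha = c(0.05, 0.001), fisher = FALSE) {
  ka <- do.call(panel_select, c(list(panel), group_a))
  kb <- do.call(panel_select, c(list(panel), group_b))
  if (!any(ka) || !any(kb)) stop("both groups must be non-empty")
  if (any(ka & kb)) stop("groups must be disjoint")
  ca <- panel_allele_counts(panel, ka)
  cb <- panel_allele_counts(panel, kb)
  p_snp <- length(panel$snp_ids)
  chi2 <- p <- pf <- rep(NA_real_, p_snp)
  defined <- rep(FALSE, p_snp)
  for (j in seq_len(p_snp)) {
    m2 <- rbind(ca[j, ], cb[j, ])
    if (any(rowSums(m2) == 0)) next  # all-missing group at this SNP
    r <- allelic_chi2(m2)
    chi2[j] <- r$chi2; p[j] <- r$p; defined[j] <- r$defined
    if (fisher && r$defined) pf[j] <- fisher_exact(m2)$p
  }
  m <- sum(defined)
  out <- data.frame(snp_id = panel$snp_ids, chi2 = chi2, p = p,
                    stringsAsFactors = FALSE)
  if (fisher) out$p_fisher <- pf
  out$defined <- defined
  for (a in alpha) {
    out[[paste0("sig_", a)]] <- defined & !is.na(p) & p < a / m
  }
  attr(out, "m") <- m
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Centered sliding-window mean along the marker map
#'
#' Moving average of a per-SNP series within each chromosome, window of `w`
#' markers centered on each SNP; flanks use the markers available. Optional
#' normalisation by a constant (e.g. the group-size-dependent maximum
#' chi-square, 80 for 20 vs 20 or 118 for 49 vs 10) puts scans from
#' different sample sizes on a common 0-1 scale.
#'
#' @param values numeric per-SNP series, ordered along the map.
#' @param chromosome chromosome label per SNP (windows never span
#'   chromosomes); a single label may be given for a one-chromosome series.
#' @param w window size in markers (default 20).
#' @param normalize optional divisor applied after smoothing.
#' @return numeric vector of smoothed values, same length as `values`.
#' @export
sliding_window_mean <- function(values, chromosome = "1", w = 20L,
                                normalize = NULL) {
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1")
  n <- length(values)
  if (length(chromosome) == 1L) chromosome <- rep(chromosome, n)
  if (length(chromosome) != n) stop("chromosome labels must match values")
  out <- numeric(n)
  lo_off <- (w - 1L) %/% 2L
  hi_off <- w %/% 2L
  for (chr in unique(chromosome)) {
    idx <- which(chromosome == chr)
    v <- values[idx]
    cs <- cumsum(c(0, v))
    nn <- length(v)
    i <- seq_len(nn)
    lo <- pmax(1L, i - lo_off)
    hi <- pmin(nn, i + hi_off)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (!is.null(normalize)) out <- out / normalize
  out
}

#' Smallest Poisson outlier count that is genome-wide significant
#'
#' Under the null, outlier blocks fall independently with rate 5% so a
#' window of `window_blocks` blocks contains Poisson(`lambda`) outliers
#' (`lambda = 1` for 20 blocks). Returns the smallest k with
#' `P(Poisson(lambda) >= k) <= p_threshold`.
#'
#' @param lambda Poisson mean (default 1).
#' @param p_threshold tail probability (default 1e-5).
#' @return integer threshold count k*.
#' @examples
#' poisson_window_threshold(1, 1e-5)  # 9
#' @export
poisson_window_threshold <- function(lambda = 1, p_threshold = 1e-5) {
  k <- 0L
  while (stats::ppois(k - 1L, lambda, lower.tail = FALSE) > p_threshold) {
    k <- k + 1L
  }
  k
}

#' Block-based allele-frequency-change scan within one line
#'
#' Computes per-SNP absolute allele frequency change between two sampled
#' generations of one line, averages it over non-overlapping blocks of
#' `block_size` consecutive SNPs (blocks never span chromosomes; trailing
#' partial blocks are dropped), flags blocks whose mean change lies strictly
#' above the genome-wide 95th percentile as outliers, counts outliers in
#' sliding windows of `window_blocks` blocks within each chromosome, and
#' marks windows significant when the count reaches the Poisson threshold
#' k* from [poisson_window_threshold()].
#'
#' @param panel a `genotype_panel` containing the line at both generations.
#' @param map a `marker_map` aligned to the panel.
#' @param line line label ("HIGH" or "LOW").
#' @param gen1,gen2 the two sampled generations to compare.
#' @param block_size SNPs per block (default 5).
#' @param percentile outlier quantile of the genome-wide block means
#'   (default 0.95, linear-interpolation empirical quantile; block means
#'   exactly at the threshold are not outliers).
#' @param window_blocks blocks per sliding window (default 20).
#' @param p_threshold genome-wide significance level for the window outlier
#'   count (default 1e-5).
#' @return object of class `block_scan`: `blocks` data.frame (chromosome,
#'   first/last bp, mean |dp|, outlier flag), `windows` data.frame
#'   (chromosome, window index, outlier count, significant flag),
#'   `threshold` (the percentile value) and `k_star`.
#' @export
block_change_scan <- function(panel, map, line, gen1, gen2,
                              block_size = 5L, percentile = 0.95,
                              window_blocks = 20L, p_threshold = 1e-5) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(map, "marker_map"))
  if (!identical(panel$snp_ids, map$snp_id)) stop("panel and map not aligned")
  f1 <- allele_frequencies(panel, line = line, generation = gen1)
  f2 <- allele_frequencies(panel, line = line, generation = gen2)
  dp <- abs(f2 - f1)
  blocks <- NULL
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    nb <- length(idx) %/% block_size
    if (nb == 0L) {
      warning("chromosome ", chr, " has fewer than ", block_size,
              " SNPs; skipped")
      next
    }
    used <- idx[seq_len(nb * block_size)]
    bid <- rep(seq_len(nb), each = block_size)
    bm <- tapply(dp[used], bid, mean, na.rm = TRUE)
    first <- tapply(map$position_bp[used], bid, min)
    last <- tapply(map$position_bp[used], bid, max)
    blocks <- rbind(blocks, data.frame(
      chromosome = chr, block = seq_len(nb),
      first_bp = as.integer(first), last_bp = as.integer(last),
      mean_abs_dp = as.numeric(bm), stringsAsFactors = FALSE))
  }
  if (is.null(blocks)) stop("no chromosome had enough SNPs for one block")
  thr <- stats::quantile(blocks$mean_abs_dp, percentile, na.rm = TRUE,
                         names = FALSE)
  blocks$outlier <- !is.na(blocks$mean_abs_dp) & blocks$mean_abs_dp > thr
  k_star <- poisson_window_threshold(window_blocks * (1 - percentile),
                                     p_threshold)
  windows <- NULL
  for (chr in unique(blocks$chromosome)) {
    ob <- blocks$outlier[blocks$chromosome == chr]
    nb <- length(ob)
    if (nb < window_blocks) next
    cnt <- vapply(seq_len(nb - window_blocks + 1L), function(i)
      sum(ob[i:(i + window_blocks - 1L)]), integer(1))
    windows <- rbind(windows, data.frame(
      chromosome = chr, window = seq_along(cnt), n_outliers = cnt,
      significant = cnt >= k_star, stringsAsFactors = FALSE))
  }
  structure(list(blocks = blocks, windows = windows, threshold = thr,
                 k_star = k_star),
            class = "block_scan")
}

#' @export
print.block_scan <- function(x, ...) {
  cat("block_scan:", nrow(x$blocks), "blocks, threshold",
      signif(x$threshold, 4), "| k* =", x$k_star, "\n")
  if (!is.null(x$windows)) {
    cat(sum(x$windows$significant), "of", nrow(x$windows),
        "windows significant\n")
  }
  invisible(x)
}

#' Observed heterozygosity decline and its between-line comparison
#'
#' Observed heterozygosity H_o per SNP is the fraction of heterozygous
#' non-missing calls. For each line the per-SNP decrease between `gen1` and
#' `gen2` is computed, and the decreases of the two lines are compared with
#' a two-sample two-sided t-test.
#'
#' @param panel a `genotype_panel` with both lines at both generations.
#' @param gen1,gen2 generations compared (decrease = H_o(gen1) - H_o(gen2)).
#' @param lines the two line labels (default `c("HIGH", "LOW")`).
#' @param snps optional logical/index vector restricting the SNPs used
#'   (e.g. autosomal markers only).
#' @return list with `mean_ho` (lines x generations matrix of mean H_o),
#'   `decrease` (per-SNP decrease matrix, one column per line), and `t_test`
#'   (the `htest`, or NULL with a warning if a variance is degenerate).
#' @export
heterozygosity_decline <- function(panel, gen1, gen2,
                                   lines = c("HIGH", "LOW"), snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(snps)) snps <- seq_along(panel$snp_ids)
  ho <- function(line, gen) {
    keep <- panel_select(panel, line = line, generation = gen)
    if (!any(keep)) stop("no samples for line ", line, " generation ", gen)
    g <- panel$genotypes[keep, snps, drop = FALSE]
    colSums(g == 1L, na.rm = TRUE) / colSums(!is.na(g))
  }
  h11 <- ho(lines[1], gen1); h12 <- ho(lines[1], gen2)
  h21 <- ho(lines[2], gen1); h22 <- ho(lines[2], gen2)
  mean_ho <- matrix(c(mean(h11, na.rm = TRUE), mean(h12, na.rm = TRUE),
                      mean(h21, na.rm = TRUE), mean(h22, na.rm = TRUE)),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(lines, as.character(c(gen1, gen2))))
  dec <- cbind(h11 - h12, h21 - h22)
  colnames(dec) <- lines
  ok <- stats::complete.cases(dec)
  tt <- NULL
  if (stats::sd(dec[ok, 1]) == 0 && stats::sd(dec[ok, 2]) == 0) {
    warning("degenerate variance in per-locus decreases; t-test undefined")
  } else {
    tt <- stats::t.test(dec[ok, 1], dec[ok, 2])
  }
  list(mean_ho = mean_ho, decrease = dec, t_test = tt)
}
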
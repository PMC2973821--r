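# In-code fixtures shared across test files.

# a small hand-built panel: 4 samples (2 HIGH, 2 LOW), 3 SNPs
tiny_panel <- function() {
  g <- rbind(c(2L, 1L, 0L),
             c(2L, 2L, NA),
             c(0L, 1L, 2L),
             c(0L, 0L, 2L))
  genotype_panel(g, c("h1", "h2", "l1", "l2"), c("s1", "s2", "s3"),
                 c("HIGH", "HIGH", "LOW", "LOW"), c(40L, 40L, 40L, 40L))
}

tiny_map <- function() {
  marker_map(c("s1", "s2", "s3"), "1", c(100L, 200000L, 5000000L),
             cm_per_mb = 10)
}

# a random valid panel for property checks
random_panel <- function(n_samples, n_snps, missing_rate = 0.05) {
  g <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
              nrow = n_samples)
  g[runif(n_samples * n_snps) < missing_rate] <- NA_integer_
  line <- rep(c("HIGH", "LOW"), length.out = n_samples)
  genotype_panel(g, sprintf("smp%03d", seq_len(n_samples)),
                 sprintf("snp%04d", seq_len(n_snps)),
                 line, rep(40L, n_samples))
}

# brute-force two-sided Fisher p by hypergeometric enumeration
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_range, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force cluster partitioner: split ordered DIFF positions at gaps
# larger than max_gap, keep runs of at least min_snps
brute_clusters <- function(pos, max_gap, min_snps) {
  if (!length(pos)) return(NULL)
  pos <- sort(pos)
  out <- NULL
  start <- 1L
  for (i in seq_along(pos)) {
    if (i == length(pos) || pos[i + 1] - pos[i] > max_gap) {
      if (i - start + 1L >= min_snps) {
        out <- rbind(out, c(first = pos[start], last = pos[i],
                            n = i - start + 1L))
      }
      start <- i + 1L
    }
  }
  out
}
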
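# Clustering of SNPs fixed for alternative alleles into candidate selective
# sweeps, physical -> map length conversion, Haldane's map function, and the
# probability that a haplotype persists un-recombined through a sweep.

#' Cluster fixed SNPs into candidate selective sweeps
#'
#' Orders the SNPs flagged as fixed for alternative alleles (DIFF) along
#' each chromosome and forms maximal runs in which consecutive flagged SNPs
#' are at most `max_gap_bp` apart; runs with fewer than `min_snps` members
#' are discarded. Cluster length is `last_bp - first_bp` (1-based inclusive
#' coordinates), and map length uses the chromosome's cM/Mb ratio.
#'
#' @param diff per-SNP DIFF indicator aligned to `map`: either a logical
#'   vector or the factor returned by [classify_fixation()] (where the
#'   `DIFF` level is taken).
#' @param map a `marker_map`.
#' @param max_gap_bp maximum distance between subsequent fixed SNPs within a
#'   cluster (default 1 Mb).
#' @param min_snps minimum SNPs per cluster (default 2; 5 is the stringent
#'   choice).
#' @return object of class `sweep_clusters`: `clusters` data.frame
#'   (chromosome, first_bp, last_bp, n_snps, length_mb, length_cm — NA where
#'   the chromosome has no cM/Mb ratio) and `summary` list (`n_clusters`,
#'   `pct_diff_in_clusters`, `pct_genome_covered` — the covered share of the
#'   marker-spanned genome).
#' @examples
#' m <- marker_map(paste0("s", 1:3), "1", c(1e6, 1.5e6, 3e6), 10)
#' cluster_fixed_snps(c(TRUE, TRUE, TRUE), m, max_gap_bp = 1e6, min_snps = 2)
#' @export
cluster_fixed_snps <- function(diff, map, max_gap_bp = 1e6, min_snps = 2L) {
  stopifnot(inherits(map, "marker_map"))
  if (is.factor(diff)) diff <- diff == "DIFF"
  diff[is.na(diff)] <- FALSE
  if (length(diff) != nrow(map)) stop("diff flags and map not aligned")
  clusters <- NULL
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr & diff)
    if (!length(idx)) next
    pos <- map$position_bp[idx]  # map is sorted within chromosome
    brk <- c(0L, which(diff(pos) > max_gap_bp), length(pos))
    for (k in seq_len(length(brk) - 1L)) {
      run <- (brk[k] + 1L):brk[k + 1L]
      if (length(run) < min_snps) next
      ratio <- map$cm_per_mb[idx[1]]
      len_mb <- (pos[run[length(run)]] - pos[run[1]]) / 1e6
      clusters <- rbind(clusters, data.frame(
        chromosome = chr,
        first_bp = pos[run[1]], last_bp = pos[run[length(run)]],
        n_snps = length(run),
        length_mb = len_mb,
        length_cm = if (is.na(ratio)) NA_real_ else len_mb * ratio,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(clusters)) {
    clusters <- data.frame(chromosome = character(), first_bp = integer(),
                           last_bp = integer(), n_snps = integer(),
                           length_mb = numeric(), length_cm = numeric(),
                           stringsAsFactors = FALSE)
  }
  span <- sum(tapply(map$position_bp, map$chromosome,
                     function(p) max(p) - min(p)))
  n_diff <- sum(diff)
  structure(list(
    clusters = clusters,
    summary = list(
      n_clusters = nrow(clusters),
      pct_diff_in_clusters = if (n_diff)
        100 * sum(clusters$n_snps) / n_diff else NA_real_,
      pct_genome_covered = 100 *
        sum(clusters$last_bp - clusters$first_bp) / span)),
    class = "sweep_clusters")
}

#' @export
print.sweep_clusters <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "sweep_clusters: %d clusters, %.1f%% of DIFF SNPs, %.1f%% of genome\n",
    s$n_clusters, s$pct_diff_in_clusters, s$pct_genome_covered))
  invisible(x)
}

#' Map length of a cluster from its chromosome's cM/Mb ratio
#'
#' @param length_mb physical length in Mb.
#' @param cm_per_mb chromosome-specific ratio; NA (e.g. Z without a linkage
#'   map) yields NA.
#' @return length in cM.
#' @export
cm_length <- function(length_mb, cm_per_mb) {
  if (any(length_mb < 0, na.rm = TRUE)) stop("length_mb must be >= 0")
  length_mb * cm_per_mb
}

#' Haldane's map function
#'
#' Converts a map distance in cM to a recombination fraction assuming no
#' interference: `r = (1 - exp(-2 d)) / 2` with `d` in Morgans.
#'
#' @param d_cm map distance in centimorgans, `>= 0`.
#' @return recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_r(5)  # ~0.0476
#' @export
haldane_r <- function(d_cm) {
  if (any(d_cm < 0, na.rm = TRUE)) stop("map distance must be >= 0")
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' Probability that a haplotype persists un-recombined through a sweep
#'
#' A cluster stays fixed for alternative alleles only if no effective
#' recombination separates its ends during the sweep: each of the `2 N g`
#' transmitted gametes either does not recombine (probability `1 - r`) or
#' recombines in a homozygous (non-informative) individual (probability
#' `r (p^2 + q^2)` under random pairing of haplotypes at frequencies `p` and
#' `q = 1 - p`). The persistence probability is
#' `((1 - r) + r (p^2 + q^2))^(2 N g)`.
#'
#' @param r recombination fraction across the region, in `[0, 0.5]`
#'   (e.g. from [haldane_r()]).
#' @param p frequency of the swept haplotype (`q = 1 - p`).
#' @param N effective population size (default 36.21, the harmonic-mean
#'   effective size of the selected lines through generation 50).
#' @param g generations until fixation of the cluster.
#' @return probability in `[0, 1]`.
#' @examples
#' persistence_probability(haldane_r(5), p = 1/7, N = 36.21, g = 3)  # ~0.078
#' @export
persistence_probability <- function(r, p, N = 36.21, g) {
  if (any(r < 0 | r > 0.5)) stop("r must be in [0, 0.5]")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(N <= 0)) stop("N must be > 0")
  if (any(g < 0)) stop("g must be >= 0")
  q <- 1 - p
  ((1 - r) + r * (p^2 + q^2))^(2 * N * g)
}

#' Annotate clusters with overlapping intervals (e.g. known QTL)
#'
#' Reads BED-style intervals (0-based half-open; converted to 1-based
#' inclusive) and labels each cluster with the names of all intervals it
#' intersects by at least one bp.
#'
#' @param clusters a `sweep_clusters` object.
#' @param intervals data.frame with columns `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive), `name`; or a path to a BED file
#'   (chrom, start, end, name).
#' @return the `sweep_clusters` object with an `overlaps` column added
#'   (comma-separated interval names, "" if none).
#' @export
annotate_clusters <- function(clusters, intervals) {
  stopifnot(inherits(clusters, "sweep_clusters"))
  if (is.character(intervals)) {
    bed <- utils::read.table(intervals, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) bed[[4]] <- paste0("iv", seq_len(nrow(bed)))
    intervals <- data.frame(chromosome = as.character(bed[[1]]),
                            start_bp = bed[[2]] + 1L,  # BED is 0-based
                            end_bp = bed[[3]],
                            name = as.character(bed[[4]]),
                            stringsAsFactors = FALSE)
  }
  cl <- clusters$clusters
  cl$overlaps <- vapply(seq_len(nrow(cl)), function(i) {
    hit <- intervals$chromosome == cl$chromosome[i] &
      intervals$start_bp <= cl$last_bp[i] &
      intervals$end_bp >= cl$first_bp[i]
    paste(intervals$name[hit], collapse = ",")
  }, character(1))
  clusters$clusters <- cl
  clusters
}
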
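# Synthetic two-line, two-timepoint genotype panels with drift and planted
# selective sweeps.
#
# The generator emulates a 60K-chip-style marker set (a few macro and micro
# chromosomes, ~1 marker / 15 kb, near-uniform segregating allele-frequency
# spectrum on multiples of 1/7) evolving in two divergently selected lines:
# neutral SNPs drift by per-line binomial sampling of 2*Ne gametes per
# generation, with SNPs grouped into LD blocks that share one drift
# trajectory plus a small per-SNP offset; SNPs inside a planted sweep ramp
# to fixation for alternative alleles in the two lines by a stated
# generation, with a per-SNP escape probability growing linearly with
# distance from the sweep centre (soft-sweep edges). Every run returns a
# ground-truth table sufficient to score sweep recovery.

#' Specification of one planted selective sweep
#'
#' SNPs within `half_width_bp` of `center_bp` ramp to fixation for the
#' reference allele in `line_favoured` and for the alternative allele in the
#' other line by `fixation_generation` (divergent selection fixes opposite
#' alleles). Each member SNP escapes the sweep (keeps drifting) with
#' probability proportional to its distance from the centre.
#'
#' @param chromosome chromosome label.
#' @param center_bp sweep centre (bp).
#' @param half_width_bp half-width of the swept region (> 0).
#' @param line_favoured `"HIGH"` or `"LOW"`: the line fixing the reference
#'   allele.
#' @param fixation_generation generation by which non-escaped SNPs are fixed.
#' @param start_generation generation at which the sweep starts moving
#'   (default 0; set between two sampled generations to emulate an ongoing
#'   sweep with large recent frequency changes).
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(chromosome, center_bp, half_width_bp,
                       line_favoured = "HIGH", fixation_generation = 30L,
                       start_generation = 0L) {
  if (half_width_bp <= 0) stop("half_width_bp must be > 0")
  if (!line_favoured %in% c("HIGH", "LOW")) {
    stop("line_favoured must be HIGH or LOW")
  }
  if (start_generation >= fixation_generation) {
    stop("start_generation must precede fixation_generation")
  }
  structure(list(chromosome = as.character(chromosome),
                 center_bp = as.numeric(center_bp),
                 half_width_bp = as.numeric(half_width_bp),
                 line_favoured = line_favoured,
                 fixation_generation = as.integer(fixation_generation),
                 start_generation = as.integer(start_generation)),
            class = "sweep_spec")
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults emulate the study conditions of a two-line chicken selection
#' experiment at test scale: 5,000 SNPs on 5 chromosomes (set
#' `n_snps = 57636` for a full-chip-sized emulation), ~1 marker / 15 kb,
#' founder frequencies uniform on multiples of 1/7, per-line effective size
#' 35, panels sampled at generations 40 (20 HIGH + 20 LOW) and 50 (49 HIGH +
#' 10 LOW).
#'
#' @param n_snps total number of SNPs (default 5000).
#' @param chromosomes data.frame with columns `name`, `weight` (share of
#'   SNPs) and `cm_per_mb`; the default mimics macro chromosomes (low cM/Mb)
#'   through micro chromosomes (high cM/Mb).
#' @param marker_spacing_bp mean distance between adjacent markers
#'   (default 15000).
#' @param ne per-line effective population size driving drift (default 35).
#' @param generations sampled generations (default `c(40, 50)`).
#' @param sample_sizes named list (one element per sampled generation) of
#'   named vectors `c(HIGH = ..., LOW = ...)`.
#' @param sweeps list of [sweep_spec()] objects (default none).
#' @param base_freqs allele-frequency spectrum of segregating founder SNPs
#'   (default uniform on 1/7 ... 6/7).
#' @param ld_block_bp size of the LD blocks sharing one drift trajectory
#'   (default 45000, the 30-60 kb range seen in such populations).
#' @param jitter_generations generations of independent per-SNP drift that
#'   set the within-block offsets (default 2).
#' @param escape_max escape probability at the sweep edge (default 0.5;
#'   linear in distance from the centre).
#' @param missing_rate per-call missing probability (default 0).
#' @param seed integer seed; identical configurations give identical data.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_snps = 5000L,
                         chromosomes = data.frame(
                           name = as.character(1:5),
                           weight = c(0.35, 0.25, 0.18, 0.12, 0.10),
                           cm_per_mb = c(2.8, 3.2, 6.0, 9.0, 12.0),
                           stringsAsFactors = FALSE),
                         marker_spacing_bp = 15000L,
                         ne = 35,
                         generations = c(40L, 50L),
                         sample_sizes = list(
                           `40` = c(HIGH = 20L, LOW = 20L),
                           `50` = c(HIGH = 49L, LOW = 10L)),
                         sweeps = list(),
                         base_freqs = (1:6) / 7,
                         ld_block_bp = 45000L,
                         jitter_generations = 2L,
                         escape_max = 0.5,
                         missing_rate = 0,
                         seed = 1L) {
  if (n_snps < 1L) stop("n_snps must be >= 1")
  if (any(unlist(lapply(sample_sizes, function(x) x < 1L)))) {
    stop("all sample sizes must be >= 1")
  }
  if (!setequal(names(sample_sizes), as.character(generations))) {
    stop("sample_sizes must have one element per sampled generation")
  }
  if (length(sweeps) && inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  for (sw in sweeps) {
    if (!inherits(sw, "sweep_spec")) stop("sweeps must be sweep_spec objects")
    if (sw$fixation_generation > max(generations)) {
      stop("sweep fixation_generation exceeds the latest sampled generation")
    }
  }
  # overlapping sweeps on one chromosome are not allowed
  if (length(sweeps) > 1L) {
    for (chr in unique(vapply(sweeps, `[[`, "", "chromosome"))) {
      iv <- do.call(rbind, lapply(sweeps, function(s)
        if (s$chromosome == chr)
          c(s$center_bp - s$half_width_bp, s$center_bp + s$half_width_bp)))
      if (!is.null(iv) && nrow(iv) > 1L) {
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
          stop("overlapping sweeps on chromosome ", chr)
        }
      }
    }
  }
  structure(list(n_snps = as.integer(n_snps), chromosomes = chromosomes,
                 marker_spacing_bp = as.integer(marker_spacing_bp),
                 ne = ne, generations = as.integer(generations),
                 sample_sizes = sample_sizes, sweeps = sweeps,
                 base_freqs = base_freqs,
                 ld_block_bp = as.integer(ld_block_bp),
                 jitter_generations = as.integer(jitter_generations),
                 escape_max = escape_max, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

drift_generations <- function(p, ne, n_gen) {
  for (t in seq_len(n_gen)) p <- stats::rbinom(length(p), 2 * ne, p) / (2 * ne)
  p
}

#' Generate a synthetic two-line genotype dataset
#'
#' Runs the drift/sweep model described in [synth_config()] and draws
#' genotype panels at the sampled generations (Hardy-Weinberg sampling of
#' individuals from the line frequencies).
#'
#' @param config a [synth_config()].
#' @return list with `panel` (one `genotype_panel` holding all sampled
#'   individuals, labelled by line and generation), `map` (a `marker_map`)
#'   and `truth` (data.frame with per-SNP block id, base frequency, sweep
#'   membership, per-line escape flags, expected DIFF status at each sampled
#'   generation, and the true line frequencies `freq_<line>_<gen>` at each
#'   sampled generation).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  chr_tab <- config$chromosomes
  n_per_chr <- round_half_up(config$n_snps * chr_tab$weight /
                               sum(chr_tab$weight))
  n_per_chr[1] <- n_per_chr[1] + config$n_snps - sum(n_per_chr)

  chrom <- rep(chr_tab$name, n_per_chr)
  pos <- unlist(lapply(n_per_chr, function(k)
    cumsum(round(config$marker_spacing_bp * stats::runif(k, 0.5, 1.5)))))
  snp_id <- sprintf("snp_%s_%06d", chrom, unlist(lapply(n_per_chr, seq_len)))
  map <- marker_map(snp_id, chrom, pos,
                    chr_tab$cm_per_mb[match(chrom, chr_tab$name)])
  n <- config$n_snps

  # LD blocks: consecutive SNPs within ld_block_bp windows share drift
  block <- paste(chrom, pos %/% config$ld_block_bp)
  block_id <- match(block, unique(block))
  n_block <- max(block_id)

  base_block <- sample(config$base_freqs, n_block, replace = TRUE)
  base <- base_block[block_id]

  gens <- sort(config$generations)
  max_gen <- max(gens)
  lines <- c("HIGH", "LOW")

  # per-line block trajectories and per-SNP offsets
  freq <- list()
  for (ln in lines) {
    p_block <- base_block
    at <- list()
    prev <- 0L
    for (g in gens) {
      p_block <- drift_generations(p_block, config$ne, g - prev)
      at[[as.character(g)]] <- p_block
      prev <- g
    }
    offset <- drift_generations(base, config$ne,
                                config$jitter_generations) - base
    freq[[ln]] <- lapply(at, function(pb) clamp01(pb[block_id] + offset))
  }

  # planted sweeps override drift for non-escaped member SNPs
  truth <- data.frame(snp_id = snp_id, chromosome = chrom, position_bp = pos,
                      block = block_id, base_freq = base,
                      sweep = NA_integer_,
                      escaped_HIGH = FALSE, escaped_LOW = FALSE,
                      stringsAsFactors = FALSE)
  for (k in seq_along(config$sweeps)) {
    sw <- config$sweeps[[k]]
    mem <- which(chrom == sw$chromosome &
                   abs(pos - sw$center_bp) <= sw$half_width_bp)
    if (!length(mem)) next
    truth$sweep[mem] <- k
    dist_rel <- abs(pos[mem] - sw$center_bp) / sw$half_width_bp
    for (ln in lines) {
      esc <- stats::runif(length(mem)) < config$escape_max * dist_rel
      truth[[paste0("escaped_", ln)]][mem] <- esc
      target <- if (ln == sw$line_favoured) 1 else 0
      for (g in gens) {
        ramp <- clamp01((g - sw$start_generation) /
                          (sw$fixation_generation - sw$start_generation))
        pg <- base[mem] + (target - base[mem]) * ramp
        cur <- freq[[ln]][[as.character(g)]]
        cur[mem[!esc]] <- pg[!esc]
        freq[[ln]][[as.character(g)]] <- cur
      }
    }
  }
  for (g in gens) {
    gh <- freq$HIGH[[as.character(g)]]
    gl <- freq$LOW[[as.character(g)]]
    truth[[paste0("freq_HIGH_", g)]] <- gh
    truth[[paste0("freq_LOW_", g)]] <- gl
    truth[[paste0("expected_diff_", g)]] <- !is.na(truth$sweep) &
      !truth$escaped_HIGH & !truth$escaped_LOW &
      vapply(truth$sweep, function(s)
        !is.na(s) && config$sweeps[[s]]$fixation_generation <= g,
        logical(1))
  }

  # draw individuals: HWE within line at the true frequency
  geno <- NULL; ids <- character(); smp_line <- character()
  smp_gen <- integer()
  for (g in gens) {
    sizes <- config$sample_sizes[[as.character(g)]]
    for (ln in lines) {
      k <- sizes[[ln]]
      p <- freq[[ln]][[as.character(g)]]
      m <- matrix(stats::rbinom(k * n, 2L, rep(p, each = k)), nrow = k)
      if (config$missing_rate > 0) {
        m[stats::runif(k * n) < config$missing_rate] <- NA_integer_
      }
      geno <- rbind(geno, m)
      ids <- c(ids, sprintf("%s%d_%02d", substr(ln, 1, 1), g, seq_len(k)))
      smp_line <- c(smp_line, rep(ln, k))
      smp_gen <- c(smp_gen, rep(g, k))
    }
  }
  panel <- genotype_panel(geno, ids, snp_id, smp_line, smp_gen)
  list(panel = panel, map = map, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Generates a dataset and writes PED/MAP files with sidecars (see
#' [write_panel()]) plus `ground_truth.tsv`.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix (default "synth").
#' @return invisibly, the files written.
#' @export
write_synthetic_dataset <- function(config, out_dir, prefix = "synth") {
  ds <- generate_dataset(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_panel(ds$panel, ds$map, file.path(out_dir, prefix))
  gt <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(ds$truth, gt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, gt))
}
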
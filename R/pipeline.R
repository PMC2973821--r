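# End-to-end orchestration: synth -> scan -> blockscan -> clusters ->
# quantgen, plus replicated forward-simulation experiments, from one YAML
# config with a global seed. Every produced file is recorded in a manifest
# with its md5 checksum, so identical config + seed gives identical
# manifests.

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline from a config
#'
#' Stages (each optional, executed in dependency order):
#' \describe{
#'   \item{synth}{generate the synthetic dataset and write PED/MAP +
#'     ground truth.}
#'   \item{scan}{between-line allelic chi-square scans at each sampled
#'     generation (`scan.tsv`).}
#'   \item{blockscan}{within-line 5-SNP-block allele-frequency-change scan
#'     between the two sampled generations (`blocks.tsv`, `windows.tsv`).}
#'   \item{clusters}{clusters of SNPs fixed for alternative alleles at each
#'     generation (`clusters.tsv`).}
#'   \item{quantgen}{effective-size and Otto-Jones estimates from config
#'     values (`quantgen.tsv`).}
#'   \item{simulate}{replicated two-locus forward simulations for a list of
#'     selection regimes (`simulation.tsv`).}
#' }
#'
#' @param config path to a YAML file or an equivalent nested list. Top-level
#'   keys: `out_dir`, `seed`, `stages` (character vector), and one block per
#'   stage (`synth`, `scan`, `blockscan`, `clusters`, `quantgen`,
#'   `simulate`) holding that stage's parameters.
#' @return data.frame manifest (file, md5), invisibly written to
#'   `manifest.tsv` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config must give out_dir")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("synth", "scan", "blockscan", "clusters")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- character()
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("divselscan ", as.character(utils::packageVersion("divselscan")),
       " | seed ", seed, " | stages: ", paste(stages, collapse = ","))

  ds <- NULL
  if (any(c("synth", "scan", "blockscan", "clusters") %in% stages)) {
    sy <- config$synth %||% list()
    sweeps <- lapply(sy$sweeps %||% list(), function(s)
      sweep_spec(s$chromosome, s$center_bp, s$half_width_bp,
                 s$line_favoured %||% "HIGH",
                 s$fixation_generation %||% 30L,
                 s$start_generation %||% 0L))
    cfg <- synth_config(
      n_snps = sy$n_snps %||% 5000L,
      ne = sy$ne %||% 35,
      sweeps = sweeps,
      missing_rate = sy$missing_rate %||% 0,
      seed = seed)
    ds <- generate_dataset(cfg)
    if ("synth" %in% stages) {
      files <- write_panel(ds$panel, ds$map, file.path(out_dir, "synth"))
      gt <- write_tsv(ds$truth, file.path(out_dir, "ground_truth.tsv"))
      produced <- c(produced, files, gt)
      logf("synth: ", length(ds$panel$sample_ids), " samples x ",
           length(ds$panel$snp_ids), " SNPs")
    }
    gens <- sort(cfg$generations)
  }

  if ("scan" %in% stages) {
    sc <- config$scan %||% list()
    alpha <- sc$alpha %||% c(0.05, 0.001)
    rows <- NULL
    for (g in gens) {
      res <- scan_divergence(ds$panel,
                             list(line = "HIGH", generation = g),
                             list(line = "LOW", generation = g),
                             alpha = alpha,
                             fisher = isTRUE(sc$fisher))
      res$generation <- g
      rows <- rbind(rows, res)
    }
    produced <- c(produced, write_tsv(rows, file.path(out_dir, "scan.tsv")))
    logf("scan: ", nrow(rows), " SNP tests")
  }

  if ("blockscan" %in% stages) {
    bs <- config$blockscan %||% list()
    rows_b <- NULL; rows_w <- NULL
    for (ln in bs$lines %||% c("HIGH", "LOW")) {
      b <- block_change_scan(ds$panel, ds$map, ln, gens[1], gens[2],
                             block_size = bs$block_size %||% 5L,
                             percentile = bs$percentile %||% 0.95,
                             window_blocks = bs$window_blocks %||% 20L,
                             p_threshold = bs$p_threshold %||% 1e-5)
      b$blocks$line <- ln
      rows_b <- rbind(rows_b, b$blocks)
      if (!is.null(b$windows)) {
        b$windows$line <- ln
        rows_w <- rbind(rows_w, b$windows)
      }
    }
    produced <- c(produced,
                  write_tsv(rows_b, file.path(out_dir, "blocks.tsv")),
                  write_tsv(rows_w %||% data.frame(),
                            file.path(out_dir, "windows.tsv")))
    logf("blockscan: ", nrow(rows_b), " blocks")
  }

  if ("clusters" %in% stages) {
    cl <- config$clusters %||% list()
    rows <- NULL
    for (g in gens) {
      fh <- allele_frequencies(ds$panel, "HIGH", g)
      fl <- allele_frequencies(ds$panel, "LOW", g)
      cls <- cluster_fixed_snps(classify_fixation(fh, fl), ds$map,
                                max_gap_bp = cl$max_gap_bp %||% 1e6,
                                min_snps = cl$min_snps %||% 2L)
      if (!is.null(cl$qtl_bed)) cls <- annotate_clusters(cls, cl$qtl_bed)
      if (nrow(cls$clusters)) {
        cls$clusters$generation <- g
        rows <- rbind(rows, cls$clusters)
      }
      logf("clusters gen ", g, ": ", cls$summary$n_clusters, " clusters (",
           round(cls$summary$pct_diff_in_clusters, 1), "% of DIFF SNPs)")
    }
    produced <- c(produced,
                  write_tsv(rows %||% data.frame(),
                            file.path(out_dir, "clusters.tsv")))
  }

  if ("quantgen" %in% stages) {
    qg <- config$quantgen %||% list()
    rows <- data.frame(quantity = character(), value = numeric(),
                       stringsAsFactors = FALSE)
    if (!is.null(qg$parents)) {
      rows <- rbind(rows, data.frame(
        quantity = "ne_from_parents",
        value = ne_from_parents(qg$parents$males, qg$parents$females)))
    }
    if (!is.null(qg$ne_epochs)) {
      e <- qg$ne_epochs
      rows <- rbind(rows, data.frame(
        quantity = "harmonic_ne",
        value = harmonic_ne(unlist(e$n_generations), unlist(e$ne),
                            e$total_generations %||%
                              sum(unlist(e$n_generations)))))
    }
    for (tr in qg$otto_jones %||% list()) {
      oj <- otto_jones(tr$D, tr$M, tr$a_min, tr$n_d)
      rows <- rbind(rows,
                    data.frame(quantity = paste0("otto_jones_T_", tr$trait),
                               value = oj$T),
                    data.frame(quantity = paste0("otto_jones_n_", tr$trait),
                               value = oj$n))
    }
    produced <- c(produced,
                  write_tsv(rows, file.path(out_dir, "quantgen.tsv")))
    logf("quantgen: ", nrow(rows), " quantities")
  }

  if ("simulate" %in% stages) {
    sim <- config$simulate %||% list()
    scheme <- breeding_scheme(sim$n_sires %||% 12L, sim$n_dams %||% 48L,
                              sim$dams_per_sire %||% 4L,
                              sim$offspring_per_dam %||% 6L)
    n_rep <- sim$n_rep %||% 1000L
    max_gen <- sim$max_gen %||% 40L
    r <- sim[["r"]] %||% haldane_r(5)  # [[ ]]: $r would partial-match $regimes
    code <- as.character(sim$hap_code %||% "4003")
    rows <- NULL
    for (i in seq_along(sim$regimes)) {
      rg <- sim$regimes[[i]]
      out <- run_replicates(hap_freqs(code), scheme,
                            selection_params(rg$s_male, rg$s_female,
                                             rg$h %||% 0.5),
                            r = r, n_rep = n_rep, max_gen = max_gen,
                            seed = seed + i)
      s <- out$summary
      rows <- rbind(rows, data.frame(
        regime = rg$name %||% paste0("regime", i),
        s_male = rg$s_male, s_female = rg$s_female,
        first_fixation_gen = s$first_fixation_gen,
        gen_10pct = s$gen_10pct,
        prop_fixed = s$prop_fixed_A,
        prop_selected_allele = s$prop_selected_allele,
        stringsAsFactors = FALSE))
    }
    produced <- c(produced,
                  write_tsv(rows, file.path(out_dir, "simulation.tsv")))
    logf("simulate: ", length(sim$regimes), " regimes x ", n_rep,
         " replicates")
  }

  manifest <- data.frame(file = basename(produced),
                         md5 = unname(tools::md5sum(produced)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
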
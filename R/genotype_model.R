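# Core containers: genotype panels and marker maps.
#
# Genotypes are stored as allele dosages in {0, 1, 2} counted against a
# declared reference allele per SNP (allele1 in the marker map), with NA for
# missing calls. All downstream stages (scans, clustering, heterozygosity)
# operate on these two containers.

#' Construct a genotype panel
#'
#' A `genotype_panel` holds a samples x SNPs matrix of allele dosages for a
#' two-line selection experiment sampled at one or more generations. Dosage
#' is the count of the reference allele (allele1 in the paired marker map),
#' so 2 means homozygous reference, 0 homozygous alternative and NA missing.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param snp_ids character vector of unique SNP identifiers, aligned to the
#'   columns of `genotypes`.
#' @param line character vector per sample, each `"HIGH"` or `"LOW"`.
#' @param generation integer vector per sample (e.g. 40 or 50).
#' @return An object of class `genotype_panel`.
#' @examples
#' g <- matrix(c(2L, 1L, 0L, 2L, 2L, 0L), nrow = 2, byrow = TRUE)
#' genotype_panel(g, c("h1", "l1"), c("s1", "s2", "s3"),
#'                c("HIGH", "LOW"), c(40L, 40L))
#' @export
genotype_panel <- function(genotypes, sample_ids, snp_ids, line, generation) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  if (length(sample_ids) != n) {
    stop("sample_ids length (", length(sample_ids),
         ") does not match genotype rows (", n, ")")
  }
  if (length(snp_ids) != ncol(genotypes)) {
    stop("snp_ids length does not match genotype columns")
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids")
  line <- as.character(line)
  generation <- as.integer(generation)
  if (length(line) != n || length(generation) != n) {
    stop("line and generation must have one entry per sample")
  }
  bad_line <- is.na(line) | !(line %in% c("HIGH", "LOW"))
  if (any(bad_line)) {
    stop("sample(s) without a valid line label (HIGH/LOW): ",
         paste(sample_ids[bad_line], collapse = ", "))
  }
  if (anyNA(generation)) {
    stop("sample(s) without a generation: ",
         paste(sample_ids[is.na(generation)], collapse = ", "))
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  dimnames(genotypes) <- list(sample_ids, snp_ids)
  structure(
    list(genotypes = genotypes,
         sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids),
         line = line,
         generation = generation),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs\n")
  tab <- table(line = x$line, generation = x$generation)
  print(tab)
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Construct a marker map
#'
#' Per-SNP chromosome and physical position (1-based bp), the per-chromosome
#' cM/Mb ratio used to convert physical cluster lengths to map lengths, and
#' the declared reference/alternative allele codes against which dosages are
#' counted. Positions must be strictly increasing within a chromosome.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param chromosome chromosome label per SNP (autosomes, "Z", linkage groups).
#' @param position_bp integer, 1-based physical position.
#' @param cm_per_mb per-chromosome map ratio (cM per Mb); NA allowed (e.g. Z
#'   without a linkage map), in which case map lengths are left blank.
#' @param allele1,allele2 allele codes (reference and alternative) as they
#'   appear in PED files; defaults "1" and "2".
#' @return A `data.frame` of class `marker_map`.
#' @export
marker_map <- function(snp_id, chromosome, position_bp, cm_per_mb,
                       allele1 = "1", allele2 = "2") {
  m <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = as.character(chromosome),
    position_bp = as.integer(position_bp),
    cm_per_mb = as.numeric(cm_per_mb),
    allele1 = as.character(allele1),
    allele2 = as.character(allele2),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(m$snp_id)) stop("duplicated SNP ids in map")
  if (any(m$position_bp < 1L, na.rm = TRUE)) stop("positions must be >= 1 (1-based)")
  if (any(m$cm_per_mb < 0, na.rm = TRUE)) stop("cm_per_mb must be >= 0")
  for (chr in unique(m$chromosome)) {
    pos <- m$position_bp[m$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("positions not strictly increasing on chromosome ", chr)
    }
  }
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Allele counts for two groups at one SNP
#'
#' The 2x2 allele-count table compared by the allelic chi-square and Fisher
#' tests: rows are groups (e.g. high vs low line), columns alleles. Row
#' totals equal twice the number of non-missing diploid samples per group.
#'
#' @param n_allele1_g1,n_allele2_g1 counts of allele1/allele2 in group 1.
#' @param n_allele1_g2,n_allele2_g2 counts in group 2.
#' @return 2x2 integer matrix of class `group_allele_counts`.
#' @export
group_allele_counts <- function(n_allele1_g1, n_allele2_g1,
                                n_allele1_g2, n_allele2_g2) {
  cnt <- c(n_allele1_g1, n_allele2_g1, n_allele1_g2, n_allele2_g2)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("allele counts must be non-negative integers")
  }
  m <- matrix(as.integer(cnt), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("g1", "g2"),
                              allele = c("allele1", "allele2")))
  class(m) <- c("group_allele_counts", class(m))
  m
}

# ---- selectors ------------------------------------------------------------

#' Select samples of a panel by line and/or generation
#'
#' @param panel a `genotype_panel`.
#' @param line optional line label ("HIGH"/"LOW").
#' @param generation optional generation.
#' @return logical vector over samples.
#' @export
panel_select <- function(panel, line = NULL, generation = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- rep(TRUE, length(panel$sample_ids))
  if (!is.null(line)) keep <- keep & panel$line %in% line
  if (!is.null(generation)) keep <- keep & panel$generation %in% generation
  keep
}

#' Per-SNP allele frequencies in a sample group
#'
#' Frequency of the reference allele (allele1) with missing-aware
#' denominators: count of allele1 divided by twice the number of non-missing
#' calls. SNPs with no non-missing call in the group get NA.
#'
#' @param panel a `genotype_panel`.
#' @param line,generation group selector passed to [panel_select()].
#' @return numeric vector of frequencies in `[0, 1]` (NA where undefined),
#'   named by SNP id.
#' @export
allele_frequencies <- function(panel, line = NULL, generation = NULL) {
  keep <- panel_select(panel, line, generation)
  if (!any(keep)) stop("empty sample group selector")
  g <- panel$genotypes[keep, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0L] <- NA_real_
  names(f) <- panel$snp_ids
  f
}

#' Classify per-SNP fixation status between two lines
#'
#' Given reference-allele frequencies in the high and low line, each SNP is
#' assigned one of five exclusive classes: `DIFF` (fixed for alternative
#' alleles), `SAME` (fixed for the same allele in both lines), `H_NOT_L`
#' (fixed in the high line only), `L_NOT_H` (fixed in the low line only) or
#' `BOTH_SEG` (segregating in both). SNPs with an undefined frequency in
#' either line are classed `UNKNOWN` and should be excluded from counts.
#'
#' @param freq_high,freq_low numeric vectors of per-SNP reference-allele
#'   frequencies (NA = undefined).
#' @return factor with levels DIFF, SAME, H_NOT_L, L_NOT_H, BOTH_SEG, UNKNOWN.
#' @examples
#' classify_fixation(c(1, 1, 1, 0.5), c(0, 1, 0.5, 0.5))
#' @export
classify_fixation <- function(freq_high, freq_low) {
  if (length(freq_high) != length(freq_low)) {
    stop("frequency vectors must have equal length")
  }
  fh <- freq_high
  fl <- freq_low
  fixed_h <- fh %in% c(0, 1)
  fixed_l <- fl %in% c(0, 1)
  cls <- rep("BOTH_SEG", length(fh))
  cls[fixed_h & !fixed_l] <- "H_NOT_L"
  cls[!fixed_h & fixed_l] <- "L_NOT_H"
  cls[fixed_h & fixed_l & fh == fl] <- "SAME"
  cls[fixed_h & fixed_l & fh != fl] <- "DIFF"
  cls[is.na(fh) | is.na(fl)] <- "UNKNOWN"
  factor(cls, levels = c("DIFF", "SAME", "H_NOT_L", "L_NOT_H",
                         "BOTH_SEG", "UNKNOWN"))
}

# ---- PED/MAP I/O ----------------------------------------------------------

sidecar_paths <- function(ped_path, map_path) {
  prefix <- sub("\\.ped$", "", ped_path)
  list(samples = paste0(prefix, ".samples.tsv"),
       chrom   = paste0(sub("\\.map$", "", map_path), ".chrom.tsv"),
       alleles = paste0(sub("\\.map$", "", map_path), ".alleles.tsv"))
}

#' Write a panel and map as PED/MAP plus sidecar tables
#'
#' Writes the PLINK text dialect (one row per sample, two allele columns per
#' SNP; MAP with chromosome, SNP id, cM, bp) plus three TSV sidecars:
#' `<prefix>.samples.tsv` (sample_id, line, generation),
#' `<prefix>.chrom.tsv` (chromosome, cm_per_mb) and
#' `<prefix>.alleles.tsv` (snp_id, allele1, allele2). Missing genotypes are
#' written as "0 0".
#'
#' @param panel a `genotype_panel`.
#' @param map a `marker_map` aligned to the panel columns.
#' @param prefix output path prefix; files `<prefix>.ped` etc. are created.
#' @return invisibly, the vector of files written.
#' @export
write_panel <- function(panel, map, prefix) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(map, "marker_map"))
  if (!identical(panel$snp_ids, map$snp_id)) {
    stop("panel SNPs and map SNPs are not aligned")
  }
  n <- length(panel$sample_ids)
  p <- length(panel$snp_ids)
  a1 <- map$allele1
  a2 <- map$allele2
  alle <- matrix("0", nrow = n, ncol = 2L * p)
  g <- panel$genotypes
  for (j in seq_len(p)) {
    d <- g[, j]
    c1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, a1[j], a2[j]))
    c2 <- ifelse(is.na(d), "0", ifelse(d == 2L, a1[j], a2[j]))
    alle[, 2L * j - 1L] <- c1
    alle[, 2L * j] <- c2
  }
  ped <- cbind(panel$sample_ids, panel$sample_ids, "0", "0", "0", "-9", alle)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cm <- map$position_bp / 1e6 * ifelse(is.na(map$cm_per_mb), 0, map$cm_per_mb)
  utils::write.table(
    data.frame(map$chromosome, map$snp_id, cm, map$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sc <- sidecar_paths(ped_path, map_path)
  utils::write.table(
    data.frame(sample_id = panel$sample_ids, line = panel$line,
               generation = panel$generation),
    sc$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  chrom <- unique(map[, c("chromosome", "cm_per_mb")])
  utils::write.table(chrom, sc$chrom, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(map[, c("snp_id", "allele1", "allele2")], sc$alleles,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped_path, map_path, sc$samples, sc$chrom, sc$alleles))
}

#' Read a panel and map from PED/MAP plus sidecar tables
#'
#' Inverse of [write_panel()]. Alleles are recoded to dosages of the map's
#' declared reference allele (allele1 in the `.alleles.tsv` sidecar); "0"
#' calls become NA. Sidecar paths are derived from the PED/MAP paths.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return a list with elements `panel` (a `genotype_panel`) and `map`
#'   (a `marker_map`).
#' @export
read_panel <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  sc <- sidecar_paths(ped_path, map_path)
  for (f in unlist(sc)) if (!file.exists(f)) stop("sidecar file not found: ", f)

  mp <- utils::read.table(map_path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chromosome", "snp_id", "cm", "bp"),
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  chrom <- utils::read.table(sc$chrom, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "numeric"))
  alleles <- utils::read.table(sc$alleles, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  if (!identical(alleles$snp_id, mp$snp_id)) {
    stop("allele sidecar SNPs do not match MAP SNPs")
  }
  ratio <- chrom$cm_per_mb[match(mp$chromosome, chrom$chromosome)]
  map <- marker_map(mp$snp_id, mp$chromosome, mp$bp, ratio,
                    alleles$allele1, alleles$allele2)

  ped <- utils::read.table(ped_path, sep = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  p <- nrow(mp)
  if (ncol(ped) != 6L + 2L * p) {
    stop("PED column count (", ncol(ped), ") does not match MAP SNP count (",
         p, "): expected ", 6L + 2L * p, " columns")
  }
  ids <- ped[[2]]
  samples <- utils::read.table(sc$samples, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  idx <- match(ids, samples$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from sample sidecar: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  n <- length(ids)
  geno <- matrix(NA_integer_, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    c1 <- ped[[6L + 2L * j - 1L]]
    c2 <- ped[[6L + 2L * j]]
    known <- c(map$allele1[j], map$allele2[j], "0")
    bad <- !(c1 %in% known) | !(c2 %in% known)
    if (any(bad)) {
      stop("unknown allele code at SNP ", map$snp_id[j], ": ",
           paste(unique(c(c1[bad], c2[bad])), collapse = ", "))
    }
    miss <- c1 == "0" | c2 == "0"
    d <- (c1 == map$allele1[j]) + (c2 == map$allele1[j])
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
  }
  panel <- genotype_panel(geno, ids, map$snp_id,
                          samples$line[idx], samples$generation[idx])
  list(panel = panel, map = map)
}
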
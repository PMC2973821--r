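test_that("panel construction validates line labels, generations and dosages", {
  g <- matrix(c(2L, 1L), nrow = 1)
  expect_s3_class(genotype_panel(g, "a", c("x", "y"), "HIGH", 40L),
                  "genotype_panel")
  expect_error(genotype_panel(g, "a", c("x", "y"), "high", 40L), "a")
  expect_error(genotype_panel(g, "a", c("x", "y"), NA, 40L), "line")
  expect_error(genotype_panel(g, "a", c("x", "y"), "HIGH", NA), "generation")
  expect_error(genotype_panel(matrix(3L), "a", "x", "HIGH", 40L), "dosage")
})

test_that("marker map requires strictly increasing positions per chromosome", {
  expect_error(marker_map(c("a", "b"), "1", c(100L, 100L), 1), "increasing")
  expect_s3_class(marker_map(c("a", "b"), c("1", "2"), c(100L, 100L), 1),
                  "marker_map")
})

test_that("PED/MAP round-trip is the identity on panels and maps", {
  panel <- tiny_panel()
  map <- tiny_map()
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_panel(panel, map, prefix)
  back <- read_panel(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_identical(unname(back$panel$genotypes), unname(panel$genotypes))
  expect_identical(back$panel$sample_ids, panel$sample_ids)
  expect_identical(back$panel$line, panel$line)
  expect_identical(back$panel$generation, panel$generation)
  expect_equal(as.data.frame(back$map), as.data.frame(map))
})

test_that("reader reports malformed inputs with the offending identifier", {
  panel <- tiny_panel()
  map <- tiny_map()
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "toy")
  write_panel(panel, map, prefix)

  # a sample absent from the line/generation sidecar is named in the error
  sc <- read.table(paste0(prefix, ".samples.tsv"), header = TRUE)
  write.table(sc[sc$sample_id != "h2", ], paste0(prefix, ".samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_panel(paste0(prefix, ".ped"), paste0(prefix, ".map")),
               "h2")
  write.table(sc, paste0(prefix, ".samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # an allele code not declared for the SNP is a parse error naming the SNP
  ped <- readLines(paste0(prefix, ".ped"))
  ped[1] <- sub("^(\\S+ \\S+ \\S+ \\S+ \\S+ \\S+) \\S+", "\\1 X", ped[1])
  writeLines(ped, paste0(prefix, ".ped"))
  expect_error(read_panel(paste0(prefix, ".ped"), paste0(prefix, ".map")),
               "s1")

  # truncated MAP -> SNP-count mismatch is a format error
  write_panel(panel, map, prefix)
  mp <- readLines(paste0(prefix, ".map"))
  writeLines(mp[1:2], paste0(prefix, ".map"))
  writeLines(readLines(paste0(prefix, ".alleles.tsv"))[1:3],
             paste0(prefix, ".alleles.tsv"))
  expect_error(read_panel(paste0(prefix, ".ped"), paste0(prefix, ".map")),
               "count")
})

test_that("generation-50 sampling of the synthetic fixture gives 49 + 10 birds", {
  ds <- generate_dataset(synth_config(n_snps = 100L, seed = 5))
  keep <- panel_select(ds$panel, generation = 50)
  expect_equal(sum(keep), 59L)
  expect_equal(sum(ds$panel$line[keep] == "HIGH"), 49L)
  expect_equal(sum(ds$panel$line[keep] == "LOW"), 10L)
})

test_that("allele frequencies use missing-aware denominators", {
  g <- matrix(rep(2L, 10), ncol = 1)
  p <- genotype_panel(g, sprintf("s%d", 1:10), "snp", rep("HIGH", 10),
                      rep(40L, 10))
  expect_equal(unname(allele_frequencies(p, "HIGH")), 1.0)

  p2 <- genotype_panel(matrix(c(0L, 1L, 2L), ncol = 1), c("a", "b", "c"),
                       "snp", rep("LOW", 3), rep(40L, 3))
  expect_equal(unname(allele_frequencies(p2)), 0.5)

  p3 <- genotype_panel(matrix(c(NA, NA, 1L), ncol = 3), "a", c("x", "y", "z"),
                       "HIGH", 40L)
  expect_equal(unname(allele_frequencies(p3)), c(NA, NA, 0.5))
  expect_error(allele_frequencies(p3, line = "LOW"), "empty")
})

test_that("allele frequencies agree with an element-wise counting oracle", {
  set.seed(42)
  for (rep in 1:5) {
    panel <- random_panel(20, 50)
    f <- allele_frequencies(panel, line = "HIGH")
    keep <- panel$line == "HIGH"
    oracle <- sapply(seq_len(50), function(j) {
      num <- 0; den <- 0
      for (i in which(keep)) {
        d <- panel$genotypes[i, j]
        if (!is.na(d)) { num <- num + d; den <- den + 2 }
      }
      if (den == 0) NA_real_ else num / den
    })
    expect_equal(unname(f), oracle)
  }
})

test_that("fixation classes follow their definitions and partition all SNPs", {
  expect_equal(as.character(classify_fixation(1, 0)), "DIFF")
  expect_equal(as.character(classify_fixation(0, 1)), "DIFF")
  expect_equal(as.character(classify_fixation(1, 1)), "SAME")
  expect_equal(as.character(classify_fixation(0, 0)), "SAME")
  expect_equal(as.character(classify_fixation(1, 0.5)), "H_NOT_L")
  expect_equal(as.character(classify_fixation(0.3, 0)), "L_NOT_H")
  expect_equal(as.character(classify_fixation(0.3, 0.6)), "BOTH_SEG")
  expect_equal(as.character(classify_fixation(NA, 1)), "UNKNOWN")

  set.seed(7)
  fh <- sample(c(0, 1, runif(50), NA), 200, replace = TRUE)
  fl <- sample(c(0, 1, runif(50), NA), 200, replace = TRUE)
  cls <- classify_fixation(fh, fl)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 200)  # exhaustive and exclusive
  expect_equal(sum(cls == "UNKNOWN"), sum(is.na(fh) | is.na(fl)))
})
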
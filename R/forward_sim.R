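# Individual-based two-locus forward simulator of one selected line.
#
# Two linked loci A (selected) and B (neutral marker) on diploid individuals
# with sexes. Selection acts on locus A with viability-style fitnesses 1,
# 1-h*s, 1-s for AA, Aa, aa and sex-specific selection coefficients; a fixed
# number of sires and dams is chosen each generation by fitness-weighted
# sampling without replacement, reproducing the pedigreed breeding scheme of
# a divergent selection experiment (12 sires x 48 dams x 6 offspring = 288).

#' Breeding scheme of a pedigreed selection line
#'
#' @param n_sires number of sires selected per generation (default 12).
#' @param n_dams number of dams (default 48); must equal
#'   `n_sires * dams_per_sire`.
#' @param dams_per_sire dams mated to each sire (default 4).
#' @param offspring_per_dam offspring per dam (default 6). Census size per
#'   generation is `n_dams * offspring_per_dam` (default 288).
#' @return object of class `breeding_scheme`.
#' @export
breeding_scheme <- function(n_sires = 12L, n_dams = 48L, dams_per_sire = 4L,
                            offspring_per_dam = 6L) {
  n_sires <- as.integer(n_sires); n_dams <- as.integer(n_dams)
  dams_per_sire <- as.integer(dams_per_sire)
  offspring_per_dam <- as.integer(offspring_per_dam)
  if (any(c(n_sires, n_dams, dams_per_sire, offspring_per_dam) < 1L)) {
    stop("all scheme counts must be >= 1")
  }
  if (n_dams != n_sires * dams_per_sire) {
    stop("n_dams must equal n_sires * dams_per_sire")
  }
  structure(list(n_sires = n_sires, n_dams = n_dams,
                 dams_per_sire = dams_per_sire,
                 offspring_per_dam = offspring_per_dam,
                 census = n_dams * offspring_per_dam),
            class = "breeding_scheme")
}

#' Sex-specific selection parameters at the selected locus
#'
#' Fitnesses of genotypes AA, Aa, aa are 1, 1-h*s and 1-s with the selection
#' coefficient s taken from `s_male` or `s_female` according to the
#' individual's sex. `h = 0.5` gives additive alleles.
#'
#' @param s_male,s_female selection coefficients, `>= 0`.
#' @param h dominance coefficient in `[0, 1]` (default 0.5, additive).
#' @return object of class `selection_params`.
#' @export
selection_params <- function(s_male = 0, s_female = 0, h = 0.5) {
  if (s_male < 0 || s_female < 0) stop("selection coefficients must be >= 0")
  if (h < 0 || h > 1) stop("h must be in [0, 1]")
  if (any(c(1 - s_male, 1 - s_female, 1 - h * s_male, 1 - h * s_female) < 0)) {
    stop("fitnesses 1-s and 1-h*s must be >= 0")
  }
  structure(list(s_male = s_male, s_female = s_female, h = h),
            class = "selection_params")
}

#' Founder haplotype frequencies as a four-digit sevenths code
#'
#' The base population is a mixture of seven fixed founder lines, so
#' haplotype frequencies are multiples of 1/7. The code "xyzw" gives x/7 of
#' haplotype AB, y/7 of Ab, z/7 of aB and w/7 of ab, with x+y+z+w = 7.
#'
#' @param code a 4-digit string (e.g. "4003") or integer vector of length 4.
#' @return object of class `hap_freqs` with element `sevenths`.
#' @examples
#' hap_freqs("4003")  # 4/7 AB, 3/7 ab
#' @export
hap_freqs <- function(code) {
  if (is.character(code)) {
    if (length(code) != 1L || !grepl("^[0-9]{4}$", code)) {
      stop("haplotype code must be 4 digits, e.g. \"4003\"")
    }
    code <- as.integer(strsplit(code, "")[[1]])
  }
  code <- as.integer(code)
  if (length(code) != 4L || anyNA(code) || any(code < 0L)) {
    stop("haplotype code must be 4 non-negative integers")
  }
  if (sum(code) != 7L) {
    stop("haplotype code digits must sum to 7 (got ", sum(code), ")")
  }
  structure(list(sevenths = code,
                 freqs = stats::setNames(code / 7, c("AB", "Ab", "aB", "ab"))),
            class = "hap_freqs")
}

# haplotype index coding: 1 = AB, 2 = Ab, 3 = aB, 4 = ab
hap_has_A <- c(TRUE, TRUE, FALSE, FALSE)
hap_has_B <- c(TRUE, FALSE, TRUE, FALSE)

draw_sexes <- function(n, n_sires, n_dams) {
  # whole-generation redraw in the (negligible) event of a parent shortage
  repeat {
    sex <- as.integer(stats::runif(n) < 0.5)  # 1 = male, 0 = female
    if (sum(sex) >= n_sires && n - sum(sex) >= n_dams) return(sex)
  }
}

#' Initialise a founder population
#'
#' Each of the `2 * census` founder haplotypes is drawn i.i.d. from the
#' code's distribution; sexes are i.i.d. Bernoulli(1/2) (redrawn as a whole
#' in the negligible event that a sex has fewer members than the scheme
#' requires).
#'
#' @param freqs a [hap_freqs()] object (or a code accepted by it).
#' @param scheme a [breeding_scheme()].
#' @param seed optional integer seed for reproducibility.
#' @return object of class `sim_population`: vectors `A1`, `A2`, `B1`, `B2`
#'   (1 = allele A resp. B on haplotype 1/2), `sex` (1 male, 0 female) and
#'   `generation = 0`.
#' @export
init_population <- function(freqs, scheme = breeding_scheme(), seed = NULL) {
  if (!inherits(freqs, "hap_freqs")) freqs <- hap_freqs(freqs)
  stopifnot(inherits(scheme, "breeding_scheme"))
  if (!is.null(seed)) set.seed(seed)
  n <- scheme$census
  h1 <- sample.int(4L, n, replace = TRUE, prob = freqs$freqs)
  h2 <- sample.int(4L, n, replace = TRUE, prob = freqs$freqs)
  structure(list(
    A1 = as.integer(hap_has_A[h1]), A2 = as.integer(hap_has_A[h2]),
    B1 = as.integer(hap_has_B[h1]), B2 = as.integer(hap_has_B[h2]),
    sex = draw_sexes(n, scheme$n_sires, scheme$n_dams),
    generation = 0L), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  n <- length(x$A1)
  cat("sim_population: ", n, " individuals (",
      sum(x$sex), " males), generation ", x$generation, "\n", sep = "")
  cat(sprintf("freq(A) = %.3f, freq(B) = %.3f\n",
              mean(x$A1 + x$A2) / 2, mean(x$B1 + x$B2) / 2))
  invisible(x)
}

weighted_parents <- function(idx, w, k, sex_label) {
  if (length(idx) < k) {
    stop("fewer eligible ", sex_label, "s (", length(idx),
         ") than required (", k, ")")
  }
  if (sum(w[idx] > 0) < k) {
    stop("fewer ", sex_label, "s with positive fitness (", sum(w[idx] > 0),
         ") than required (", k, ")")
  }
  if (length(idx) == 1L) return(idx)
  sample(idx, k, prob = w[idx])
}

#' Advance the population one generation
#'
#' Parents are chosen within each sex by fitness-weighted sampling without
#' replacement (fitness from the locus-A genotype with that sex's selection
#' coefficient); dams are partitioned uniformly at random among sires at
#' `dams_per_sire` each; every dam produces `offspring_per_dam` offspring.
#' Each gamete is one of the parent's two haplotypes with the locus-B allele
#' swapped onto the other haplotype with probability `r` (recombination).
#'
#' @param pop a `sim_population`.
#' @param scheme a [breeding_scheme()].
#' @param sel a [selection_params()].
#' @param r recombination fraction between loci A and B, in `[0, 0.5]`.
#' @return the next `sim_population` (census unchanged).
#' @export
step_generation <- function(pop, scheme = breeding_scheme(),
                            sel = selection_params(), r = 0) {
  stopifnot(inherits(pop, "sim_population"),
            inherits(scheme, "breeding_scheme"),
            inherits(sel, "selection_params"))
  if (r < 0 || r > 0.5) stop("r must be in [0, 0.5]")
  nA <- pop$A1 + pop$A2  # copies of allele A: fitness 1-s, 1-hs, 1 for 0,1,2
  w_m <- c(1 - sel$s_male, 1 - sel$h * sel$s_male, 1)[nA + 1L]
  w_f <- c(1 - sel$s_female, 1 - sel$h * sel$s_female, 1)[nA + 1L]
  sires <- weighted_parents(which(pop$sex == 1L), w_m, scheme$n_sires, "male")
  dams <- weighted_parents(which(pop$sex == 0L), w_f, scheme$n_dams, "female")
  sire_of_dam <- sample(rep(sires, each = scheme$dams_per_sire))
  n_off <- scheme$census
  mo <- rep(dams, each = scheme$offspring_per_dam)
  fa <- rep(sire_of_dam, each = scheme$offspring_per_dam)
  gamete <- function(par) {
    h <- sample.int(2L, n_off, replace = TRUE)
    a <- ifelse(h == 1L, pop$A1[par], pop$A2[par])
    hb <- ifelse(stats::runif(n_off) < r, 3L - h, h)
    b <- ifelse(hb == 1L, pop$B1[par], pop$B2[par])
    list(a = a, b = b)
  }
  gm <- gamete(mo)
  gf <- gamete(fa)
  structure(list(
    A1 = gm$a, A2 = gf$a, B1 = gm$b, B2 = gf$b,
    sex = draw_sexes(n_off, scheme$n_sires, scheme$n_dams),
    generation = pop$generation + 1L), class = "sim_population")
}

locus_state <- function(a1, a2) {
  s <- sum(a1) + sum(a2)
  if (s == 0L) "fixed_alt" else if (s == 2L * length(a1)) "fixed_ref" else "seg"
}

#' Run replicate forward simulations
#'
#' Runs `n_rep` independent replicates of the selected line for up to
#' `max_gen` generations, recording for each replicate the generation of
#' fixation (all individuals homozygous for the same allele) and the fixed
#' allele at the selected locus A and at the linked neutral locus B. A
#' replicate stops early once both loci are fixed (the population can no
#' longer change).
#'
#' @param freqs founder [hap_freqs()] (or code).
#' @param scheme a [breeding_scheme()].
#' @param sel a [selection_params()].
#' @param r recombination fraction between A and B.
#' @param n_rep number of replicates.
#' @param max_gen maximum generations simulated.
#' @param seed integer seed; replicates are consumed sequentially from one
#'   seeded stream, so results are reproducible.
#' @return object of class `sim_outcome`: `replicates` data.frame (one row
#'   per replicate with `fix_gen_A`, `allele_A`, `fix_gen_B`, `allele_B`,
#'   NA where no fixation occurred) and `summary` list with `prop_fixed_A`,
#'   `first_fixation_gen`, `gen_10pct` (first generation with >= 10% of
#'   replicates fixed at A), `prop_selected_allele` (share of A-fixed
#'   replicates fixed for allele A) and `prop_fixed_by` (cumulative
#'   proportion fixed at A by each generation).
#' @export
run_replicates <- function(freqs, scheme = breeding_scheme(),
                           sel = selection_params(), r = 0,
                           n_rep = 1000L, max_gen = 40L, seed = NULL) {
  if (!inherits(freqs, "hap_freqs")) freqs <- hap_freqs(freqs)
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fix_gen_A <- rep(NA_integer_, n_rep)
  allele_A <- rep(NA_character_, n_rep)
  fix_gen_B <- rep(NA_integer_, n_rep)
  allele_B <- rep(NA_character_, n_rep)
  for (i in seq_len(n_rep)) {
    pop <- init_population(freqs, scheme)
    stA <- locus_state(pop$A1, pop$A2)
    stB <- locus_state(pop$B1, pop$B2)
    if (stA != "seg") { fix_gen_A[i] <- 0L; allele_A[i] <- if (stA == "fixed_ref") "A" else "a" }
    if (stB != "seg") { fix_gen_B[i] <- 0L; allele_B[i] <- if (stB == "fixed_ref") "B" else "b" }
    g <- 0L
    while (g < max_gen && (is.na(fix_gen_A[i]) || is.na(fix_gen_B[i]))) {
      pop <- step_generation(pop, scheme, sel, r)
      g <- g + 1L
      if (is.na(fix_gen_A[i])) {
        stA <- locus_state(pop$A1, pop$A2)
        if (stA != "seg") {
          fix_gen_A[i] <- g
          allele_A[i] <- if (stA == "fixed_ref") "A" else "a"
        }
      }
      if (is.na(fix_gen_B[i])) {
        stB <- locus_state(pop$B1, pop$B2)
        if (stB != "seg") {
          fix_gen_B[i] <- g
          allele_B[i] <- if (stB == "fixed_ref") "B" else "b"
        }
      }
    }
  }
  prop_by <- vapply(seq_len(max_gen), function(g)
    mean(!is.na(fix_gen_A) & fix_gen_A <= g), numeric(1))
  fixed <- !is.na(fix_gen_A)
  g10 <- which(prop_by >= 0.10)[1]
  structure(list(
    replicates = data.frame(rep = seq_len(n_rep), fix_gen_A = fix_gen_A,
                            allele_A = allele_A, fix_gen_B = fix_gen_B,
                            allele_B = allele_B,
                            stringsAsFactors = FALSE),
    summary = list(
      n_rep = n_rep, max_gen = as.integer(max_gen),
      prop_fixed_A = mean(fixed),
      first_fixation_gen = if (any(fixed)) min(fix_gen_A[fixed]) else NA_integer_,
      gen_10pct = if (is.na(g10)) NA_integer_ else as.integer(g10),
      prop_selected_allele = if (any(fixed)) mean(allele_A[fixed] == "A") else NA_real_,
      prop_fixed_by = prop_by)),
    class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  s <- x$summary
  cat("sim_outcome over", s$n_rep, "replicates,", s$max_gen, "generations\n")
  cat(sprintf("  fixed at A: %.1f%% | first fixation: gen %s | 10%% fixation: gen %s\n",
              100 * s$prop_fixed_A,
              ifelse(is.na(s$first_fixation_gen), "-", s$first_fixation_gen),
              ifelse(is.na(s$gen_10pct), "-", s$gen_10pct)))
  invisible(x)
}

#' Neutral per-allele fixation probabilities in one line
#'
#' Runs the simulator with selection switched off and estimates the
#' probability that allele A (resp. a) is fixed within `max_gen` generations,
#' with binomial Monte-Carlo standard errors.
#'
#' @inheritParams run_replicates
#' @return list with `p_fix_A`, `p_fix_a`, `se_A`, `se_a`, `n_rep`, and the
#'   underlying `sim_outcome` as `outcome`.
#' @export
neutral_fixation_probabilities <- function(freqs, scheme = breeding_scheme(),
                                           n_rep = 1000L, max_gen = 40L,
                                           seed = NULL) {
  out <- run_replicates(freqs, scheme, selection_params(0, 0), r = 0,
                        n_rep = n_rep, max_gen = max_gen, seed = seed)
  fixed_A <- !is.na(out$replicates$fix_gen_A) & out$replicates$allele_A == "A"
  fixed_a <- !is.na(out$replicates$fix_gen_A) & out$replicates$allele_A == "a"
  pA <- mean(fixed_A); pa <- mean(fixed_a)
  list(p_fix_A = pA, p_fix_a = pa,
       se_A = sqrt(pA * (1 - pA) / n_rep),
       se_a = sqrt(pa * (1 - pa) / n_rep),
       n_rep = n_rep, outcome = out)
}
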
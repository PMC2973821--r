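# Quantitative-genetic estimators: selection intensity and coefficients,
# effective population size, Otto-Jones estimation of the number of trait
# loci, and drift-versus-selection fixation attribution.

#' Selection intensity from the proportion selected
#'
#' Mean phenotypic superiority of truncation-selected parents in phenotypic
#' standard deviation units, computed analytically from the standard normal
#' distribution: `i = phi(z) / p` where `z` is the upper-`p` quantile.
#'
#' @param p_selected proportion of candidates selected, in (0, 1).
#' @return selection intensity `i` (SD units).
#' @examples
#' selection_intensity(0.5)  # ~0.798
#' @export
selection_intensity <- function(p_selected) {
  if (any(p_selected <= 0 | p_selected >= 1)) {
    stop("p_selected must be in (0, 1)")
  }
  z <- stats::qnorm(p_selected, lower.tail = FALSE)
  stats::dnorm(z) / p_selected
}

#' Selection coefficient of a QTL from its effect and the selection intensity
#'
#' `s = i * 2a / sigma`: the fitness deficit of the disfavoured homozygote
#' implied by truncation selection of intensity `i` on a trait with
#' phenotypic SD `sigma` at a locus of additive effect `a`. Values above
#' `cap` (fitness `1 - s` would go negative beyond 1) are capped with a
#' warning.
#'
#' @param a additive effect in trait units.
#' @param sigma phenotypic standard deviation in trait units, > 0.
#' @param i selection intensity (SD units), >= 0.
#' @param cap maximum returned value (default 1).
#' @return selection coefficient `s`.
#' @export
selection_coefficient <- function(a, sigma, i, cap = 1) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(i < 0)) stop("selection intensity must be >= 0")
  s <- i * 2 * a / sigma
  if (any(s > cap)) {
    warning("selection coefficient ", paste(signif(s[s > cap], 3),
            collapse = ", "), " capped at ", cap)
    s <- pmin(s, cap)
  }
  s
}

#' Effective population size from parent counts
#'
#' `Ne = 4 Nm Nf / (Nm + Nf)` for unequal numbers of male and female
#' parents (equivalently, twice the harmonic mean of `2 Nm` and `2 Nf`).
#'
#' @param n_males,n_females numbers of sires and dams, > 0.
#' @return effective population size.
#' @examples
#' ne_from_parents(12, 48)  # 38.4
#' @export
ne_from_parents <- function(n_males, n_females) {
  if (any(n_males <= 0) || any(n_females <= 0)) {
    stop("parent counts must be > 0")
  }
  4 * n_males * n_females / (n_males + n_females)
}

#' Harmonic-mean effective size over epochs
#'
#' `Ne = total_generations / sum(n_g / Ne_g)` over epochs of `n_g`
#' generations with epoch effective size `Ne_g`. The numerator defaults to
#' the sum of the epoch lengths but can be set explicitly.
#'
#' @param n_generations integer vector of epoch lengths (each >= 1).
#' @param ne positive numeric vector of epoch effective sizes.
#' @param total_generations numerator of the harmonic mean (default
#'   `sum(n_generations)`).
#' @return harmonic-mean effective size.
#' @examples
#' harmonic_ne(c(4, 26, 15), c(27.43, 38.40, 44.80),
#'             total_generations = 40)  # 34.55
#' @export
harmonic_ne <- function(n_generations, ne,
                        total_generations = sum(n_generations)) {
  if (!length(ne)) stop("no epochs given")
  if (length(n_generations) != length(ne)) {
    stop("n_generations and ne must have equal length")
  }
  if (any(n_generations < 1)) stop("epoch lengths must be >= 1")
  if (any(ne <= 0)) stop("all epoch Ne must be > 0")
  total_generations / sum(n_generations / ne)
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Otto-Jones estimate of the number of loci determining a trait
#'
#' From the detected QTL of an intercross between divergent lines, the
#' detection threshold is approximated as
#' `T = (a_min * n_d - M) / (n_d - 1)` and the total number of loci as
#' `n = D / (M - T)`, where `D` is half the parental-line phenotypic
#' difference, `M` the mean additive effect of the `n_d` detected loci and
#' `a_min` the smallest detected effect (all in trait units).
#'
#' @param D half the difference between the parental line means.
#' @param M mean additive effect of detected loci, > 0.
#' @param a_min smallest detected additive effect.
#' @param n_d number of detected loci, >= 2.
#' @return list with `T` (threshold), `n_raw` and `n` (rounded half away
#'   from zero).
#' @examples
#' otto_jones(D = 670.5, M = 37.9, a_min = 34.2, n_d = 3)  # 121 loci
#' @export
otto_jones <- function(D, M, a_min, n_d) {
  if (n_d < 2) stop("n_d must be >= 2")
  if (M <= 0) stop("M must be > 0")
  T_thr <- (a_min * n_d - M) / (n_d - 1)
  if (M <= T_thr) {
    stop("estimator undefined: mean detected effect M (", M,
         ") does not exceed threshold T (", signif(T_thr, 4), ")")
  }
  n_raw <- D / (M - T_thr)
  list(T = T_thr, n_raw = n_raw, n = round_half_up(n_raw))
}

#' Attribute observed alternative-allele fixations to drift vs selection
#'
#' Under pure drift, a locus ends fixed for different alleles in two
#' independent lines with probability `2 * p_fix_A * p_fix_a` (per-line
#' fixation probabilities of the two alleles). Multiplying by the number of
#' scored SNPs gives the expected count of drift-caused alternative
#' fixations; the excess of the observed count is attributed to selection.
#'
#' @param n_snps number of SNPs scored.
#' @param p_fix_A,p_fix_a per-line probabilities of fixation of each allele
#'   within the experiment, in `[0, 1]`.
#' @param observed_diff observed count of SNPs fixed for alternative
#'   alleles, `<= n_snps`.
#' @return list with `p_diff_drift`, `expected_drift_fixations` and
#'   `fraction_selection` (`max(0, (observed - expected) / observed)`; NA
#'   when `observed_diff` is 0).
#' @examples
#' drift_attribution(56000, 0.038, 0.094, 998)
#' @export
drift_attribution <- function(n_snps, p_fix_A, p_fix_a, observed_diff) {
  if (any(c(p_fix_A, p_fix_a) < 0) || any(c(p_fix_A, p_fix_a) > 1)) {
    stop("fixation probabilities must be in [0, 1]")
  }
  if (observed_diff > n_snps) stop("observed_diff cannot exceed n_snps")
  p_diff <- 2 * p_fix_A * p_fix_a
  expected <- n_snps * p_diff
  frac <- if (observed_diff == 0) NA_real_ else
    max(0, (observed_diff - expected) / observed_diff)
  list(p_diff_drift = p_diff,
       expected_drift_fixations = expected,
       fraction_selection = frac)
}

#' Expected fixation fractions under uniformly distributed start frequencies
#'
#' Given per-starting-frequency-pair probabilities of same-allele and
#' different-allele fixation under drift, returns the expectation under a
#' uniform distribution over the founder frequencies (multiples of 1/7).
#' The three unordered pairs (1/7, 6/7), (2/7, 5/7), (3/7, 4/7) cover all
#' six equally likely configurations by symmetry, so the expectation is the
#' unweighted mean of the per-pair values.
#'
#' @param pairs data.frame with columns `p1`, `p2` (the pair, in sevenths or
#'   as fractions), `p_same` and `p_diff`. All three symmetric pairs must be
#'   present.
#' @return list with `expected_same` and `expected_diff` (same scale as the
#'   inputs).
#' @examples
#' uniform_start_expectation(data.frame(
#'   p1 = c(3, 2, 1) / 7, p2 = c(4, 5, 6) / 7,
#'   p_same = c(1, 6, 27), p_diff = c(0.7, 0.4, 0.2)))
#' @export
uniform_start_expectation <- function(pairs) {
  req <- c("p1", "p2", "p_same", "p_diff")
  if (!all(req %in% names(pairs))) {
    stop("pairs must have columns ", paste(req, collapse = ", "))
  }
  p1 <- pairs$p1; p2 <- pairs$p2
  if (all(p1 == round(p1)) && all(p2 == round(p2))) {  # given in sevenths
    p1 <- p1 / 7; p2 <- p2 / 7
  }
  key <- paste(pmin(p1, p2) * 7, pmax(p1, p2) * 7)
  need <- c("1 6", "2 5", "3 4")
  if (!setequal(unique(key), need) || anyDuplicated(key)) {
    stop("pairs must cover exactly the starting pairs ",
         "(1/7,6/7), (2/7,5/7), (3/7,4/7)")
  }
  list(expected_same = mean(pairs$p_same),
       expected_diff = mean(pairs$p_diff))
}
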
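# Pairwise fixation-index (F_ST) estimation from allele frequencies.
#
# Three estimators are exposed:
#   variance_ratio  F_ST = sigma2_S / sigma2_T with sigma2_S the
#                   (population, divide-by-2) variance of the two group
#                   frequencies, (p_a - p_b)^2 / 4, and sigma2_T =
#                   pbar (1 - pbar): the literal variance-in-subpopulations
#                   over variance-in-total form.
#   hudson          (p_a - p_b)^2 / (p_a (1 - p_b) + p_b (1 - p_a)), the
#                   standard two-population frequency estimator; the
#                   pipeline default for thresholding.
#   weir_cockerham  The sample-size-corrected two-population ANOVA
#                   estimator on called allele counts; may be slightly
#                   negative at low differentiation (raw value retained,
#                   floor at 0 when thresholding).
#
# All estimators return 0 for the degenerate case of equal fixed
# frequencies (both 0 or both 1), where the denominator vanishes.

FST_ESTIMATORS <- c("hudson", "variance_ratio", "weir_cockerham")

# Vectorized numerator/denominator components; value = num/den with 0/0 -> 0.
fst_components <- function(p_a, p_b, estimator, n_a = NULL, n_b = NULL) {
  if (any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1, na.rm = TRUE) ||
      any(is.na(p_a) | is.na(p_b))) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (estimator == "variance_ratio") {
    pbar <- (p_a + p_b) / 2
    num <- (p_a - p_b)^2 / 4
    den <- pbar * (1 - pbar)
  } else if (estimator == "hudson") {
    num <- (p_a - p_b)^2
    den <- p_a * (1 - p_b) + p_b * (1 - p_a)
  } else if (estimator == "weir_cockerham") {
    if (is.null(n_a) || is.null(n_b)) {
      stop("weir_cockerham requires called allele counts n_a and n_b",
           call. = FALSE)
    }
    if (any(n_a < 2 | n_b < 2)) {
      stop("weir_cockerham requires at least 2 called alleles per group",
           call. = FALSE)
    }
    n_tot <- n_a + n_b
    n_c <- n_tot - (n_a^2 + n_b^2) / n_tot
    pbar <- (n_a * p_a + n_b * p_b) / n_tot
    msp <- n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2
    msg <- (n_a * p_a * (1 - p_a) + n_b * p_b * (1 - p_b)) / (n_tot - 2)
    num <- msp - msg
    den <- msp + (n_c - 1) * msg
  } else {
    stop("unknown estimator: ", estimator, call. = FALSE)
  }
  value <- ifelse(den > 0, num / den, 0)
  list(num = num, den = den, value = value)
}

#' Pairwise F_ST between two populations from allele frequencies
#'
#' @param p_a,p_b Effect-allele frequencies of the two populations, in
#'   `[0, 1]`.
#' @param estimator One of `"hudson"` (default), `"variance_ratio"`,
#'   `"weir_cockerham"`.
#' @param n_a,n_b Called allele counts per population; required for
#'   `weir_cockerham` only.
#' @param dbsnp_id,pop_a,pop_b Optional labels carried into the result.
#' @return A one-row tibble with columns `dbsnp_id`, `pop_a`, `pop_b`,
#'   `estimator`, `value`, `sigma2_s` and `sigma2_t` (the estimator's
#'   numerator and denominator components, so `value = sigma2_s / sigma2_t`
#'   whenever `sigma2_t > 0`).
#' @export
#' @examples
#' pairwise_fst(0.11, 0.82, "variance_ratio")  # value 0.5066
#' pairwise_fst(0.11, 0.82, "hudson")          # value 0.6725
#' pairwise_fst(0.0, 1.0, "variance_ratio")    # fixed difference: 1
pairwise_fst <- function(p_a, p_b, estimator = FST_ESTIMATORS,
                         n_a = NULL, n_b = NULL, dbsnp_id = NA_character_,
                         pop_a = NA_character_, pop_b = NA_character_) {
  estimator <- match.arg(estimator)
  cmp <- fst_components(p_a, p_b, estimator, n_a, n_b)
  tibble::tibble(
    dbsnp_id = dbsnp_id, pop_a = pop_a, pop_b = pop_b,
    estimator = estimator, value = cmp$value,
    sigma2_s = cmp$num, sigma2_t = cmp$den
  )
}

# Coerce a one-row SuperpopFrequencies tibble / named vector to a named
# frequency vector over the superpopulation codes present (ALL excluded).
superpop_freq_vector <- function(freqs) {
  if (is.data.frame(freqs)) {
    if (nrow(freqs) != 1) {
      stop("expected a single frequency record (one row)", call. = FALSE)
    }
    pops <- intersect(SUPERPOPS, names(freqs))
    out <- setNames(as.numeric(unlist(freqs[1, pops])), pops)
  } else {
    pops <- intersect(SUPERPOPS, names(freqs))
    out <- freqs[pops]
  }
  out <- out[!is.na(out)]
  if (length(out) < 2) {
    stop("need frequencies for at least 2 superpopulations", call. = FALSE)
  }
  out
}

superpop_count_vector <- function(freqs, pops) {
  if (is.data.frame(freqs)) {
    cols <- paste0("n_", pops)
    if (all(cols %in% names(freqs))) {
      return(setNames(as.numeric(unlist(freqs[1, cols])), pops))
    }
  }
  NULL
}

#' All pairwise F_ST values among the superpopulations of one SNP
#'
#' Evaluates [pairwise_fst()] over every unordered pair of superpopulation
#' codes present (the pooled `ALL` group is excluded from pairing). The
#' result is symmetric by construction; pairs are reported once with
#' `pop_a < pop_b` lexicographically.
#'
#' @param freqs A one-row frequency record (tibble with columns named by
#'   superpopulation code, e.g. from [load_frequency_table()]) or a named
#'   numeric vector of frequencies. For `weir_cockerham`, allele counts are
#'   taken from `n_<code>` columns.
#' @inheritParams pairwise_fst
#' @return A tibble with one row per pair (10 rows for all five codes).
#' @export
fst_matrix <- function(freqs, estimator = FST_ESTIMATORS) {
  estimator <- match.arg(estimator)
  p <- superpop_freq_vector(freqs)
  n <- superpop_count_vector(freqs, names(p))
  id <- if (is.data.frame(freqs) && "dbsnp_id" %in% names(freqs)) {
    freqs$dbsnp_id[1]
  } else {
    NA_character_
  }
  pairs <- combn(sort(names(p)), 2)
  a <- pairs[1, ]
  b <- pairs[2, ]
  cmp <- fst_components(p[a], p[b], estimator,
                        if (is.null(n)) NULL else n[a],
                        if (is.null(n)) NULL else n[b])
  tibble::tibble(
    dbsnp_id = id, pop_a = a, pop_b = b, estimator = estimator,
    value = unname(cmp$value), sigma2_s = unname(cmp$num),
    sigma2_t = unname(cmp$den)
  )
}

#' Maximal pairwise F_ST over the superpopulations of one SNP
#'
#' Returns the superpopulation pair attaining the largest F_ST; this
#' maximum decides membership in the differentiation screen of the
#' prioritization pipeline. Ties are broken by lexicographic order of
#' `(pop_a, pop_b)`.
#'
#' @inheritParams fst_matrix
#' @return A one-row tibble in the [pairwise_fst()] layout.
#' @export
#' @examples
#' vdr <- c(AFR = 0.11, AMR = 0.82, EAS = 0.60, EUR = 0.77, SAS = 0.64)
#' max_pairwise_fst(vdr, "hudson")  # AFR-AMR, 0.6725
max_pairwise_fst <- function(freqs, estimator = FST_ESTIMATORS) {
  estimator <- match.arg(estimator)
  m <- fst_matrix(freqs, estimator)
  m <- m[order(m$pop_a, m$pop_b, method = "radix"), , drop = FALSE]
  m[which.max(m$value), , drop = FALSE]
}

#' Mean F_ST across loci by the ratio-of-averages
#'
#' Combines per-locus estimator components as
#' `sum(numerators) / sum(denominators)` rather than averaging per-locus
#' ratios, the standard way to summarize F_ST over many loci (per-locus
#' ratios are noisy and their mean is biased). For the Hudson estimator
#' this recovers the generating differentiation of a Balding-Nichols
#' population without bias.
#'
#' @param p_a,p_b Vectors of per-locus allele frequencies for the two
#'   populations.
#' @inheritParams pairwise_fst
#' @return A single F_ST value.
#' @export
mean_fst <- function(p_a, p_b, estimator = FST_ESTIMATORS,
                     n_a = NULL, n_b = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(length(p_a) == length(p_b))
  cmp <- fst_components(p_a, p_b, estimator, n_a, n_b)
  den <- sum(cmp$den)
  if (den <= 0) return(0)
  sum(cmp$num) / den
}
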
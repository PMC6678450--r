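# Annotation quality gate and database summary statistics.
#
# A curated finding is retained when its significance passes the study-type
# threshold (candidate-gene: p < 0.05; GWAS: p < 5e-8, the genome-wide
# Bonferroni convention) AND its odds ratio falls strictly outside a null
# band around OR = 1 (default [0.97, 1.03]) -- an OR that close to 1 cannot
# evidence an association. All comparisons are strict: p = 0.05 fails,
# OR = 0.97 fails.

#' Quality-gate thresholds for curated gene-diet interaction findings
#'
#' @param candidate_p_max Significance threshold for candidate-gene studies
#'   (default 0.05; a record passes when `p < candidate_p_max`).
#' @param gwas_p_max Genome-wide significance threshold for GWAS findings
#'   (default `5e-8`).
#' @param or_null_band Closed interval of odds ratios treated as
#'   indistinguishable from the null; a record passes only when its OR lies
#'   strictly outside it. Default `c(0.97, 1.03)`.
#' @return An object of class `quality_criteria`.
#' @export
#' @examples
#' quality_criteria()
quality_criteria <- function(candidate_p_max = 0.05, gwas_p_max = 5e-8,
                             or_null_band = c(0.97, 1.03)) {
  stopifnot(
    length(candidate_p_max) == 1, length(gwas_p_max) == 1,
    length(or_null_band) == 2,
    gwas_p_max > 0, gwas_p_max < candidate_p_max, candidate_p_max <= 1,
    or_null_band[1] > 0, or_null_band[1] <= or_null_band[2],
    or_null_band[1] <= 1, or_null_band[2] >= 1
  )
  structure(
    list(candidate_p_max = candidate_p_max, gwas_p_max = gwas_p_max,
         or_null_band = or_null_band),
    class = "quality_criteria"
  )
}

#' @export
print.quality_criteria <- function(x, ...) {
  cat("Quality criteria for curated gene-diet findings\n")
  cat(sprintf("  candidate-gene studies: p < %g\n", x$candidate_p_max))
  cat(sprintf("  GWAS:                   p < %g\n", x$gwas_p_max))
  cat(sprintf("  OR null band:           [%g, %g] (excluded)\n",
              x$or_null_band[1], x$or_null_band[2]))
  invisible(x)
}

validate_gate_inputs <- function(p_value, odds_ratio, study_type) {
  if (any(is.na(p_value)) || any(p_value <= 0) || any(p_value > 1)) {
    stop("p_value must lie in (0, 1]", call. = FALSE)
  }
  if (any(is.na(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds_ratio must be positive", call. = FALSE)
  }
  if (any(is.na(study_type)) || !all(study_type %in% STUDY_TYPES)) {
    stop("study_type must be 'candidate' or 'gwas'", call. = FALSE)
  }
}

#' Does a curated finding pass the annotation quality gate?
#'
#' Vectorized over records: `TRUE` iff the p-value beats the study-type
#' threshold (strict) and the odds ratio lies strictly outside the null
#' band.
#'
#' @param p_value Reported p-value(s) in `(0, 1]`.
#' @param odds_ratio Reported odds ratio(s), positive.
#' @param study_type `"candidate"` or `"gwas"` per record.
#' @param criteria A [quality_criteria()] object.
#' @return Logical vector, one element per record.
#' @export
#' @examples
#' passes_quality(0.002, 0.62, "candidate")  # significant protective finding
#' passes_quality(0.04, 1.00, "candidate")   # OR = 1: no association
#' passes_quality(1e-6, 1.5, "gwas")         # not genome-wide significant
passes_quality <- function(p_value, odds_ratio, study_type,
                           criteria = quality_criteria()) {
  n <- max(length(p_value), length(odds_ratio), length(study_type))
  p_value <- rep_len(p_value, n)
  odds_ratio <- rep_len(odds_ratio, n)
  study_type <- rep_len(study_type, n)
  validate_gate_inputs(p_value, odds_ratio, study_type)
  p_max <- ifelse(study_type == "gwas", criteria$gwas_p_max,
                  criteria$candidate_p_max)
  outside_band <- odds_ratio < criteria$or_null_band[1] |
    odds_ratio > criteria$or_null_band[2]
  p_value < p_max & outside_band
}

#' Classify a passing odds ratio as a risk or protective effect
#'
#' A record that passed the gate has its OR strictly outside the null band:
#' above the band it increases phenotype risk, below it is protective.
#' ORs inside the band signal a record that should have been filtered and
#' raise an error.
#'
#' @param odds_ratio Odds ratio(s) strictly outside the null band.
#' @inheritParams passes_quality
#' @return Character vector of `"risk"` / `"protective"`.
#' @export
#' @examples
#' classify_effect(c(0.62, 2.17))
classify_effect <- function(odds_ratio, criteria = quality_criteria()) {
  if (any(is.na(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds_ratio must be positive", call. = FALSE)
  }
  band <- criteria$or_null_band
  inside <- odds_ratio >= band[1] & odds_ratio <= band[2]
  if (any(inside)) {
    stop("odds ratio(s) inside the null band [", band[1], ", ", band[2],
         "] cannot be classified (record should have been filtered): ",
         paste(odds_ratio[inside], collapse = ", "), call. = FALSE)
  }
  ifelse(odds_ratio > band[2], "risk", "protective")
}

#' Apply the quality gate to an annotation table
#'
#' Filters a loaded annotation table to the records passing
#' [passes_quality()] and fills their `effect_class` via
#' [classify_effect()].
#'
#' @param annotations Annotation tibble (see [load_annotations()]).
#' @inheritParams passes_quality
#' @return The passing subset with `effect_class` populated.
#' @export
apply_quality_gate <- function(annotations, criteria = quality_criteria()) {
  keep <- passes_quality(annotations$p_value, annotations$odds_ratio,
                         annotations$study_type, criteria)
  out <- annotations[keep, , drop = FALSE]
  out$effect_class <- if (nrow(out) > 0) {
    classify_effect(out$odds_ratio, criteria)
  } else {
    character(0)
  }
  out
}

#' Summary statistics over a curated annotation store
#'
#' Computes the construction statistics of the curation database: counts of
#' source articles (distinct PubMed ids), annotation entries, phenotypes,
#' genes and unique SNPs (distinct dbSNP ids); risk/protective counts with
#' the risk percentage (over classified entries); ranges and means of the
#' odds ratios, p-values and participant counts; and, when a suggestion
#' table is supplied, the number of distinct diet items.
#'
#' An empty store yields a summary with all counts zero and `NA` ranges,
#' not an error. The stored `risk_percent` is exact; displays round it
#' half-up to the nearest integer (see `print()`).
#'
#' @param annotations Annotation tibble, `effect_class` already assigned for
#'   classified records.
#' @param suggestions Optional suggestion tibble used only for the
#'   diet-type count.
#' @return An object of class `database_summary` (a named list).
#' @export
#' @examples
#' store <- simulate_annotations(simulation_config(annotation_n = 50, seed = 7))
#' summarize_annotations(apply_quality_gate(store$annotations),
#'                       store$suggestions)
summarize_annotations <- function(annotations, suggestions = NULL) {
  n <- nrow(annotations)
  n_risk <- sum(annotations$effect_class == "risk", na.rm = TRUE)
  n_prot <- sum(annotations$effect_class == "protective", na.rm = TRUE)
  rng <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) c(NA_real_, NA_real_, NA_real_)
    else c(min(x), max(x), mean(x))
  }
  or_s <- if (n > 0) rng(annotations$odds_ratio) else rep(NA_real_, 3)
  p_s <- if (n > 0) rng(annotations$p_value) else rep(NA_real_, 3)
  pa_s <- if (n > 0) rng(annotations$n_participants) else rep(NA_real_, 3)
  structure(list(
    n_articles = if (n > 0) dplyr::n_distinct(annotations$pubmed_id) else 0L,
    n_annotations = n,
    n_phenotypes = if (n > 0) dplyr::n_distinct(annotations$phenotype) else 0L,
    n_genes = if (n > 0) dplyr::n_distinct(annotations$gene) else 0L,
    n_unique_snps = if (n > 0) dplyr::n_distinct(annotations$dbsnp_id) else 0L,
    n_protective = n_prot,
    n_risk = n_risk,
    risk_percent = if (n_risk + n_prot > 0) 100 * n_risk / (n_risk + n_prot)
                   else NA_real_,
    or_min = or_s[1], or_max = or_s[2], or_mean = or_s[3],
    p_min = p_s[1], p_max = p_s[2], p_mean = p_s[3],
    n_diet_types = if (!is.null(suggestions))
                     dplyr::n_distinct(suggestions$item) else NA_integer_,
    participants_min = pa_s[1], participants_max = pa_s[2],
    participants_mean = pa_s[3]
  ), class = "database_summary")
}

#' @export
print.database_summary <- function(x, ...) {
  fmt_rng <- function(lo, hi, avg) {
    if (is.na(lo)) "-" else sprintf("%g-%g (%g)", lo, hi, signif(avg, 4))
  }
  cat("Statistics for construction of the nutrigenetic database\n")
  cat(sprintf("  Articles            %d\n", x$n_articles))
  cat(sprintf("  Annotations         %d\n", x$n_annotations))
  cat(sprintf("  Phenotypes          %d\n", x$n_phenotypes))
  cat(sprintf("  Genes               %d\n", x$n_genes))
  cat(sprintf("  SNPs                %d\n", x$n_unique_snps))
  cat(sprintf("  Protective          %d\n", x$n_protective))
  cat(sprintf("  Risk                %d", x$n_risk))
  if (!is.na(x$risk_percent)) {
    cat(sprintf("  (%d%% of classified entries)",
                as.integer(round_half_up(x$risk_percent))))
  }
  cat("\n")
  cat(sprintf("  OR range (Avg)      %s\n",
              fmt_rng(x$or_min, x$or_max, x$or_mean)))
  cat(sprintf("  P-value range (Avg) %s\n",
              fmt_rng(x$p_min, x$p_max, x$p_mean)))
  if (!is.na(x$n_diet_types)) {
    cat(sprintf("  Diet types          %d\n", x$n_diet_types))
  }
  cat(sprintf("  Participants (Avg)  %s\n",
              fmt_rng(x$participants_min, x$participants_max,
                      x$participants_mean)))
  invisible(x)
}

#' Summary as a one-row tibble
#'
#' @param summary A `database_summary` from [summarize_annotations()].
#' @return A one-row tibble of all summary fields plus
#'   `risk_percent_display`, the half-up integer rounding used in reports.
#' @export
summary_as_tibble <- function(summary) {
  stopifnot(inherits(summary, "database_summary"))
  out <- tibble::as_tibble(summary[!vapply(summary, is.null, logical(1))])
  out$risk_percent_display <- if (is.na(summary$risk_percent)) NA_integer_
    else as.integer(round_half_up(summary$risk_percent))
  out
}
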
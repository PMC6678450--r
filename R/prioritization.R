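# Two-stage variant prioritization and per-superpopulation suggestion
# reports.
#
# Stage 1 (differentiation screen): a variant is retained when the maximum
# pairwise F_ST over the five superpopulations strictly exceeds
# `fst_threshold` (default 0.5).
# Stage 2 (commonness screen): the variant must also have an effect-allele
# frequency strictly above `freq_threshold` (default 0.5, i.e. "above
# 50%") in at least one group, the pooled ALL cohort included.
#
# Suggestion assignment: a prioritized variant common in the pooled cohort
# (ALL frequency above the threshold) contributes its dietary change to the
# "All" report only; otherwise it contributes to exactly the named
# superpopulations where it is common, so population rows list
# population-specific rather than globally common variants.

PRIORITY_CATEGORIES <- c("All", "AFR", "AMR", "EAS", "EUR", "SAS")

#' Select prioritized variants by differentiation and commonness
#'
#' Joins quality-passing annotations to their superpopulation frequencies
#' and keeps the variants passing both screens (strict inequalities at both
#' thresholds). Output rows are sorted by descending pooled (`ALL`)
#' frequency. Annotations without resolved frequencies are reported in the
#' `unresolved` attribute and a warning, never silently dropped.
#'
#' @param annotations Tibble with at least `dbsnp_id`; `gene`, `phenotype`
#'   and `dietary_change` are carried through when present (a curation
#'   store can provide `dietary_change` by joining its suggestion
#'   descriptions, see [dietary_change_from_suggestions()]).
#' @param freqs Frequency tibble (one row per SNP, proportion columns
#'   `ALL`, `AFR`, ..., e.g. from [load_frequency_table()] or
#'   [superpop_frequencies()]).
#' @param fst_threshold Differentiation screen threshold (default 0.5).
#' @param freq_threshold Commonness screen threshold as a proportion
#'   (default 0.5).
#' @param estimator F_ST estimator for the screen (default `"hudson"`).
#' @return A tibble of priority records: identity columns, the six
#'   frequencies, `max_fst`, `max_fst_pop_a`, `max_fst_pop_b`, `estimator`
#'   and a list-column `qualifying_pops` of the group codes (including
#'   `ALL`) whose frequency exceeds the threshold. Attribute `unresolved`
#'   lists dbSNP ids lacking frequencies.
#' @export
#' @examples
#' tab <- load_frequency_table(nutrifst_example("prioritized_snp_frequencies.tsv"))
#' pr <- select_priority(tab, tab)
#' pr[, c("dbsnp_id", "max_fst")]
select_priority <- function(annotations, freqs, fst_threshold = 0.5,
                            freq_threshold = 0.5,
                            estimator = FST_ESTIMATORS) {
  estimator <- match.arg(estimator)
  stopifnot(fst_threshold >= 0, freq_threshold >= 0, freq_threshold <= 1)
  keep_cols <- intersect(c("dbsnp_id", "gene", "phenotype", "dietary_change"),
                         names(annotations))
  ann <- dplyr::distinct(annotations[keep_cols])
  unresolved <- setdiff(ann$dbsnp_id, freqs$dbsnp_id)
  if (length(unresolved) > 0) {
    warning(length(unresolved),
            " annotation(s) without resolved frequencies: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(ann, freqs, by = "dbsnp_id",
                              suffix = c("", ".freq"))
  groups <- intersect(FREQ_GROUPS, names(joined))
  rows <- vector("list", nrow(joined))
  for (i in seq_len(nrow(joined))) {
    row <- joined[i, , drop = FALSE]
    mx <- max_pairwise_fst(row, estimator)
    fv <- setNames(as.numeric(unlist(row[1, groups])), groups)
    qualifying <- groups[!is.na(fv) & fv > freq_threshold]
    if (max(mx$value, 0) > fst_threshold && length(qualifying) > 0) {
      row$max_fst <- mx$value
      row$max_fst_pop_a <- mx$pop_a
      row$max_fst_pop_b <- mx$pop_b
      row$estimator <- estimator
      row$qualifying_pops <- list(qualifying)
      rows[[i]] <- row
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$ALL))
  } else {
    empty <- joined[0, , drop = FALSE]
    empty$max_fst <- numeric(0)
    empty$max_fst_pop_a <- character(0)
    empty$max_fst_pop_b <- character(0)
    empty$estimator <- character(0)
    empty$qualifying_pops <- list()
    empty
  }
  attr(out, "unresolved") <- unresolved
  out
}

#' Derive a `dietary_change` column from a suggestion table
#'
#' Collapses the suggestion descriptions linked to each annotation entry
#' into one text per entry (first occurrence order, "; "-separated), the
#' form carried by priority records.
#'
#' @param annotations Annotation tibble with `entry_id`.
#' @param suggestions Suggestion tibble with `entry_id`, `description`.
#' @return `annotations` with a `dietary_change` column appended.
#' @export
dietary_change_from_suggestions <- function(annotations, suggestions) {
  agg <- dplyr::summarise(
    dplyr::group_by(suggestions, .data$entry_id),
    dietary_change = paste(unique(.data$description), collapse = "; "),
    .groups = "drop"
  )
  dplyr::left_join(annotations, agg, by = "entry_id")
}

#' Aggregate prioritized variants into per-superpopulation reports
#'
#' Applies the assignment rule described above to the priority records and
#' aggregates, per category, the phenotypes and the dietary-change texts
#' (both deduplicated, preserving first occurrence over the record order).
#' Always returns six reports in the fixed order
#' All, AFR, AMR, EAS, EUR, SAS; categories with no contributing record
#' carry empty lists.
#'
#' @param records Priority records from [select_priority()].
#' @param freq_threshold Commonness threshold, matching the selection
#'   (default 0.5).
#' @return A tibble with `category` and list-columns `diseases` and
#'   `suggestions`.
#' @export
assign_suggestions <- function(records, freq_threshold = 0.5) {
  cats <- setNames(
    lapply(PRIORITY_CATEGORIES,
           function(x) list(diseases = character(0),
                            suggestions = character(0))),
    PRIORITY_CATEGORIES
  )
  add <- function(cat, phenotype, change) {
    if (!is.na(phenotype) && !phenotype %in% cats[[cat]]$diseases) {
      cats[[cat]]$diseases <<- c(cats[[cat]]$diseases, phenotype)
    }
    if (!is.na(change) && !change %in% cats[[cat]]$suggestions) {
      cats[[cat]]$suggestions <<- c(cats[[cat]]$suggestions, change)
    }
  }
  for (i in seq_len(nrow(records))) {
    row <- records[i, , drop = FALSE]
    phen <- if ("phenotype" %in% names(row)) row$phenotype else NA_character_
    change <- if ("dietary_change" %in% names(row)) row$dietary_change
              else NA_character_
    all_freq <- if ("ALL" %in% names(row)) row$ALL else NA_real_
    if (!is.na(all_freq) && all_freq > freq_threshold) {
      add("All", phen, change)
    } else {
      pops <- intersect(SUPERPOPS, names(row))
      for (p in pops) {
        f <- row[[p]]
        if (!is.na(f) && f > freq_threshold) add(p, phen, change)
      }
    }
  }
  tibble::tibble(
    category = PRIORITY_CATEGORIES,
    diseases = lapply(cats, `[[`, "diseases"),
    suggestions = lapply(cats, `[[`, "suggestions")
  )
}

#' Write the combined prioritization report to disk
#'
#' Emits `summary.tsv` (database summary), `priority.tsv` (one prioritized
#' variant per row, frequencies as rounded percentages, qualifying groups
#' as a comma-joined field), `suggestions.tsv` (per-category diseases and
#' suggestions, "; "-joined), `freq_hist.tsv` and a human-readable
#' `report.txt`. Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param summary A `database_summary` (or `NULL` to skip).
#' @param priority_records From [select_priority()].
#' @param suggestion_reports From [assign_suggestions()].
#' @param histogram From [bin_frequencies()] (or `NULL` to skip).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(summary, priority_records, suggestion_reports,
                          histogram, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()

  if (!is.null(summary)) {
    paths["summary"] <- file.path(dir, "summary.tsv")
    readr::write_tsv(summary_as_tibble(summary), paths["summary"],
                     na = "", progress = FALSE)
  }

  pr <- priority_records
  groups <- intersect(FREQ_GROUPS, names(pr))
  flat <- pr[intersect(c("dbsnp_id", "gene", "phenotype", "dietary_change"),
                       names(pr))]
  for (g in groups) flat[[g]] <- round_half_up(100 * pr[[g]])
  if ("max_fst" %in% names(pr)) {
    flat$max_fst <- round(pr$max_fst, 4)
    flat$max_fst_pair <- paste0(pr$max_fst_pop_a, "-", pr$max_fst_pop_b)
  }
  if ("qualifying_pops" %in% names(pr)) {
    flat$qualifying_pops <- vapply(pr$qualifying_pops, paste,
                                   character(1), collapse = ",")
  }
  paths["priority"] <- file.path(dir, "priority.tsv")
  readr::write_tsv(flat, paths["priority"], na = "", progress = FALSE)

  sug <- tibble::tibble(
    category = suggestion_reports$category,
    diseases = vapply(suggestion_reports$diseases, paste, character(1),
                      collapse = "; "),
    suggestions = vapply(suggestion_reports$suggestions, paste,
                         character(1), collapse = "; ")
  )
  paths["suggestions"] <- file.path(dir, "suggestions.tsv")
  readr::write_tsv(sug, paths["suggestions"], na = "", progress = FALSE)

  if (!is.null(histogram)) {
    paths["freq_hist"] <- file.path(dir, "freq_hist.tsv")
    readr::write_tsv(histogram_as_tibble(histogram), paths["freq_hist"],
                     na = "", progress = FALSE)
  }

  paths["report"] <- file.path(dir, "report.txt")
  con <- file(paths["report"], open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  sink(con)
  cat("Nutrigenetic variant prioritization report\n")
  cat("===========================================\n\n")
  if (!is.null(summary)) {
    print(summary)
    cat("\n")
  }
  cat(sprintf("Prioritized variants: %d\n\n", nrow(pr)))
  if (nrow(pr) > 0) {
    for (i in seq_len(nrow(pr))) {
      cat(sprintf("  %-12s maxFST=%.4f (%s)  groups>threshold: %s\n",
                  flat$dbsnp_id[i],
                  if ("max_fst" %in% names(flat)) flat$max_fst[i] else NA,
                  if ("max_fst_pair" %in% names(flat)) flat$max_fst_pair[i]
                  else "",
                  if ("qualifying_pops" %in% names(flat))
                    flat$qualifying_pops[i] else ""))
    }
    cat("\n")
  }
  cat("Per-superpopulation dietary suggestions\n")
  for (i in seq_len(nrow(sug))) {
    cat(sprintf("  %-4s diseases: %s\n", sug$category[i],
                if (nzchar(sug$diseases[i])) sug$diseases[i] else "-"))
    cat(sprintf("       suggestions: %s\n",
                if (nzchar(sug$suggestions[i])) sug$suggestions[i] else "-"))
  }
  if (!is.null(histogram)) {
    cat("\n")
    print(histogram)
  }
  sink()
  invisible(paths)
}
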
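# Curated gene-diet interaction store: a six-table relational data model
# (User, UserEntry, NutrigeneticsEntry, Genotype, DietarySuggestion,
# FoodOrNutrient) serialized as UTF-8 tab-separated text with empty cells
# for nulls, so fixtures stay diff-able.

ANNOTATION_COLS <- c(
  entry_id = "character", dbsnp_id = "character", gene = "character",
  hgvs_c = "character", hgvs_p = "character", hgvs_g = "character",
  chromosome = "character", position = "double", phenotype = "character",
  pubmed_id = "double", study_type = "character", p_value = "double",
  odds_ratio = "double", ci_low = "double", ci_high = "double",
  n_participants = "double", population_studied = "character",
  effect_allele = "character", effect_class = "character"
)

SUGGESTION_COLS <- c(
  suggestion_id = "character", entry_id = "character",
  suggestion_type = "character", item = "character", direction = "character",
  quantity = "double", units = "character", interaction_p = "double",
  interaction_or = "double", interaction_ci_low = "double",
  interaction_ci_high = "double", description = "character"
)

FOOD_COLS <- c(
  suggestion_id = "character", food_name = "character",
  nutrient_content_per_serving = "double", servings_for_daily_value = "double"
)

STUDY_TYPES <- c("candidate", "gwas")
SUGGESTION_TYPES <- c("food", "nutrient", "food_group", "endophenotype_monitor")
DIRECTIONS <- c("increase", "decrease", "avoid", "moderate")

read_store_tsv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t",
                     fixed = TRUE)[[1]]
  missing <- setdiff(names(cols), header)
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spec <- do.call(readr::cols, lapply(cols, function(tp) {
    if (tp == "double") readr::col_double() else readr::col_character()
  }))
  x <- readr::read_tsv(path, col_types = spec, na = c("", "NA"),
                       progress = FALSE)
  x[names(cols)]
}

# Validate one rule over rows; returns a problems tibble (possibly empty).
row_problems <- function(bad, field, reason) {
  tibble::tibble(row = which(bad), field = field, reason = reason)
}

validate_annotations <- function(x) {
  problems <- dplyr::bind_rows(
    row_problems(is.na(x$entry_id) | !nzchar(x$entry_id),
                 "entry_id", "missing entry_id"),
    row_problems(is.na(x$dbsnp_id) | !grepl("^rs[0-9]+$", x$dbsnp_id),
                 "dbsnp_id", "malformed rs identifier"),
    row_problems(is.na(x$p_value) | x$p_value <= 0 | x$p_value > 1,
                 "p_value", "p_value outside (0, 1]"),
    row_problems(is.na(x$odds_ratio) | x$odds_ratio <= 0,
                 "odds_ratio", "odds_ratio must be > 0"),
    row_problems(!is.na(x$ci_low) & !is.na(x$ci_high) & x$ci_low > x$ci_high,
                 "ci_low", "ci_low greater than ci_high"),
    row_problems(is.na(x$position) | x$position < 1,
                 "position", "position must be >= 1"),
    row_problems(!is.na(x$study_type) & !x$study_type %in% STUDY_TYPES,
                 "study_type", "study_type not one of candidate/gwas"),
    row_problems(!is.na(x$effect_class) &
                   !x$effect_class %in% c("risk", "protective"),
                 "effect_class", "effect_class not one of risk/protective"),
    row_problems(!is.na(x$n_participants) & x$n_participants < 0,
                 "n_participants", "n_participants must be >= 0")
  )
  dplyr::arrange(problems, .data$row)
}

validate_suggestions <- function(x) {
  problems <- dplyr::bind_rows(
    row_problems(is.na(x$suggestion_id) | !nzchar(x$suggestion_id),
                 "suggestion_id", "missing suggestion_id"),
    row_problems(is.na(x$entry_id) | !nzchar(x$entry_id),
                 "entry_id", "missing entry_id link"),
    row_problems(!is.na(x$quantity) & x$quantity < 0,
                 "quantity", "quantity must be >= 0"),
    row_problems(!is.na(x$suggestion_type) &
                   !x$suggestion_type %in% SUGGESTION_TYPES,
                 "suggestion_type", "unknown suggestion_type")
  )
  dplyr::arrange(problems, .data$row)
}

validate_foods <- function(x) {
  problems <- dplyr::bind_rows(
    row_problems(is.na(x$suggestion_id) | !nzchar(x$suggestion_id),
                 "suggestion_id", "missing suggestion_id link"),
    row_problems(!is.na(x$nutrient_content_per_serving) &
                   x$nutrient_content_per_serving < 0,
                 "nutrient_content_per_serving", "must be >= 0"),
    row_problems(!is.na(x$servings_for_daily_value) &
                   x$servings_for_daily_value < 0,
                 "servings_for_daily_value", "must be >= 0")
  )
  dplyr::arrange(problems, .data$row)
}

finish_load <- function(x, problems, strict, what) {
  if (nrow(problems) > 0) {
    msgs <- sprintf("row %d [%s]: %s", problems$row, problems$field,
                    problems$reason)
    if (strict) {
      stop("invalid ", what, " row(s):\n  ", paste(msgs, collapse = "\n  "),
           call. = FALSE)
    }
    warning("dropping ", length(unique(problems$row)), " invalid ", what,
            " row(s); see attr(x, 'problems')", call. = FALSE)
    x <- x[-unique(problems$row), , drop = FALSE]
  }
  attr(x, "problems") <- problems
  x
}

#' Read curated gene-diet interaction annotations from TSV
#'
#' Each row is one curated study finding: a variant (dbSNP id, gene, HGVS
#' strings, GRCh37 position), the phenotype it affects, the reported
#' association statistics (p-value, odds ratio, optional confidence
#' interval), provenance (PubMed id, study type, population studied), the
#' effect allele the statistics refer to, and an effect classification
#' (`risk`/`protective`, empty until classified).
#'
#' Validation errors are collected per row with the row number, offending
#' field and reason; in strict mode (the default) any invalid row aborts the
#' load, in permissive mode invalid rows are dropped with a warning and the
#' problem table is attached as `attr(x, "problems")`.
#'
#' @param path Path to a tab-separated file whose header names all required
#'   fields. Empty cells are nulls (`NA`).
#' @param strict Abort on any invalid row (`TRUE`, default) or drop invalid
#'   rows with a warning (`FALSE`).
#' @return A tibble of validated annotation records with a `problems`
#'   attribute (a tibble with columns `row`, `field`, `reason`).
#' @seealso [save_annotations()], [load_suggestions()], [load_foods()]
#' @export
#' @examples
#' ann <- load_annotations(nutrifst_example("prioritized_snp_annotations_synthetic.tsv"))
#' nrow(ann)
load_annotations <- function(path, strict = TRUE) {
  x <- read_store_tsv(path, ANNOTATION_COLS)
  finish_load(x, validate_annotations(x), strict, "annotation")
}

#' Read dietary suggestions linked to annotation entries
#'
#' A suggestion is the actionable dietary change attached to one curated
#' finding: consume (or avoid) a food, nutrient or food group, or monitor an
#' endophenotype, optionally with a quantity, units and its own interaction
#' statistics.
#'
#' @inheritParams load_annotations
#' @return A tibble of suggestion records (see [load_annotations()] for the
#'   validation contract).
#' @export
load_suggestions <- function(path, strict = TRUE) {
  x <- read_store_tsv(path, SUGGESTION_COLS)
  finish_load(x, validate_suggestions(x), strict, "suggestion")
}

#' Read food/nutrient content rows linked to suggestions
#'
#' Each row records, for one suggested food, its nutrient content per
#' serving and the number of servings needed to provide the suggested daily
#' value.
#'
#' @inheritParams load_annotations
#' @return A tibble of food records.
#' @export
load_foods <- function(path, strict = TRUE) {
  x <- read_store_tsv(path, FOOD_COLS)
  finish_load(x, validate_foods(x), strict, "food")
}

write_store_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write annotation records to TSV
#'
#' Round-trip contract: `load_annotations(save_annotations(x, path))` equals
#' `x` field for field. Nulls are written as empty cells.
#'
#' @param records A validated annotation tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_annotations <- function(records, path) {
  stopifnot(all(names(ANNOTATION_COLS) %in% names(records)))
  write_store_tsv(records[names(ANNOTATION_COLS)], path)
}

#' @rdname save_annotations
#' @export
save_suggestions <- function(records, path) {
  stopifnot(all(names(SUGGESTION_COLS) %in% names(records)))
  write_store_tsv(records[names(SUGGESTION_COLS)], path)
}

#' @rdname save_annotations
#' @export
save_foods <- function(records, path) {
  stopifnot(all(names(FOOD_COLS) %in% names(records)))
  write_store_tsv(records[names(FOOD_COLS)], path)
}

#' Check referential integrity across a loaded curation store
#'
#' Verifies that every `DietarySuggestion.entry_id` resolves to an
#' annotation and every `FoodOrNutrient.suggestion_id` resolves to a
#' suggestion (and, when user tables are supplied, that user-entry links
#' resolve in both directions).
#'
#' @param annotations,suggestions,foods Tibbles as returned by the loaders.
#' @param users,user_entries Optional user tables (`user_id`;
#'   `user_id` + `entry_id`).
#' @return `TRUE` invisibly if the store is consistent; otherwise an error
#'   listing every dangling link.
#' @export
check_referential_integrity <- function(annotations, suggestions = NULL,
                                        foods = NULL, users = NULL,
                                        user_entries = NULL) {
  errs <- character(0)
  if (!is.null(suggestions)) {
    bad <- setdiff(suggestions$entry_id, annotations$entry_id)
    if (length(bad) > 0) {
      errs <- c(errs, paste0("suggestion entry_id(s) with no annotation: ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(foods)) {
    if (is.null(suggestions)) {
      errs <- c(errs, "foods supplied without suggestions")
    } else {
      bad <- setdiff(foods$suggestion_id, suggestions$suggestion_id)
      if (length(bad) > 0) {
        errs <- c(errs, paste0("food suggestion_id(s) with no suggestion: ",
                               paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.null(user_entries)) {
    if (!is.null(users)) {
      bad <- setdiff(user_entries$user_id, users$user_id)
      if (length(bad) > 0) {
        errs <- c(errs, paste0("user_entry user_id(s) with no user: ",
                               paste(bad, collapse = ", ")))
      }
    }
    bad <- setdiff(user_entries$entry_id, annotations$entry_id)
    if (length(bad) > 0) {
      errs <- c(errs, paste0("user_entry entry_id(s) with no annotation: ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (length(errs) > 0) {
    stop("referential integrity violated:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Emit the relational schema of the curation database as SQL DDL
#'
#' The store is modeled as six tables chained by foreign keys:
#' `User` -> `UserEntry` -> `NutrigeneticsEntry` -> `Genotype` ->
#' `DietarySuggestion` -> `FoodOrNutrient`. `NutrigeneticsEntry` holds the
#' variant-level fields (dbSNP id, gene, HGVS notation, GRCh37 position,
#' phenotype); `Genotype` holds the per-genotype association statistics
#' (p-value, odds ratio, confidence interval); the user tables exist for
#' schema completeness and carry no analysis logic.
#'
#' @param dialect SQL dialect; `"sqlite"` (ANSI-conservative, executable in
#'   an embedded engine) is the only dialect currently emitted.
#' @return A single character string of DDL containing six
#'   `CREATE TABLE` statements.
#' @export
#' @examples
#' cat(substr(emit_schema(), 1, 120))
emit_schema <- function(dialect = "sqlite") {
  dialect <- match.arg(dialect, "sqlite")
  paste(
    "CREATE TABLE User (",
    "  user_id TEXT PRIMARY KEY",
    ");",
    "",
    "CREATE TABLE NutrigeneticsEntry (",
    "  entry_id TEXT PRIMARY KEY,",
    "  dbsnp_id TEXT NOT NULL,",
    "  gene TEXT,",
    "  hgvs_c TEXT,",
    "  hgvs_p TEXT,",
    "  hgvs_g TEXT,",
    "  chromosome TEXT,",
    "  position INTEGER CHECK (position >= 1),",
    "  phenotype TEXT,",
    "  pubmed_id INTEGER,",
    "  gene_summary TEXT",
    ");",
    "",
    "CREATE TABLE UserEntry (",
    "  user_id TEXT NOT NULL REFERENCES User (user_id),",
    "  entry_id TEXT NOT NULL REFERENCES NutrigeneticsEntry (entry_id),",
    "  PRIMARY KEY (user_id, entry_id)",
    ");",
    "",
    "CREATE TABLE Genotype (",
    "  genotype_id TEXT PRIMARY KEY,",
    "  entry_id TEXT NOT NULL REFERENCES NutrigeneticsEntry (entry_id),",
    "  effect_allele TEXT,",
    "  study_type TEXT CHECK (study_type IN ('candidate', 'gwas')),",
    "  p_value REAL CHECK (p_value > 0 AND p_value <= 1),",
    "  odds_ratio REAL CHECK (odds_ratio > 0),",
    "  ci_low REAL,",
    "  ci_high REAL,",
    "  n_participants INTEGER CHECK (n_participants >= 0),",
    "  population_studied TEXT,",
    "  effect_class TEXT CHECK (effect_class IN ('risk', 'protective'))",
    ");",
    "",
    "CREATE TABLE DietarySuggestion (",
    "  suggestion_id TEXT PRIMARY KEY,",
    "  genotype_id TEXT NOT NULL REFERENCES Genotype (genotype_id),",
    "  suggestion_type TEXT CHECK (suggestion_type IN",
    "    ('food', 'nutrient', 'food_group', 'endophenotype_monitor')),",
    "  item TEXT,",
    "  direction TEXT CHECK (direction IN",
    "    ('increase', 'decrease', 'avoid', 'moderate')),",
    "  quantity REAL CHECK (quantity >= 0),",
    "  units TEXT,",
    "  interaction_p REAL,",
    "  interaction_or REAL,",
    "  interaction_ci_low REAL,",
    "  interaction_ci_high REAL,",
    "  description TEXT",
    ");",
    "",
    "CREATE TABLE FoodOrNutrient (",
    "  food_id TEXT PRIMARY KEY,",
    "  suggestion_id TEXT NOT NULL REFERENCES DietarySuggestion (suggestion_id),",
    "  food_name TEXT,",
    "  nutrient_content_per_serving REAL CHECK (nutrient_content_per_serving >= 0),",
    "  servings_for_daily_value REAL CHECK (servings_for_daily_value >= 0)",
    ");",
    sep = "\n"
  )
}
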
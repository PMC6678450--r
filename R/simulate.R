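# Synthetic data generation: Balding-Nichols population-structured allele
# frequencies, unphased diploid genotypes written as VCF with a matching
# sample panel, and synthetic curation records with a controllable
# quality-gate pass fraction. Everything is reproducible from the seed in
# the configuration; the global RNG state is left untouched.

#' Configuration for the synthetic-data generators
#'
#' @param n_loci Number of independent biallelic loci (no linkage,
#'   demography or selection is modeled).
#' @param n_pops Number of populations (default 5, labeled with the
#'   superpopulation codes for drop-in pipeline testing).
#' @param samples_per_pop Diploid samples per population.
#' @param ancestral_freq Ancestral allele frequency law: a single value, or
#'   a `c(lo, hi)` range for a uniform draw per locus (default
#'   `c(0.05, 0.95)`, avoiding near-fixed ancestral alleles).
#' @param F Differentiation parameter of the Balding-Nichols model, in
#'   (0, 1); scalar (shared) or one value per population.
#' @param annotation_n Number of synthetic curation records.
#' @param annotation_pass_fraction Fraction of records constructed to pass
#'   the default quality gate; exactly
#'   `round(annotation_n * annotation_pass_fraction)` records pass.
#' @param risk_fraction Fraction of passing records given a risk-side odds
#'   ratio (the rest are protective); counts are exact via rounding.
#' @param pop_labels Population labels (recycled/truncated to `n_pops`).
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_loci = 100, n_pops = 5,
                              samples_per_pop = 50,
                              ancestral_freq = c(0.05, 0.95), F = 0.1,
                              annotation_n = 100,
                              annotation_pass_fraction = 1,
                              risk_fraction = 2 / 3,
                              pop_labels = SUPERPOPS, seed = 1L) {
  if (length(ancestral_freq) == 1) {
    ancestral_freq <- rep(ancestral_freq, 2)
  }
  stopifnot(
    n_loci >= 1, n_pops >= 1, samples_per_pop >= 1,
    length(ancestral_freq) == 2,
    ancestral_freq[1] >= 0, ancestral_freq[1] <= ancestral_freq[2],
    ancestral_freq[2] <= 1,
    all(F > 0), all(F < 1), length(F) %in% c(1, n_pops),
    annotation_n >= 0,
    annotation_pass_fraction >= 0, annotation_pass_fraction <= 1,
    risk_fraction >= 0, risk_fraction <= 1
  )
  labels <- rep_len(pop_labels, n_pops)
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }
  structure(list(
    n_loci = as.integer(n_loci), n_pops = as.integer(n_pops),
    samples_per_pop = as.integer(samples_per_pop),
    ancestral_freq = ancestral_freq, F = F,
    annotation_n = as.integer(annotation_n),
    annotation_pass_fraction = annotation_pass_fraction,
    risk_fraction = risk_fraction,
    pop_labels = labels, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Balding-Nichols per-population allele frequencies
#'
#' Draws each population's allele frequency independently from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` around the ancestral
#' frequency `p`, so that `E[p_i] = p` and `Var(p_i) = F p (1 - p)`: `F`
#' is the expected differentiation among the populations. Degenerate
#' ancestral frequencies 0 and 1 are returned fixed for all populations.
#'
#' @param p_anc Ancestral allele frequency (scalar or one per locus).
#' @param F Differentiation parameter in (0, 1); scalar or one per
#'   population.
#' @param n_pops Number of populations.
#' @param seed Optional integer seed (the global RNG state is preserved).
#' @return A matrix of frequencies, `length(p_anc)` rows (loci) by
#'   `n_pops` columns.
#' @export
#' @examples
#' balding_nichols_frequencies(0.5, F = 0.1, n_pops = 5, seed = 1)
balding_nichols_frequencies <- function(p_anc, F, n_pops = 5, seed = NULL) {
  stopifnot(all(p_anc >= 0), all(p_anc <= 1), all(F > 0), all(F < 1),
            length(F) %in% c(1, n_pops), n_pops >= 1)
  F <- rep_len(F, n_pops)
  draw <- function() {
    out <- matrix(NA_real_, nrow = length(p_anc), ncol = n_pops)
    for (j in seq_len(n_pops)) {
      shape_scale <- (1 - F[j]) / F[j]
      out[, j] <- ifelse(
        p_anc <= 0 | p_anc >= 1,
        p_anc,  # fixed ancestral allele stays fixed
        rbeta(length(p_anc), p_anc * shape_scale, (1 - p_anc) * shape_scale)
      )
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

format_gt <- function(allele_count) {
  c("0/0", "0/1", "1/1")[allele_count + 1L]
}

#' Simulate a genotype VCF and sample panel under population structure
#'
#' Draws per-population allele frequencies from the Balding-Nichols model,
#' then unphased diploid genotypes binomially from each population's
#' frequency, and writes a plain-text VCF 4.2 (biallelic autosomal SNPs,
#' GT-only FORMAT) plus a sample panel TSV in the 1000 Genomes phase 3
#' layout (`sample`, `pop`, `super_pop`). Identical configurations produce
#' byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param vcf_path,panel_path Output paths (defaults under `tempdir()`).
#' @return Invisibly, a list with `vcf`, `panel` (the paths) and
#'   `frequencies`, the generating per-population frequency matrix
#'   (loci x populations), for parameter-recovery checks.
#' @export
simulate_genotype_vcf <- function(config,
                                  vcf_path = tempfile(fileext = ".vcf"),
                                  panel_path = tempfile(fileext = ".tsv")) {
  stopifnot(inherits(config, "simulation_config"))
  res <- withr::with_seed(config$seed, {
    p_anc <- if (config$ancestral_freq[1] == config$ancestral_freq[2]) {
      rep(config$ancestral_freq[1], config$n_loci)
    } else {
      runif(config$n_loci, config$ancestral_freq[1], config$ancestral_freq[2])
    }
    pf <- balding_nichols_frequencies(p_anc, config$F, config$n_pops)
    n_samples <- config$n_pops * config$samples_per_pop
    # allele counts per (locus, sample): Binomial(2, p of the sample's pop)
    pop_of_sample <- rep(seq_len(config$n_pops),
                         each = config$samples_per_pop)
    probs <- pf[, pop_of_sample, drop = FALSE]
    counts <- matrix(rbinom(length(probs), 2, probs),
                     nrow = config$n_loci)
    list(pf = pf, counts = counts, pop_of_sample = pop_of_sample)
  })

  sample_ids <- sprintf("%s%04d", res$pop_of_sample |>
                          (\(p) config$pop_labels[p])(),
                        sequence(rep(config$samples_per_pop, config$n_pops)))
  panel <- tibble::tibble(
    sample = sample_ids,
    pop = config$pop_labels[res$pop_of_sample],
    super_pop = config$pop_labels[res$pop_of_sample]
  )
  readr::write_tsv(panel, panel_path, progress = FALSE)

  gt <- matrix(format_gt(res$counts), nrow = config$n_loci)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nutrifst Balding-Nichols simulator",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- paste(
    "1", format(seq_len(config$n_loci) * 1000L, scientific = FALSE,
                trim = TRUE),
    sprintf("sim%05d", seq_len(config$n_loci)),
    "A", "G", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), vcf_path)

  invisible(list(vcf = vcf_path, panel = panel_path,
                 frequencies = res$pf))
}

# small fixed vocabularies for synthetic curation records
SIM_PHENOTYPES <- c("Colorectal Cancer", "Metabolic Syndrome",
                    "Type 2 Diabetes", "Obesity", "Hypertension",
                    "Hypercholesterolemia")
SIM_ITEMS <- c("folate", "n-3 PUFA", "n-6 fatty acid", "calcium",
               "vitamin D", "alcohol", "carbohydrate", "saturated fat")
SIM_GENES <- c("MTHFR", "VDR", "APOB", "LEPR", "FADS1", "TCF7L2", "ADH1B",
               "CBS")

#' Simulate a synthetic curation store
#'
#' Generates `annotation_n` gene-diet interaction records of which exactly
#' `round(annotation_n * annotation_pass_fraction)` pass the default
#' quality gate: passing records get a significant p-value (below the
#' study-type threshold) and a log-normal-style odds ratio drawn strictly
#' outside the null band (risk side with probability `risk_fraction`,
#' exact counts by rounding); failing records get a non-significant
#' p-value or an odds ratio inside the band. Every record is linked to one
#' dietary suggestion and one food item, so referential integrity holds by
#' construction.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, the three store TSVs
#'   (`annotations.tsv`, `suggestions.tsv`, `foods.tsv`) are written there.
#' @return A list with tibbles `annotations`, `suggestions`, `foods` (and
#'   `paths` when `out_dir` is given).
#' @export
#' @examples
#' store <- simulate_annotations(
#'   simulation_config(annotation_n = 10, annotation_pass_fraction = 0.5,
#'                     seed = 42))
#' sum(passes_quality(store$annotations$p_value,
#'                    store$annotations$odds_ratio,
#'                    store$annotations$study_type))
simulate_annotations <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$annotation_n
  n_pass <- round(n * config$annotation_pass_fraction)
  n_risk <- round(n_pass * config$risk_fraction)

  store <- withr::with_seed(config$seed, {
    passing <- seq_len(n) <= n_pass  # first block passes; ids are arbitrary
    is_risk <- logical(n)
    if (n_pass > 0) is_risk[seq_len(n_risk)] <- TRUE
    study_type <- sample(c("candidate", "gwas"), n, replace = TRUE,
                         prob = c(0.8, 0.2))

    p_value <- runif(n, 0.051, 0.9)  # default: fails either threshold
    p_value[passing & study_type == "candidate"] <-
      runif(sum(passing & study_type == "candidate"), 1e-4, 0.049)
    p_value[passing & study_type == "gwas"] <-
      runif(sum(passing & study_type == "gwas"), 1e-12, 4.9e-8)
    # a third of failing records fail on the OR band instead (p significant
    # for a candidate study, OR ~ 1)
    band_fail <- !passing & runif(n) < 1 / 3
    p_value[band_fail] <- runif(sum(band_fail), 1e-4, 0.049)
    study_type[band_fail] <- "candidate"

    odds_ratio <- numeric(n)
    odds_ratio[is_risk] <- exp(runif(sum(is_risk), log(1.031), log(3.5)))
    odds_ratio[passing & !is_risk] <-
      exp(runif(sum(passing & !is_risk), log(0.15), log(0.969)))
    odds_ratio[!passing] <- exp(runif(sum(!passing), log(0.9), log(1.1)))
    odds_ratio[band_fail] <- runif(sum(band_fail), 0.97, 1.03)

    has_ci <- runif(n) < 0.7
    ci_low <- ifelse(has_ci, odds_ratio * 0.8, NA_real_)
    ci_high <- ifelse(has_ci, odds_ratio * 1.25, NA_real_)

    annotations <- tibble::tibble(
      entry_id = sprintf("SIM%05d", seq_len(n)),
      dbsnp_id = sprintf("rs9%07d", sample.int(9999999, n)),
      gene = sample(SIM_GENES, n, replace = TRUE),
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      hgvs_g = NA_character_,
      chromosome = as.character(sample.int(22, n, replace = TRUE)),
      position = sample.int(2.4e8, n),
      phenotype = sample(SIM_PHENOTYPES, n, replace = TRUE),
      pubmed_id = 30000000 + sample.int(999999, n),
      study_type = study_type,
      p_value = p_value, odds_ratio = odds_ratio,
      ci_low = ci_low, ci_high = ci_high,
      n_participants = sample.int(16000, n),
      population_studied = "synthetic cohort",
      effect_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      effect_class = NA_character_
    )
    annotations$effect_class[passing] <-
      ifelse(is_risk[passing], "risk", "protective")

    item <- sample(SIM_ITEMS, n, replace = TRUE)
    direction <- sample(DIRECTIONS, n, replace = TRUE)
    suggestions <- tibble::tibble(
      suggestion_id = sprintf("SUG%05d", seq_len(n)),
      entry_id = annotations$entry_id,
      suggestion_type = sample(SUGGESTION_TYPES, n, replace = TRUE),
      item = item,
      direction = direction,
      quantity = round(runif(n, 0.5, 500), 1),
      units = "mg/day",
      interaction_p = p_value,
      interaction_or = odds_ratio,
      interaction_ci_low = ci_low,
      interaction_ci_high = ci_high,
      description = paste(direction, item)
    )
    foods <- tibble::tibble(
      suggestion_id = suggestions$suggestion_id,
      food_name = paste("food rich in", item),
      nutrient_content_per_serving = round(runif(n, 1, 120), 1),
      servings_for_daily_value = round(runif(n, 0.5, 6), 1)
    )
    list(annotations = annotations, suggestions = suggestions,
         foods = foods)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      annotations = file.path(out_dir, "annotations.tsv"),
      suggestions = file.path(out_dir, "suggestions.tsv"),
      foods = file.path(out_dir, "foods.tsv")
    )
    save_annotations(store$annotations, paths["annotations"])
    save_suggestions(store$suggestions, paths["suggestions"])
    save_foods(store$foods, paths["foods"])
    store$paths <- paths
  }
  store
}
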
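# Shared builders for in-code fixtures.

fixture_freq_path <- function() nutrifst_example("prioritized_snp_frequencies.tsv")

fixture_freqs <- function() load_frequency_table(fixture_freq_path())

# One valid annotation record with overridable fields.
ann_record <- function(...) {
  defaults <- tibble::tibble(
    entry_id = "E1", dbsnp_id = "rs123", gene = "MTHFR",
    hgvs_c = NA_character_, hgvs_p = NA_character_, hgvs_g = NA_character_,
    chromosome = "1", position = 11856378, phenotype = "Colorectal Cancer",
    pubmed_id = 30000000, study_type = "candidate", p_value = 0.002,
    odds_ratio = 0.62, ci_low = 0.46, ci_high = 0.84, n_participants = 787,
    population_studied = "Korean cohort", effect_allele = "C",
    effect_class = NA_character_
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# Minimal VCF writer for counting oracles: `genotypes` is a matrix of GT
# strings (variants x samples).
write_toy_vcf <- function(genotypes, samples, ids = NULL,
                          chrom = "1", pos = NULL, ref = "A", alt = "G",
                          path = tempfile(fileext = ".vcf")) {
  genotypes <- matrix(genotypes, ncol = length(samples))
  n <- nrow(genotypes)
  if (is.null(ids)) ids <- sprintf("rs%d", seq_len(n))
  if (is.null(pos)) pos <- seq_len(n) * 100
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(rep_len(chrom, n), pos, ids, rep_len(ref, n),
                rep_len(alt, n), ".", "PASS", ".", "GT",
                apply(genotypes, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

toy_panel <- function(samples, super_pops) {
  tibble::tibble(sample = samples, pop = super_pops, super_pop = super_pops)
}
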
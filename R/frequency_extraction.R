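# Per-superpopulation effect-allele frequencies, from VCF genotypes plus a
# sample panel, or from precomputed frequency tables. Frequencies are plain
# allele counting: (effect alleles among called genotypes) / (called
# alleles), with missing genotypes excluded from numerator and denominator
# alike. The pooled ALL group is counted over all panel-matched samples --
# it is NOT the unweighted mean of the five group frequencies.

#' Read a sample panel mapping samples to (super)populations
#'
#' Expects the integrated-call-samples panel layout of the 1000 Genomes
#' Project phase 3: tab-separated columns `sample`, `pop`, `super_pop`
#' (extra columns ignored). Superpopulation codes must come from the fixed
#' five-code set [SUPERPOPS] and sample ids must be unique.
#'
#' @param path Panel TSV path.
#' @return A tibble with columns `sample`, `pop`, `super_pop`.
#' @export
load_sample_panel <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("sample", "pop", "super_pop")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[need]
  if (anyDuplicated(x$sample)) {
    stop("duplicate sample ids in panel", call. = FALSE)
  }
  bad <- setdiff(unique(x$super_pop), SUPERPOPS)
  if (length(bad) > 0) {
    stop("unknown superpopulation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

# Count occurrences of allele index `target` among called alleles of a
# genotype string vector ("0/1", "1|1", "./.", ...). Returns c(hits, called).
count_alleles <- function(gt, target) {
  gt <- gt[!is.na(gt)]
  if (length(gt) == 0) return(c(hits = 0, called = 0))
  simple <- all(nchar(gt) == 3)
  if (simple) {
    alleles <- c(substr(gt, 1, 1), substr(gt, 3, 3))
  } else {
    alleles <- unlist(strsplit(gt, "[/|]"), use.names = FALSE)
  }
  alleles <- alleles[alleles != "."]
  c(hits = sum(alleles == as.character(target)), called = length(alleles))
}

#' Per-superpopulation effect-allele frequencies from VCF genotypes
#'
#' For each requested SNP, counts effect alleles among the called genotypes
#' of each superpopulation in the panel, plus the pooled `ALL` cohort.
#' SNPs are matched by VCF `ID`, or by `chrom:pos` when the query looks
#' like a coordinate. SNPs absent from the VCF (or whose effect allele
#' matches neither REF nor any ALT) are reported in the `unresolved`
#' element, never silently dropped.
#'
#' Allele orientation: when `effect_alleles` is supplied, the frequency of
#' that base is reported (equivalently `1 - freq(ALT)` when the effect
#' allele is REF of a biallelic site). Without an effect allele the first
#' ALT is used for biallelic sites; multi-allelic sites without an explicit
#' effect allele are unresolved, to avoid silent frequency errors.
#'
#' @param vcf Path to a VCF file (plain or bgzipped) with GT fields, or a
#'   `vcfR` object.
#' @param panel Sample panel tibble (see [load_sample_panel()]) or path.
#' @param snp_ids Character vector of SNP ids (`rs...`) or `chrom:pos`
#'   coordinates. Default: every variant in the VCF.
#' @param effect_alleles Optional character vector of effect alleles, named
#'   by snp id.
#' @return A list with `frequencies` (tibble: `dbsnp_id`, `effect_allele`,
#'   frequency columns `ALL`, `AFR`, ..., and called-allele counts `n_ALL`,
#'   `n_AFR`, ...) and `unresolved` (tibble: `dbsnp_id`, `reason`). Groups
#'   with no called alleles get frequency `NA`.
#' @export
superpop_frequencies <- function(vcf, panel, snp_ids = NULL,
                                 effect_alleles = NULL) {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  if (is.character(panel)) panel <- load_sample_panel(panel)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-variant VCF gives a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt)

  extra <- setdiff(vcf_samples, panel$sample)
  if (length(extra) > 0) {
    warning(length(extra), " VCF sample(s) missing from panel; excluded: ",
            paste(head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "", call. = FALSE)
  }
  use_samples <- intersect(vcf_samples, panel$sample)
  if (length(use_samples) == 0) {
    stop("no VCF samples found in the panel", call. = FALSE)
  }
  super <- setNames(panel$super_pop, panel$sample)[use_samples]
  groups <- c(list(ALL = use_samples),
              split(use_samples, factor(super, levels = SUPERPOPS)))
  groups <- groups[vapply(groups, length, integer(1)) > 0]

  if (is.null(snp_ids)) snp_ids <- fix$ID
  coord <- paste0(fix$CHROM, ":", fix$POS)

  freq_rows <- list()
  unresolved <- list()
  for (snp in snp_ids) {
    idx <- which(fix$ID == snp)
    if (length(idx) == 0) idx <- which(coord == snp)
    if (length(idx) == 0) {
      unresolved[[snp]] <- "not found in VCF"
      next
    }
    eff <- if (!is.null(effect_alleles) && snp %in% names(effect_alleles)) {
      effect_alleles[[snp]]
    } else {
      NA_character_
    }
    resolved <- FALSE
    for (i in idx) {
      alleles <- c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
      if (is.na(eff)) {
        if (length(alleles) > 2) next  # multi-allelic needs an effect allele
        target <- 1L
        eff_out <- alleles[2]
      } else {
        target <- match(eff, alleles) - 1L
        if (is.na(target)) next
        eff_out <- eff
      }
      counts <- vapply(groups, function(s) {
        count_alleles(gt[i, s], target)
      }, numeric(2))
      freqs <- ifelse(counts["called", ] > 0,
                      counts["hits", ] / counts["called", ], NA_real_)
      row <- tibble::tibble(dbsnp_id = snp, effect_allele = eff_out)
      for (g in names(groups)) row[[g]] <- unname(freqs[g])
      for (g in names(groups)) row[[paste0("n_", g)]] <-
        unname(counts["called", g])
      freq_rows[[snp]] <- row
      resolved <- TRUE
      break
    }
    if (!resolved) {
      unresolved[[snp]] <- if (is.na(eff)) {
        "multi-allelic site without an effect allele"
      } else {
        "effect allele matches neither REF nor ALT"
      }
    }
  }

  list(
    frequencies = if (length(freq_rows) > 0) dplyr::bind_rows(freq_rows)
                  else tibble::tibble(dbsnp_id = character(0),
                                      effect_allele = character(0)),
    unresolved = tibble::tibble(
      dbsnp_id = as.character(names(unresolved)),
      reason = as.character(unlist(unresolved, use.names = FALSE))
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a precomputed per-superpopulation frequency table
#'
#' Expects tab-separated columns `dbsnp_id` plus the six frequency columns
#' `ALL`, `AFR`, `AMR`, `EAS`, `EUR`, `SAS`; any other columns (e.g.
#' `gene`, `phenotype`, `dietary_change`) are carried through. Values may
#' be percentages or proportions: by default the scale is auto-detected
#' (any value > 1 means percentages) and everything is normalized to
#' proportions in `[0, 1]`.
#'
#' @param path Frequency table TSV path.
#' @param scale `"auto"` (default), `"percent"` or `"proportion"`.
#' @return A tibble with frequency columns as proportions.
#' @export
#' @examples
#' tab <- load_frequency_table(nutrifst_example("prioritized_snp_frequencies.tsv"))
#' tab[tab$dbsnp_id == "rs11568820", c("dbsnp_id", FREQ_GROUPS)]
load_frequency_table <- function(path, scale = c("auto", "percent",
                                                 "proportion")) {
  scale <- match.arg(scale)
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  missing <- setdiff(c("dbsnp_id", FREQ_GROUPS), names(x))
  if (length(missing) > 0) {
    stop("frequency table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(x[FREQ_GROUPS])
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    bad <- which(apply(vals < 0 | vals > 100, 1, any, na.rm = TRUE))
    stop("frequency value(s) outside [0, 100] in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  is_percent <- switch(scale,
    percent = TRUE,
    proportion = FALSE,
    auto = any(vals > 1, na.rm = TRUE)
  )
  if (is_percent) x[FREQ_GROUPS] <- as.data.frame(vals / 100)
  x
}

#' Bin variant frequencies into a fixed-width histogram
#'
#' Bins are half-open `[lo, hi)` in percent, except the final bin which is
#' closed at 100 so every value in `[0, 1]` lands somewhere; the counts
#' always sum to the number of variants binned.
#'
#' @param freqs Numeric vector of frequencies as proportions in `[0, 1]`.
#' @param bin_width_percent Bin width in percentage points; must divide
#'   100 (default 10).
#' @return A `frequency_histogram`: list with `bin_edges` (percent, length
#'   `nbins + 1`) and `counts`.
#' @export
#' @examples
#' h <- bin_frequencies(c(0.78, 0.02, 0.54), 10)
#' h$counts
bin_frequencies <- function(freqs, bin_width_percent = 10) {
  if (length(bin_width_percent) != 1 || bin_width_percent <= 0 ||
      100 %% bin_width_percent != 0) {
    stop("bin_width_percent must be a positive divisor of 100",
         call. = FALSE)
  }
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE)) {
    stop("frequencies must be proportions in [0, 1]", call. = FALSE)
  }
  freqs <- freqs[!is.na(freqs)]
  edges <- seq(0, 100, by = bin_width_percent)
  nbins <- length(edges) - 1
  idx <- pmin(floor(freqs * 100 / bin_width_percent) + 1, nbins)
  counts <- tabulate(idx, nbins)
  structure(list(bin_edges = edges, counts = counts),
            class = "frequency_histogram")
}

#' @export
print.frequency_histogram <- function(x, ...) {
  n <- length(x$counts)
  lab <- sprintf("[%g,%g%s", x$bin_edges[-(n + 1)], x$bin_edges[-1],
                 c(rep(")", n - 1), "]"))
  cat("Variant frequency histogram (percent bins)\n")
  for (i in seq_len(n)) cat(sprintf("  %-10s %d\n", lab[i], x$counts[i]))
  invisible(x)
}

#' Frequency histogram as a tibble
#'
#' @param histogram A [bin_frequencies()] result.
#' @return A tibble with `bin_low`, `bin_high`, `count`.
#' @export
histogram_as_tibble <- function(histogram) {
  stopifnot(inherits(histogram, "frequency_histogram"))
  n <- length(histogram$counts)
  tibble::tibble(
    bin_low = histogram$bin_edges[-(n + 1)],
    bin_high = histogram$bin_edges[-1],
    count = histogram$counts
  )
}
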
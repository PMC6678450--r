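test_that("allele frequencies are plain counting over called genotypes", {
  samples <- c("a1", "a2", "b1", "b2")
  panel <- toy_panel(samples, c("AFR", "AFR", "EUR", "EUR"))
  vcf <- write_toy_vcf(rbind(c("0/1", "1/1", "0/0", "0/0")), samples,
                       ids = "rs1")
  res <- superpop_frequencies(vcf, panel, "rs1")
  f <- res$frequencies
  expect_equal(f$AFR, 0.75)
  expect_equal(f$EUR, 0.0)
  expect_equal(f$ALL, 0.375)
  expect_equal(f$n_ALL, 8)
  expect_equal(nrow(res$unresolved), 0)
})

test_that("monomorphic reference sites give zero everywhere", {
  samples <- c("a1", "a2", "b1")
  panel <- toy_panel(samples, c("AFR", "AFR", "EUR"))
  vcf <- write_toy_vcf(rbind(c("0/0", "0/0", "0/0")), samples, ids = "rs1")
  f <- superpop_frequencies(vcf, panel, "rs1")$frequencies
  expect_equal(unname(unlist(f[c("ALL", "AFR", "EUR")])), c(0, 0, 0))
})

test_that("missing genotypes are excluded from numerator and denominator", {
  samples <- c("a1", "a2", "a3")
  panel <- toy_panel(samples, c("AFR", "AFR", "AFR"))
  vcf <- write_toy_vcf(rbind(c("0/1", "1/1", "./.")), samples, ids = "rs1")
  f <- superpop_frequencies(vcf, panel, "rs1")$frequencies
  expect_equal(f$AFR, 3 / 4)
  expect_equal(f$n_AFR, 4)
})

test_that("absent SNPs and unmatched effect alleles are reported, not dropped", {
  samples <- c("a1", "b1")
  panel <- toy_panel(samples, c("AFR", "EUR"))
  vcf <- write_toy_vcf(rbind(c("0/1", "0/0")), samples, ids = "rs1")
  res <- superpop_frequencies(vcf, panel, c("rs1", "rs_missing"))
  expect_equal(res$unresolved$dbsnp_id, "rs_missing")

  # effect allele equal to REF: complement orientation via direct counting
  res <- superpop_frequencies(vcf, panel, "rs1",
                              effect_alleles = c(rs1 = "A"))
  expect_equal(res$frequencies$ALL, 0.75)
  expect_equal(res$frequencies$effect_allele, "A")

  res <- superpop_frequencies(vcf, panel, "rs1",
                              effect_alleles = c(rs1 = "T"))
  expect_equal(res$unresolved$reason,
               "effect allele matches neither REF nor ALT")

  # coordinate matching
  res <- superpop_frequencies(vcf, panel, "1:100")
  expect_equal(res$frequencies$ALL, 0.25)
})

test_that("multi-allelic sites require an explicit effect allele", {
  samples <- c("a1", "a2")
  panel <- toy_panel(samples, c("AFR", "AFR"))
  vcf <- write_toy_vcf(rbind(c("1/2", "0/2")), samples, ids = "rs1",
                       alt = "G,T")
  res <- superpop_frequencies(vcf, panel, "rs1")
  expect_equal(res$unresolved$reason,
               "multi-allelic site without an effect allele")
  res <- superpop_frequencies(vcf, panel, "rs1",
                              effect_alleles = c(rs1 = "T"))
  # alleles called: 1,2 and 0,2 -> two copies of T among four
  expect_equal(res$frequencies$AFR, 1 / 2)
  res <- superpop_frequencies(vcf, panel, "rs1",
                              effect_alleles = c(rs1 = "G"))
  expect_equal(res$frequencies$AFR, 1 / 4)
})

test_that("VCF samples missing from the panel are excluded with a warning", {
  samples <- c("a1", "a2", "stray")
  panel <- toy_panel(c("a1", "a2"), c("AFR", "AFR"))
  vcf <- write_toy_vcf(rbind(c("0/1", "0/1", "1/1")), samples, ids = "rs1")
  expect_warning(res <- superpop_frequencies(vcf, panel, "rs1"),
                 "missing from panel")
  expect_equal(res$frequencies$ALL, 0.5)
})

test_that("frequencies are invariant to sample order and pool consistently", {
  withr::with_seed(707, {
    n_per <- 6
    supers <- rep(c("AFR", "EAS", "EUR"), each = n_per)
    samples <- sprintf("s%02d", seq_along(supers))
    gts <- matrix(sample(c("0/0", "0/1", "1/1", "./."), 5 * length(samples),
                         replace = TRUE, prob = c(.4, .3, .2, .1)),
                  nrow = 5)
    panel <- toy_panel(samples, supers)
    vcf1 <- write_toy_vcf(gts, samples)
    perm <- sample(seq_along(samples))
    vcf2 <- write_toy_vcf(gts[, perm], samples[perm])
    f1 <- superpop_frequencies(vcf1, panel)$frequencies
    f2 <- superpop_frequencies(vcf2, panel)$frequencies
    expect_equal(f1, f2)
    # pooling identity: ALL equals the count-weighted mean of group freqs
    groups <- intersect(SUPERPOPS, names(f1))
    fg <- as.matrix(f1[groups])
    ng <- as.matrix(f1[paste0("n_", groups)])
    expect_equal(f1$ALL, rowSums(fg * ng) / rowSums(ng))
  })
})

test_that("the packaged frequency table loads as proportions with auto-detected scale", {
  tab <- fixture_freqs()
  expect_equal(nrow(tab), 16)
  vdr <- tab[tab$dbsnp_id == "rs11568820", ]
  expect_equal(unname(unlist(vdr[FREQ_GROUPS])),
               c(0.54, 0.11, 0.82, 0.60, 0.77, 0.64))
  # an all-zero row is valid; out-of-range values are row errors
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(dbsnp_id = "rs1", ALL = 0, AFR = 0,
                                  AMR = 0, EAS = 0, EUR = 0, SAS = 0), path)
  z <- load_frequency_table(path)
  expect_equal(sum(unlist(z[FREQ_GROUPS])), 0)
  readr::write_tsv(tibble::tibble(dbsnp_id = "rs1", ALL = 101, AFR = 0,
                                  AMR = 0, EAS = 0, EUR = 0, SAS = 0), path)
  expect_error(load_frequency_table(path), "outside \\[0, 100\\]")
  # explicit scale override beats auto-detection
  readr::write_tsv(tibble::tibble(dbsnp_id = "rs1", ALL = 0.5, AFR = 0.5,
                                  AMR = 0.5, EAS = 0.5, EUR = 0.5,
                                  SAS = 0.5), path)
  pct <- load_frequency_table(path, scale = "percent")
  expect_equal(pct$ALL, 0.005)
})

test_that("binning the published pooled frequencies reproduces the histogram", {
  h <- bin_frequencies(fixture_freqs()$ALL, 10)
  expect_equal(h$counts, c(1, 1, 3, 3, 1, 4, 1, 2, 0, 0))
  expect_equal(sum(h$counts), 16)
  expect_equal(h$bin_edges, seq(0, 100, 10))
})

test_that("histogram counts conserve the number of variants for any width", {
  withr::with_seed(808, {
    for (w in c(5, 10, 20, 25, 50)) {
      x <- runif(137)
      expect_equal(sum(bin_frequencies(x, w)$counts), 137)
    }
  })
  # the final bin is closed at 100
  h <- bin_frequencies(rep(1, 7), 10)
  expect_equal(h$counts, c(rep(0, 9), 7))
  # empty input: all-zero counts
  expect_equal(sum(bin_frequencies(numeric(0), 10)$counts), 0)
  # width must divide 100
  expect_error(bin_frequencies(0.5, 33), "divisor of 100")
})
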
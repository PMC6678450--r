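test_that("every published prioritized SNP is common in at least one group", {
  tab <- fixture_freqs()
  above <- apply(as.matrix(tab[FREQ_GROUPS]) > 0.5, 1, any)
  expect_true(all(above))
})

test_that("the differentiation and commonness screens select the expected variants", {
  tab <- fixture_freqs()
  pr <- select_priority(tab, tab, estimator = "hudson")

  expect_true("rs11568820" %in% pr$dbsnp_id)
  vdr <- pr[pr$dbsnp_id == "rs11568820", ]
  expect_equal(round(vdr$max_fst, 4), 0.6725)
  expect_equal(c(vdr$max_fst_pop_a, vdr$max_fst_pop_b), c("AFR", "AMR"))
  expect_setequal(vdr$qualifying_pops[[1]],
                  c("ALL", "AMR", "EAS", "EUR", "SAS"))

  expect_true("rs75038630" %in% pr$dbsnp_id)
  nad <- pr[pr$dbsnp_id == "rs75038630", ]
  expect_equal(nad$max_fst, 1)
  expect_equal(nad$qualifying_pops[[1]], "EAS")

  # output is sorted by descending pooled frequency
  expect_equal(pr$ALL, sort(pr$ALL, decreasing = TRUE))
})

test_that("both screens are strict inequalities at their thresholds", {
  flat <- tibble::tibble(dbsnp_id = "rs1", gene = "G", phenotype = "P",
                         dietary_change = "D", ALL = 0.5, AFR = 0.5,
                         AMR = 0.5, EAS = 0.5, EUR = 0.5, SAS = 0.5)
  expect_equal(nrow(select_priority(flat, flat)), 0)
  # common in one group but under-differentiated: fails the F_ST screen
  # (the intergenic alcohol-dependence variant is the published example of
  # frequencies whose standard-estimator maximum stays below 0.5)
  tab <- fixture_freqs()
  inter <- tab[tab$dbsnp_id == "rs2168784", ]
  expect_lt(max_pairwise_fst(inter, "hudson")$value, 0.5)
  expect_equal(nrow(select_priority(inter, inter)), 0)
})

test_that("annotations without resolved frequencies are reported as unresolved", {
  tab <- fixture_freqs()
  ann <- dplyr::bind_rows(
    tab[1:2, c("dbsnp_id", "gene", "phenotype", "dietary_change")],
    tibble::tibble(dbsnp_id = "rs404", gene = "X", phenotype = "Y",
                   dietary_change = "Z")
  )
  expect_warning(pr <- select_priority(ann, tab), "rs404")
  expect_equal(attr(pr, "unresolved"), "rs404")
})

test_that("raising either threshold never adds a priority record", {
  tab <- fixture_freqs()
  for (est in c("hudson", "variance_ratio")) {
    n_prev <- Inf
    for (th in c(0, 0.3, 0.5, 0.7, 0.9)) {
      n <- nrow(select_priority(tab, tab, fst_threshold = th,
                                estimator = est))
      expect_lte(n, n_prev)
      n_prev <- n
    }
    n_prev <- Inf
    for (th in c(0.1, 0.5, 0.8, 0.95)) {
      n <- nrow(select_priority(tab, tab, freq_threshold = th,
                                estimator = est))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("suggestions are assigned to All when globally common, else to common groups", {
  tab <- fixture_freqs()
  # the published prioritized set itself (all 16 rows) drives the
  # per-superpopulation summary
  pr <- select_priority(tab, tab, fst_threshold = 0)
  expect_equal(nrow(pr), 16)
  sug <- assign_suggestions(pr)
  expect_equal(sug$category, c("All", "AFR", "AMR", "EAS", "EUR", "SAS"))

  all_row <- sug$suggestions[[which(sug$category == "All")]]
  afr_row <- sug$suggestions[[which(sug$category == "AFR")]]
  # PPARA variant is common in the pooled cohort: All row carries it
  expect_true("Low n–6 fatty Acid (≤7.99 g/day)" %in% all_row)
  # the intergenic alcohol-dependence variant is common in AFR only
  expect_true("no alcoholic drinks/week" %in% afr_row)
  expect_false("no alcoholic drinks/week" %in% all_row)
  afr_dis <- sug$diseases[[which(sug$category == "AFR")]]
  expect_true("Alcohol dependence" %in% afr_dis)
})

test_that("a record common nowhere contributes to no report", {
  rec <- tibble::tibble(dbsnp_id = "rs1", gene = "G", phenotype = "P",
                        dietary_change = "D", ALL = 0.2, AFR = 0.3,
                        AMR = 0.1, EAS = 0.4, EUR = 0.2, SAS = 0.1)
  sug <- assign_suggestions(rec)
  expect_true(all(lengths(sug$suggestions) == 0))
  # empty input: six empty reports, fixed order
  sug <- assign_suggestions(rec[0, ])
  expect_equal(nrow(sug), 6)
  expect_true(all(lengths(sug$diseases) == 0))
})

test_that("globally common records are partitioned away from population rows", {
  tab <- fixture_freqs()
  pr <- select_priority(tab, tab, fst_threshold = 0)
  sug <- assign_suggestions(pr)
  all_set <- sug$suggestions[[1]]
  for (i in 2:6) {
    pop_set <- sug$suggestions[[i]]
    for (s in pop_set) {
      contributors <- pr[!is.na(pr$dietary_change) &
                           pr$dietary_change == s, ]
      # at least one contributor is common in this population but not
      # globally
      expect_true(any(contributors[[sug$category[i]]] > 0.5 &
                        contributors$ALL <= 0.5))
    }
  }
  # traceability: every suggestion text equals some record's dietary change
  for (i in 1:6) {
    expect_true(all(sug$suggestions[[i]] %in% pr$dietary_change))
  }
})

test_that("suggestions deduplicate preserving first occurrence", {
  recs <- tibble::tibble(
    dbsnp_id = c("rs1", "rs2", "rs3"),
    phenotype = c("P1", "P2", "P3"),
    dietary_change = c("High folate", "High folate", "Low fat"),
    ALL = c(0.8, 0.9, 0.7),
    AFR = 0.1, AMR = 0.1, EAS = 0.1, EUR = 0.1, SAS = 0.1
  )
  sug <- assign_suggestions(recs)
  expect_equal(sug$suggestions[[1]], c("High folate", "Low fat"))
  expect_equal(sug$diseases[[1]], c("P1", "P2", "P3"))
})

test_that("rendered reports are deterministic and mirror the fixture", {
  tab <- fixture_freqs()
  pr <- select_priority(tab, tab, fst_threshold = 0)
  sug <- assign_suggestions(pr)
  h <- bin_frequencies(tab$ALL, 10)
  cfg <- simulation_config(annotation_n = 20, seed = 5)
  s <- summarize_annotations(
    apply_quality_gate(simulate_annotations(cfg)$annotations))

  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  p1 <- render_report(s, pr, sug, h, d1)
  p2 <- render_report(s, pr, sug, h, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  prio <- readr::read_tsv(p1[["priority"]], show_col_types = FALSE)
  expect_equal(nrow(prio), 16)
  expect_equal(prio$ALL[prio$dbsnp_id == "rs11568820"], 54)
  sug_out <- readr::read_tsv(p1[["suggestions"]], show_col_types = FALSE)
  expect_equal(sug_out$category, c("All", "AFR", "AMR", "EAS", "EUR", "SAS"))

  # empty store: zeroed summary, no priority rows
  empty_pr <- select_priority(tab[0, ], tab)
  p3 <- render_report(summarize_annotations(ann_record()[0, ]), empty_pr,
                      assign_suggestions(empty_pr), NULL,
                      file.path(tempdir(), "rep3"))
  prio3 <- readr::read_tsv(p3[["priority"]], show_col_types = FALSE)
  expect_equal(nrow(prio3), 0)
})
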
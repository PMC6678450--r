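Package: nutrifst
Title: Prioritization of Nutrigenetic Variants Across Human Superpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating published gene-diet interaction findings and
    prioritizing nutrigenetic variants by population differentiation. Curated
    annotation records pass a statistical quality gate (p-value and odds-ratio
    thresholds), are joined to per-superpopulation effect-allele frequencies
    extracted from VCF genotypes or precomputed tables, scored by pairwise
    fixation index (F_ST) between the five continental superpopulations of the
    1000 Genomes Project, and filtered into per-superpopulation dietary
    suggestion reports. A Balding-Nichols simulator generates population
    structured allele frequencies, genotypes and synthetic curation records so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    rlang,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
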
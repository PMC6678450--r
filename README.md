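# nutrifst

Prioritization of curated nutrigenetic variants across human
superpopulations by allele-frequency differentiation.

Gene–diet interaction studies report variants whose effect on disease risk
depends on nutrient intake (folate and *MTHFR* in colorectal cancer,
calcium and *VDR* in prostate cancer, alcohol and *ADH1B* in alcohol
dependence, ...). Because many of these variants have sharply different
allele frequencies among the five continental superpopulations of the
1000 Genomes Project (AFR, AMR, EAS, EUR, SAS), a dietary suggestion tied
to a variant can be highly relevant in one population and irrelevant in
another. `nutrifst` implements the full prioritization pipeline:

1. **Curation store** — a six-table relational model for curated findings
   (variant, association statistics, provenance, dietary suggestions, food
   content), serialized as tab-separated text, with validation and SQL
   DDL export.
2. **Quality gate** — keep findings with `p < 0.05` (candidate-gene) or
   `p < 5e-8` (GWAS) whose odds ratio lies strictly outside the null band
   `[0.97, 1.03]`; classify survivors as risk (OR above the band) or
   protective (below).
3. **Frequency extraction** — per-superpopulation effect-allele
   frequencies by direct allele counting from VCF genotypes plus a sample
   panel, or from precomputed frequency tables.
4. **F_ST screen** — pairwise fixation index between superpopulations,
   with three estimators:
   the variance ratio `F_ST = sigma2_S / sigma2_T` where
   `sigma2_S = (p_A - p_B)^2 / 4` and `sigma2_T = p̄(1 - p̄)`;
   the Hudson two-population estimator
   `(p_A - p_B)^2 / (p_A(1-p_B) + p_B(1-p_A))` (the default); and the
   sample-size-corrected Weir–Cockerham ANOVA estimator. A variant passes
   when its maximal pairwise F_ST exceeds 0.5.
5. **Reporting** — variants also common (frequency > 50%) in at least one
   group are assigned to per-superpopulation dietary-suggestion reports:
   globally common variants go to the `All` category, the rest to exactly
   the populations where they are common.
6. **Synthetic data** — a Balding–Nichols simulator (per-population
   frequencies `Beta(p(1-F)/F, (1-p)(1-F)/F)`) generating VCF genotypes,
   sample panels and curation records with a controllable quality-gate
   pass rate, so the entire pipeline is testable offline.

A fixture with the published superpopulation frequencies of 16 prioritized
nutrigenetic SNPs ships with the package
(`nutrifst_example("prioritized_snp_frequencies.tsv")`); its companion
annotation/suggestion/food tables are synthetic placeholders (the
underlying curation database is proprietary) and are named accordingly.

## Worked example

```r
library(nutrifst)

tab <- load_frequency_table(nutrifst_example("prioritized_snp_frequencies.tsv"))
pr  <- select_priority(tab, tab, estimator = "hudson")
pr[, c("dbsnp_id", "gene", "ALL", "max_fst", "max_fst_pop_a", "max_fst_pop_b")]
#>      dbsnp_id    gene  ALL   max_fst max_fst_pop_a max_fst_pop_b
#> 1   rs9997745   ACSL1 0.78 0.6000000           AFR           EAS
#> 2   rs6008259   PPARA 0.73 0.7600000           AMR           EAS
#> 3   rs3790433    LEPR 0.59 0.5443242           AFR           EAS
#> 4  rs11568820     VDR 0.54 0.6724920           AFR           AMR
#> 5    rs512535    APOB 0.53 0.5553308           AFR           EAS
#> 6  rs10495563  ADAM17 0.52 0.5454545           AFR           EAS
#> 7   rs3827730    FAF1 0.38 0.6917534           AFR           EAS
#> 8   rs2424913  DNMT3B 0.31 0.5719143           EAS           EUR
#> 9   rs1801181     CBS 0.30 0.5333216           AFR           EAS
#> 10  rs1378942     CSK 0.24 0.5575075           AFR           EUR
#> 11  rs1229984   ADH1B 0.16 0.7000000           AFR           EAS
#> 12 rs75038630 NADSYN1 0.02 1.0000000           AFR           EAS
```

Twelve of the 16 fixture SNPs pass both screens at the default thresholds
with the Hudson estimator. The *VDR* calcium-response variant is maximally
differentiated between Africans (frequency 0.11) and Admixed Americans
(0.82) with Hudson F_ST 0.6725 (variance ratio: 0.5066); the *NADSYN1*
vitamin-D variant is fixed in East Asians and absent in Africans
(F_ST = 1).

Per-superpopulation suggestions over the full 16-SNP prioritized set
(East Asian category shown):

```r
sug <- assign_suggestions(select_priority(tab, tab, fst_threshold = 0))
sug$suggestions[[which(sug$category == "EAS")]]
#> [1] "Low amounts of alcohol"      "High RBC folate"
#> [3] "no alcoholic drinks/week"    "High vitamin D (>75 nmol/L)"
```

Binning the pooled-cohort frequencies:

```r
bin_frequencies(tab$ALL, 10)
#> Variant frequency histogram (percent bins)
#>   [0,10)     1
#>   [10,20)    1
#>   [20,30)    3
#>   [30,40)    3
#>   [40,50)    1
#>   [50,60)    4
#>   [60,70)    1
#>   [70,80)    2
#>   [80,90)    0
#>   [90,100]   0
```

A thin CLI wrapper over the same functions is installed under `exec/`:

```sh
nutrifst simulate --out-dir sim/
nutrifst freqs --vcf sim/genotypes.vcf --panel sim/panel.tsv --out freqs.tsv
nutrifst prioritize --freqs freqs.tsv --out-dir report/
```

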
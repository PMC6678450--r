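---
title: "Prioritizing nutrigenetic variants by superpopulation differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing nutrigenetic variants by superpopulation differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrifst)
```

## The problem

Gene–diet interaction studies report variants whose effect on a disease or
endophenotype depends on nutrient intake: a classic example is a *MTHFR*
polymorphism whose carriers show reduced colorectal-cancer risk under high
folate intake (OR 0.62, p < 0.002). Such findings are scattered across the
literature with heterogeneous statistics, and most of the variants involved
are common, with allele frequencies that differ sharply between the five
continental superpopulations of the 1000 Genomes Project (AFR, AMR, EAS,
EUR, SAS). When a diet-responsive allele is the major allele in one
superpopulation but rare in another, a population-level dietary suggestion
becomes plausible for the former and pointless for the latter.

`nutrifst` turns that reasoning into a reproducible pipeline:

1. **Curation store** — a six-table relational model for curated findings
   (variant, statistics, provenance, dietary suggestions, food content),
   serialized as tab-separated text.
2. **Quality gate** — retain findings with study-type-appropriate
   significance and an odds ratio distinguishable from the null.
3. **Frequency extraction** — per-superpopulation effect-allele
   frequencies from VCF genotypes plus a sample panel, or from precomputed
   tables.
4. **F_ST screen** — maximal pairwise fixation index between
   superpopulations above 0.5.
5. **Commonness screen and reporting** — frequency above 50% in at least
   one group; dietary suggestions aggregated per superpopulation.
6. **Synthetic data** — a Balding–Nichols simulator so every stage is
   testable without any download.

## The quality gate

A curated finding passes when

* `p < 0.05` for candidate-gene studies, or `p < 5e-8` for GWAS findings
  (the genome-wide threshold that already embeds a Bonferroni-style
  multiple-testing correction across the genome); and
* its odds ratio lies strictly outside the null band `[0.97, 1.03]`.

The null band encodes the judgment that an OR within ±3% of 1 cannot
evidence an association regardless of its p-value. Both comparisons are
strict (`p = 0.05` fails; `OR = 0.97` fails), matching how the inequalities
are conventionally written. A passing OR above the band classifies the
variant as a *risk* factor, below the band as *protective*; classification
of an OR inside the band is an error by design, because such a record
should never have survived the gate — this invariant is property-tested.
No cross-study meta-analysis or evidence-hierarchy grading is attempted;
the gate is per-record.

`summarize_annotations()` reproduces the construction statistics a curator
would report: entry/article/gene/SNP counts, risk/protective composition
(with the risk percentage computed over classified entries and displayed
rounded half-up), and ranges of OR, p and participant counts.

## Allele frequencies

Frequencies are plain allele counting: effect alleles among called
genotypes divided by called alleles, per superpopulation and for the
pooled `ALL` cohort. Missing genotypes (`./.`) drop out of both numerator
and denominator. The pooled frequency is the count-weighted mean of the
group frequencies — never the unweighted mean — and this pooling identity
is checked on every extraction.

Because published association tables rarely state whether reported
frequencies refer to the reference, alternate or risk allele, the effect
allele is stored explicitly per annotation and all frequencies are defined
with respect to it. When the effect allele is the REF of a biallelic site
the complement of the ALT frequency results automatically from direct
counting. Multi-allelic sites are used only when an explicit effect allele
matches one of the alleles; otherwise the SNP is reported *unresolved*
rather than silently guessed. Sites are diploid autosomal; no phasing,
imputation or sex-chromosome ploidy handling is attempted.

The packaged fixture `prioritized_snp_frequencies.tsv` records the
published superpopulation frequencies (as printed percentages) of 16
prioritized nutrigenetic SNPs together with their genes, phenotypes and
dietary changes. Table loading auto-detects percent vs proportion scales
(any value above 1 implies percentages), with an explicit override.

## F_ST estimators

For two populations with effect-allele frequencies $p_A$, $p_B$ and
$\bar p = (p_A + p_B)/2$, three estimators are exposed:

* **variance_ratio** — the literal variance decomposition
  $F_{ST} = \sigma^2_S / \sigma^2_T$ with
  $\sigma^2_S = (p_A - p_B)^2 / 4$ (the population variance of the two
  frequencies) and $\sigma^2_T = \bar p (1 - \bar p)$. The divide-by-2
  variance keeps the value in $[0, 1]$.
* **hudson** — $\dfrac{(p_A - p_B)^2}{p_A(1-p_B) + p_B(1-p_A)}$, the
  standard two-population frequency estimator and the pipeline default
  for thresholding.
* **weir_cockerham** — the sample-size-corrected two-population ANOVA
  estimator on called allele counts; it can be slightly negative at low
  differentiation (the raw value is retained; thresholding floors it at
  zero). Algebraically its large-sample limit coincides with the Hudson
  form, which the test suite verifies numerically.

Degenerate pairs (both frequencies 0 or both 1) return 0 rather than an
error. Per-SNP screening uses the maximum over the 10 superpopulation
pairs, with ties broken lexicographically. Across many loci, mean F_ST is
combined as a ratio of averages (sum of numerators over sum of
denominators), the standard recommendation, because averaging per-locus
ratios is biased; for Balding–Nichols data the Hudson ratio-of-averages is
unbiased for the generating differentiation
($E[(p_A-p_B)^2] = 2Fp(1-p)$ against $E[\mathrm{den}] = 2p(1-p)$).

## Prioritization and suggestion assignment

Both screens are strict: `max F_ST > 0.5` and frequency `> 0.5` in at
least one group (`ALL` included). Output is sorted by descending pooled
frequency.

The assignment of suggestions to superpopulation reports is not uniquely
determined by the screening rules, so the package adopts an explicit
partition: a prioritized variant common in the pooled cohort contributes
its dietary change to the **All** category only; otherwise it contributes
to exactly the named superpopulations where it is common. This keeps
population rows specific — a globally common variant never re-appears
under each population. On the packaged fixture this reproduces the
expected memberships (the *PPARA* n–6 fatty-acid suggestion lands in All;
the intergenic alcohol-dependence variant's suggestion lands in AFR only).
Suggestions deduplicate per category preserving first occurrence, and
every suggestion string is traceable to a contributing record (tested).

### Known non-reproducibilities

Two published figures connected to the fixture cannot be regenerated from
the printed frequencies and are deliberately not asserted anywhere:

* a per-SNP pairwise F_ST range of 0.06–0.71 for the *VDR* variant — the
  variance-ratio maximum on the printed frequencies is 0.5066 and the
  Hudson maximum 0.6725, and no standard estimator yields both printed
  endpoints (the original computation was a spreadsheet whose estimator
  is unspecified);
* a count of 17 SNPs exceeding F_ST 0.5, against 16 printed rows.

Relatedly, the intergenic variant rs2168784 (AFR 0.62, all other groups
≤ 0.13) has a maximal Hudson F_ST of ≈ 0.469 — *below* the 0.5 screen —
although it appears in the published prioritized set; its maximal
frequency difference (0.53) does exceed 0.5, suggesting the original
screen may have operated on frequency differences. The package therefore
treats the full 16-row fixture as the prioritized set when reproducing the
per-superpopulation suggestion summary (`select_priority(...,
fst_threshold = 0)`), and documents that at default thresholds with the
Hudson estimator 12 of the 16 fixture SNPs pass. The estimator property
suite (bounds, symmetry, zero-iff-equal, monotonicity in $|\Delta p|$,
exhaustive-pair oracle agreement) stands in for the irreproducible
numbers.

The fixture's companion annotation/suggestion/food files are labelled
`_synthetic`: the underlying curation database is proprietary, so their
statistics, coordinates and food contents are placeholders that satisfy
the schema, not published values. Only the frequency table is verbatim.

## The synthetic-data generator

The generator exists so the pipeline's statistical behavior can be
verified end-to-end. It emulates:

* **Population structure** via the Balding–Nichols model: each
  population's frequency is drawn independently from
  $\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$
  around an ancestral frequency $p$, giving $E[p_i] = p$ and
  $\mathrm{Var}(p_i) = F\,p(1-p)$. This is the minimal standard model
  producing the superpopulation differentiation the F_ST screen assumes.
  Defaults: five populations labelled with the superpopulation codes,
  shared $F = 0.1$ (a realistic continental-scale differentiation),
  ancestral frequencies uniform on $[0.05, 0.95]$ to avoid near-fixed
  loci.
* **Genotypes**: unphased diploid calls drawn binomially from each
  population's frequency, written as plain VCF 4.2 with a matching
  panel file. Loci are independent — no linkage disequilibrium,
  demography, selection or admixture.
* **Curation records**: exactly `round(n × pass_fraction)` records are
  constructed to pass the default gate (significant p, OR outside the
  band, risk-side with probability `risk_fraction`), the rest to fail
  (non-significant p, or a significant p with OR inside the band). Every
  record links to one suggestion and one food item, so referential
  integrity holds by construction.

All generators are pure functions of their configuration (including the
seed): repeated calls are byte-identical, and the global RNG state is
left untouched.

What passing tests on synthetic data do **not** show: real 1000 Genomes
frequencies are not Beta-distributed around a shared ancestral value,
real panels are unbalanced, real VCFs contain multi-allelic and missing
calls at structured rates, and curated literature statistics are not
log-uniform. The synthetic results validate the *computations*, not the
biological conclusions.

## Problem sizes and numerical choices

The calibration checks use 5,000 Balding–Nichols loci at $p = 0.5$,
$F = 0.10$ (mean pairwise Hudson F_ST expected within 0.10 ± 0.02, the
tolerance following from Beta/binomial sampling error at that size) and a
genotype round-trip of 2,000 loci × 200 diploid samples per population
(per-population frequency correlation above 0.99). These sizes were chosen
as the smallest at which the sampling error of the checked quantities is
an order of magnitude below the asserted tolerances.

Other numerical conventions: report percentages round half-up;
frequency-histogram bins are half-open `[lo, hi)` in percent with the
final bin closed at 100 so counts always conserve the input; degenerate
F_ST denominators return 0; `weir_cockerham` requires at least two called
alleles per group; empty stores summarize to zero counts and `NA` ranges
rather than erroring.

## Interfaces

The R functions are the primary interface. A thin command-line wrapper
(`exec/nutrifst`, subcommands `ingest`, `filter`, `freqs`, `fst`,
`prioritize`, `simulate`, `schema`) exposes the same functions for shell
pipelines and contains no logic of its own. `emit_schema()` exports the
six-table relational model as SQL DDL executable in an embedded engine.
Identifier fields (dbSNP, PubMed, HGVS) are stored strings; no live
database lookups are performed.
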
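# neosurv

Neoantigen cataloging and survival stratification for tumor cohorts.

## The problem

Somatic missense mutations in a tumor can create **neoantigens** —
mutated peptides presented by the patient's own HLA class I molecules
and absent from the normal proteome, hence visible to CD8+ T cells.
`neosurv` is for cancer immunoinformaticians and biostatisticians who
want to ask, on a cohort with exome, expression, HLA and outcome data:
does the number or predicted *quality* of neoantigens relate to
survival, and does the tumor microenvironment (cytotoxic activity,
regulatory infiltration, checkpoint expression) modify that relation?

The package implements the full analysis as composable, tibble-first
functions:

* **Prediction cascade** — enumerate all mutant/wild-type **9-mer**
  pairs around expressed missense variants (gene expression > 2);
  keep peptides with percent rank ≤ 2 and IC50 < 500 nM on the
  patient's alleles; compute the **differential agretopicity index**
  DAI = IC50\_wt − IC50\_mut (nM); assign nested quality tiers
  (`DAI10`: DAI > 10; `DAI10_HIGHAFF`: additionally IC50\_mut < 50 nM);
  attribute candidates to HLA-A/B/C; summarize per patient including
  **TMB** (mutations/Mb).
* **Epitope homology** — ungapped 9-vs-9 comparison of each neoepitope
  against a local catalog of validated self and pathogen epitopes:
  homology fraction > 0.70 (BLOSUM62 similarity by default) **and**
  ≥ 2 identical residues at the TCR-contact positions {1, 4, 5, 8};
  samples classified `none` / `self` / `pathogen`.
* **Survival statistics** — Kaplan–Meier product-limit curves,
  Mantel–Cox log-rank tests, and the two stratification schemes used
  throughout: first-vs-third quartile (tails only) and below-vs-above
  mean (full partition).
* **Microenvironment profiles** — two-cluster hierarchical clustering
  of patients on immune gene sets with 100-iteration bootstrap
  stability (HIGH/LOW infiltration), plus single and combined
  marker-gene strata (GZMA, FOXP3, PD-L1/CD274).
* **Synthetic cohorts** — a seeded generator for every input (variants,
  proteome, expression, HLA, survival, epitope catalog with planted
  homologs) and a deterministic toy binding predictor, so the entire
  pipeline runs offline and deterministically.

Fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 displays.

## Worked example

Simulate a 115-patient cohort at the default study conditions (all
deaths observed, mean burden 2.56 mutations/Mb over 38 Mb, protective
above-mean GZMA effect of −0.7 log-hazard) and run every stage:

```r
library(neosurv)

cfg <- run_config(sim = simulation_config(n_patients = 115, seed = 7),
                  paper_mode = TRUE)
report <- run_all(cfg)
report
#> <neo_run_report>
#>   patients: 115
#>   neoantigen records: 2510 | DAI tier: 1681 | high-affinity: 127
#>   homology classes: class_none 108, class_self 3, class_pathogen 4
#>   survival tests: 18

report$fractions[, c("label", "numerator", "denominator", "percent")]
#> # A tibble: 2 × 4
#>   label               numerator denominator percent
#>   <chr>                   <int>       <int>   <dbl>
#> 1 dai10_of_candidates      1681        2510   67.0
#> 2 highaff_of_dai10          127        1681    7.56

head(report$survival$tests[, c("score", "mode", "chi_square", "p_value")], 5)
#> # A tibble: 5 × 4
#>   score       mode     chi_square p_value
#>   <chr>       <chr>         <dbl>   <dbl>
#> 1 tmb         quartile     0.575    0.448
#> 2 tmb         mean         0.0320   0.858
#> 3 neoantigens quartile     0.0600   0.806
#> 4 neoantigens mean         1.37     0.243
#> 5 dai10       quartile     1.09     0.297
```

Reading the output: 2510 (mutant peptide, allele) records pass the
binding filters across 115 patients; 67% gain binding strength by more
than 10 nM over wild type (`DAI10`), and 127 of those also bind below
50 nM.  The homology stage classifies 108/3/4 samples as
none/self/pathogen (the generator planted 3 self and 2 pathogen
homologs; one planted patient carried homologs of both classes and
resolves to the priority class).  The survival table reports one
log-rank test per score × split — here, as expected under the default
generator (where only GZMA affects hazard), neoantigen-load strata show
no significant survival difference.

Per-patient results live in `report$patient_summaries` (TMB, tier
counts, per-locus counts); `glance(report)` gives the one-row overview;
`plot_tier_funnel(report)` and `autoplot()` on any KM fit draw the
standard displays.

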
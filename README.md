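# oacevo

Multi-region, multi-timepoint analysis of tumour evolution for oesophageal
adenocarcinoma (OAC) cohorts — or any cancer cohort with several somatic
SNV call sets per tumour.

Standard curative treatment for OAC is platinum-based chemotherapy (with
or without radiotherapy) followed by surgery, and genomic intra-tumour
heterogeneity (ITH) is a known obstacle to it. Given two spatially
distinct treatment-naive biopsies per tumour — and, where available,
post-treatment samples — this package quantifies that heterogeneity and
how therapy reshapes it, for researchers analysing multi-region
sequencing cohorts:

* **Mutation populations** — mutations *shared* by both treatment-naive
  biopsies versus *private* to one; with post-treatment samples,
  *unique-pre* versus *unique-post* (`classify_spatial()`,
  `classify_temporal()`).
* **Mutational signatures** — SBS-96 catalogues with simplex-constrained
  least-squares exposure refitting (quadratic programming), a 10% cohort
  screen, and iterative 5% per-population pruning; APOBEC (SBS2/13),
  BRCA-like (SBS3) and MMR/MSI groups dichotomised into present/absent
  (`fit_exposures()`, `refit_with_pruning()`,
  `population_signature_profile()`).
* **Platinum enrichment** — the odds ratio for C>A (or G>T) mutations in
  CpC (or GpG) context within 41-base mutation-centred windows, the
  genomic footprint of platinum chemotherapy (`platinum_enrichment()`).
* **Clonal decomposition** — multi-sample binomial-mixture clustering of
  cancer-cell fractions with BIC model selection (up to 40 clones, 100
  restarts), a 1% clone-size filter, automated clone-tree construction
  and fishplot-ready per-timepoint prevalences (`cluster_mutations()`,
  `prune_clones()`, `infer_tree()`, `timepoint_prevalence()`).
* **Neoantigen agretopicity** — IC50 <= 500 nM binder filtering and the
  differential agretopicity index, DAI = IC50(WT) − IC50(MT), summarised
  per population or clone (`filter_binders()`, `compute_dai()`,
  `dai_by_population()`).
* **Survival association** — Kaplan-Meier/log-rank and stage-adjusted Cox
  models of disease-specific survival (censored at 60 months) against
  signature presence (`km_logrank()`, `cox_adjusted()`).

The core statistic of the signature step is the exposure vector
**w** = argmin ‖c/|c| − P·w‖² subject to w ≥ 0, Σw = 1, where `c` is the
96-channel catalogue of a mutation population and `P` the signature
matrix; the clustering step maximises the binomial mixture likelihood
Σᵢ log Σₖ πₖ Πₛ Binom(aᵢₛ | dᵢₛ, cᵢₛ·φₖₛ) over clone CCFs φ.

Because the motivating patient-level WGS data are under restricted
access, the package includes a first-class synthetic-cohort generator
(`simulate_cohort()`) that plants known clone structures, signature
mixtures, platinum footprints and survival effects, so the whole pipeline
is testable end to end.

## Worked example

```r
library(oacevo)

# a seeded synthetic cohort at study-default conditions:
# 29 tumours, two treatment-naive biopsies each
cohort <- simulate_cohort(sim_config(seed = 1))
cfg    <- pipeline_config()

spatial <- run_spatial(cohort, cfg)
head(spatial$proportions[, c("tumour_id", "n_keys", "prop_shared")], 3)
#> # A tibble: 3 × 3
#>   tumour_id n_keys prop_shared
#>   <chr>      <int>       <dbl>
#> 1 TUM01        700       0.501
#> 2 TUM02       3157       0.762
#> 3 TUM03       2083       0.721

mean(spatial$proportions$prop_shared)
#> [1] 0.6420634
spatial$paired_test
#> # A tibble: 1 × 3
#>   statistic     p.value estimate
#>       <dbl>       <dbl>    <dbl>
#> 1      7.08 0.000000107    0.284
```

About 64% of each tumour's mutations are shared between its two biopsies
(the planted cohort mean is 62.8%), and the paired t-test confirms shared
mutations significantly outnumber private ones. Signature presence then
links to survival:

```r
spatial$survival$APOBEC$km$logrank_p   # patients with APOBEC in private mutations
#> [1] 0.002409519
tidy(spatial$survival$APOBEC$cox)[, c("hr", "conf.low", "conf.high", "p.value")]
#> # A tibble: 1 × 4
#>      hr conf.low conf.high p.value
#>   <dbl>    <dbl>     <dbl>   <dbl>
#> 1  3.55     1.49      8.43 0.00415
```

Patients carrying the (planted) APOBEC signature in their private
mutations die significantly earlier (hazard ratio ~3.6 after stage
adjustment; the generator planted HR 4). Clonal structure for one tumour:

```r
clonal <- run_clonal(cohort, pipeline_config(max_clusters = 8, restarts = 6),
                     tumours = "TUM02")
clonal$models$TUM02
#> <clone_model> K = 3 clones over 2 sample(s)
#>    TUM02_T1 TUM02_T2
#> C1    1.000    1.000
#> C3    0.000    0.803
#> C4    0.411    0.000
autoplot(clonal$models$TUM02)   # CCF profile plot
```

A founder clone (C1) spans both biopsies; C3 and C4 are each private to
one region — heterogeneity that single-biopsy sequencing would miss.
(Clone ids keep their pre-pruning labels; a sub-1% clone was excluded
here, which is why C2 is absent.)

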
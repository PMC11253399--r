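---
title: "Methods: multi-region, multi-timepoint tumour evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region, multi-timepoint tumour evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oacevo)
```

## Scope and data model

`oacevo` analyses somatic SNV calls from tumours sampled in several spatial
regions (typically two treatment-naive biopsies) and, optionally, at a
second timepoint after neoadjuvant chemo(radio)therapy, as in oesophageal
adenocarcinoma (OAC) trial cohorts. The unit of analysis is the *mutation
key* (chromosome, position, reference and alternate allele); a mutation may
be *called* in any subset of a patient's samples, and the pattern of
carriage across samples drives everything downstream.

All user-facing functions take and return tibbles so analyses compose with
the pipe; fitted objects (`exposure_fit`, `clone_model`, survival
summaries) carry `tidy()`, `glance()` and `autoplot()` methods.

## Mutation populations

For the two treatment-naive biopsies of a tumour, a mutation called in both
is **shared**, and one called in a single biopsy is **private**
(`classify_spatial()`). When post-treatment samples exist, a mutation
called in *all* samples is **shared**, one called in at least one
treatment-naive but no post-treatment sample is **unique-pre**, and the
reverse is **unique-post** (`classify_temporal()`). Mutations present in
some-but-not-all samples spanning both timepoints fit none of these
definitions; we assign them an explicit **partial** label and exclude them
from unique-pre/unique-post contrasts rather than folding them in
silently. For patients with more than two treatment-naive biopsies the
spatial pair is an explicit argument (the convention is to pick the two
biopsies most similar in cellularity).

Presence means *called*: no pileup-based rescue of uncalled sites is
attempted at this stage. Rescued read counts are used only by the clonal
decomposition, which models evidence strength explicitly.

## Mutational signatures

Catalogues are built on the pyrimidine-centric SBS-96 trinucleotide
alphabet; purine-reference records are reverse-complemented onto it.
Exposure fitting (`fit_exposures()`) minimises the squared error between
the frequency-normalised catalogue and a convex combination of signature
columns — least squares constrained to the probability simplex, solved
exactly as a quadratic programme (`quadprog::solve.QP`). Weights are
therefore mutation-fraction exposures.

Signature selection is two-staged:

1. **Cohort screen (10%)** — every sample's full catalogue is fitted
   against the candidate catalogue; signatures reaching at least 10%
   exposure in at least one sample are retained. The screen uses whole
   samples, not populations.
2. **Per-population pruning (5%)** — each mutation population (shared,
   private, unique-pre, unique-post, or one clone's mutations) is fitted
   against the retained set, signatures below 5% are removed, and the
   population is refitted on the survivors. We iterate this prune-and-fit
   step to a fixed point so the output guarantee is clean (every retained
   weight is at least 5%, or a single signature remains); a single-pass
   variant is available via `iterate = FALSE`. The largest-weight signature
   is never pruned, so the result is always a valid exposure vector.

The platinum signatures SBS31 and SBS35 are added to the candidate set
*only* for pre-/post-treatment analyses, where treatment-induced mutagenesis
is the question. Populations smaller than 50 mutations are fitted but
flagged low-confidence; the flag is a guard against over-interpreting tiny
catalogues, not a hard filter.

A group (APOBEC = SBS2 + SBS13; MMR/MSI = SBS20 + SBS26 + SBS44; BRCA-like
= SBS3) is **present** in a population exactly when it survives the 5%
pruning — the dichotomisation used for contingency tables and survival
stratification.

### The bundled signature catalogue is synthetic

The genuine COSMIC catalogue is licensed by COSMIC and is not
redistributed here. `sbs_reference()` builds a deterministic synthetic
stand-in: each signature concentrates probability mass on its well-known
characteristic channels (APOBEC C>T/C>G at TpC, the OAC-hallmark T>G at
NpTpT, platinum C>A/C>T at CpC, CpG deamination for SBS1, and so on) over
a signature-specific smooth background that makes every column linearly
independent. These profiles are suitable for simulation and testing; real
data should be analysed against the real catalogue loaded with
`read_signature_matrix()`.

## Platinum enrichment odds ratio

Platinum chemotherapy leaves C>A substitutions in CpC context. For a
mutation population, `platinum_enrichment()` compares the odds that a
mutated cytosine (C>A on either strand; G>T records are
reverse-complemented) has a cytosine as its 5' neighbour against the
background odds of CpC among all reference cytosines — counting both
strands — inside 41-base windows centred on each mutated base.

Choices a reader should know:

* "CpC" is read as *5' neighbour is C* on the C-containing strand; the
  source convention is ambiguous, so the 3' variant is available via
  `context_side = "3p"`.
* The background pools the per-mutation windows **with multiplicity**
  (overlapping windows count once per mutation), because the statistic is
  defined per mutation-centred region; a genome-wide background is a
  different statistic and is out of scope.
* When any cell of the 2x2 table is zero, 0.5 is added to every cell
  (Haldane correction) and the result flagged, keeping the odds ratio
  finite on small populations. Zero eligible mutations yield a flagged,
  undefined result rather than a number.

## Clonal decomposition

Read counts for the union of a tumour's mutation keys are collated across
samples (`build_count_matrix()`), with uncalled cells taken from a pileup
table (alt = 0 is informative absence; cells missing from the pileup are
flagged). Each mutation's cancer cell fraction (CCF) in a sample follows
the standard multiplicity-based estimator from VAF, purity and local copy
number (`ccf()`).

`cluster_mutations()` fits a finite mixture over per-sample CCF centroids
by EM on binomial read-count likelihoods: a mutation from clone *k*
produces alt reads Binomial(depth, c * phi[k, s]), with *c* the linear
VAF-per-CCF factor from purity, copy number and multiplicity. The M-step
maximises each centroid by a guarded 1-D Brent search, so the observed-data
log-likelihood is non-decreasing up to the optimiser tolerance. Model size
is chosen by BIC over K = 1..40 (the scan stops after three consecutive
non-improving sizes); each size takes the best of 100 seeded restarts
(defaults; both are configurable). One restart per size is initialised by
splitting the worst-fitting clone of the previous size's best solution,
which recovers small subclones much more reliably than random starts
alone. This binomial-mixture EM deliberately replaces the external
variational beta-binomial tool the field often uses, while preserving its
operating contract: at most 40 clusters, 100 restarts, clones holding
under 1% of a tumour's mutations excluded (`prune_clones()`), prevalences
averaged per timepoint (`timepoint_prevalence()`), and per-clone analyses
restricted to mutations unique to the clone (`clone_mutations()`).

Clone trees (`infer_tree()`) are built by a greedy heuristic standing in
for manual review: clones in decreasing mean prevalence, each attached to
the smallest already-placed ancestor satisfying per-sample containment and
the sum rule, both with tolerance 0.05; ties prefer the larger-prevalence
candidate, then the lexicographically first id. Unattachable clones become
children of the founder, and the model is flagged a forest if the founder
fails to dominate every sample.

## Neoantigens and DAI

Predicted epitopes are consumed as input (mutation key, HLA allele,
wild-type and mutant IC50 in nM); prediction itself is upstream and out of
scope. Binders are epitopes with mutant IC50 <= 500 nM (inclusive), and
the differential agretopicity index is DAI = IC50(wild-type) -
IC50(mutant), positive when the mutant binds more strongly. Group
summaries are per epitope record by default because the aggregation level
is not fixed by convention; `per_mutation_best = TRUE` reduces each
mutation to its best binder first.

## Survival and testing toolkit

Disease-specific survival is censored at 60 months *at read time*, so no
downstream code ever sees uncensored times. Kaplan-Meier curves and the
log-rank test come from the survival package; the stage-adjusted Cox model
encodes cTNM stage as one ordinal covariate (IB = 1, IIB = 2, III = 3,
IVA = 4) with Breslow tie handling by default, and complete separation is
flagged rather than reported as a finite hazard ratio. Paired t, Fisher
exact, Kruskal-Wallis and Benjamini-Hochberg FDR adjustment wrap base R.

## The synthetic cohort generator

Because the motivating WGS data are under restricted access, every stage
is exercised on `simulate_cohort()`. Defaults are fixed to the study
conditions the pipeline assumes; they are not tuning knobs:

* 29 tumours, two treatment-naive biopsies each; optional post-treatment
  samples (two per tumour) for treatment analyses.
* Clone counts drawn from a binomial centred on the midpoint of 1-9 (so
  the cohort averages ~5 clones and near-clonal tumours are rare, as
  multi-region cohorts show); up to 3 additional post-only clones.
  Candidate clones must be *detectable* — prevalence at least 0.12
  wherever present, at least 0.25 somewhere, and at least 0.1 (L-infinity)
  from every other clone's profile — or they are dropped from the planted
  truth, which keeps recovery well-posed.
* 50-250 mutations per clone. This is a deliberate desk-scale choice
  (real WGS assigns thousands of mutations per clone); it preserves every
  statistical contrast while keeping a full cohort analysis in minutes.
* Cohort shared-mutation fraction targeted at 0.628 with per-tumour
  targets dispersed +/-0.2, reproducing both the cohort mean (62.8%) and
  the wide per-tumour spread real cohorts print. The founder clone's
  mutation count (or, when the target lies below the structural floor,
  the size of subclones detectable in both biopsies) is calibrated against
  the *expected called* counts, which integrate the binomial detection
  probability of each clone's mutations at the simulated depth.
* Purity 0.38-0.94, depth ~Poisson(60), binomial read counts (an
  overdispersion stress-test would use a beta-binomial; we keep binomial
  as the default to match the clustering model).
* A mutation is "called" in a sample when it has >= 3 alt reads, minus a
  6% per-sample false-negative caller rate. The rate is derived from the
  best cross-biopsy concordance such cohorts report (~88.7% shared in the
  most clonal tumour implies ~6% per-sample call loss); without it a
  single-clone tumour would show an unrealistic 100% shared fraction.
* APOBEC (SBS2/13 with co-occurring SBS3) is planted in the
  private-to-one-biopsy clones of ~40% of tumours, and survival times are
  exponential with hazard ratio 4 for those patients (baseline median 35
  months, censoring at 60), so presence-vs-survival associations are
  recoverable at cohort size.
* Post-only clones carry 30% planted platinum-style C>A events, 90% of
  them at CpC cytosines.

What the generator does *not* emulate: chromosome-scale genomes and
mutation hotspots, copy-number variation (all sites are diploid with
multiplicity 1), germline contamination, indels, subclonal copy number,
and caller false positives. Green tests therefore demonstrate that the
implementation recovers what it models — not that the model captures every
property of real sequencing data.

## Numerical choices and degenerate inputs

* Exposure QP adds a 1e-10 ridge to the Gram matrix for numerical
  positive-definiteness; weights are clipped at zero and renormalised.
* Signature matrix columns must sum to 1 within 1e-3 (then renormalised);
  channel rows are canonicalised to the standard order on read.
* Zero catalogues, empty sample lists, single-group survival and constant
  Cox covariates are errors or flagged results, never silent numbers.
* EM clamps success probabilities to [1e-9, 1 - 1e-9]; clone labels are
  ordered by mean prevalence (founder first) so output is invariant to
  label switching.
* All simulation randomness flows from a single integer seed;
  sub-analyses derive fixed offsets from it, and repeated runs are
  byte-identical.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run, by design, at desk
scale: exposure recovery on 5,000-mutation catalogues; clone recovery on a
300-mutation, 3-clone tumour and a 30-tumour end-to-end cohort
(`max_clusters = 10`, 4 restarts); log-rank calibration over 2,000 null
cohorts of 80 patients; platinum calibration on 2,000-mutation
populations. These sizes were chosen so the full battery completes on one
CPU in minutes while keeping every statistical conclusion stable across
seeds.

## Known limitations

* The clustering replaces a variational beta-binomial model with a
  binomial-mixture EM; with strong read-count overdispersion it will
  over-split clones unless depths are modest.
* Clones whose prevalence profiles coincide across all samples are
  unidentifiable in principle; the generator avoids planting them, and on
  real data such clones will merge.
* The tree heuristic is a reviewable approximation of manual curation; it
  does not explore alternative topologies or quantify uncertainty.
* The synthetic signature catalogue shares only the *shape* of the real
  signatures' characteristic peaks; exposures fitted against it are not
  comparable to exposures fitted against the real catalogue.
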
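---
title: "Quantifying cistrome heterogeneity across a patient cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cistrome heterogeneity across a patient cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromeHet)
```

## The problem

A transcription factor's cistrome differs between patients far more than
between replicates of one sample. When dozens of tumors are profiled by
ChIP-seq, the pooled set of binding sites splits into a small core seen
in most patients and a long tail seen in few or one. `cistromeHet`
formalizes this picture — a prevalence-ranked site universe — and
provides the statistics needed to ask what the heterogeneity does:
where mutations fall, which enhancers drive expression, and whether
site usage stratifies outcome. This vignette explains the models,
parameters and numerical choices; the README shows the API.

## Universe construction

All coordinates follow the BED convention on disk (0-based, half-open)
and live as 1-based closed `GRanges` in memory. Two intervals interact
only when they share at least one base pair; book-ended intervals do
not.

Peaks within `tss_window_bp` (default 1000 bp) of any TSS are removed
first, so the universe represents distal regulatory elements; the
window is half-open, so a peak starting exactly 1000 bp downstream
survives.

Merging is **single linkage**: peaks from all patients form one
universe site whenever they overlap, possibly through a chain of
intermediates. We chose merging over strict coordinate intersection
because it yields a single, reproducible universe with one prevalence
per site; the alternative (counting occurrence on some reference
patient's coordinates) depends on the reference choice. This is a
genuine modelling decision — chained overlaps can fuse two adjacent
elements — and it is the one interpretation under which a pooled
universe has a well-defined size. A patient counts once per site no
matter how many of their peaks fall in it, because prevalence is a
per-patient quantity; their site score is the maximum peak score.

Occupancy is recorded as `log(score + 1)`, absent sites as exactly 0.
The `+1` keeps the transform defined at score 0 and keeps presence
strictly positive, so absence and presence are separable in a design
matrix (see the GLM section).

### Ranking and binning

Sites are ranked by prevalence (descending), ties broken by chromosome
(lexicographic) then start. Bins:

| bin | definition | default |
|-----|------------|---------|
| UN  | prevalence = 1 | fixed |
| SH  | prevalence ≥ ⌈`sh_fraction` · n⌉ | `sh_fraction` = 0.68 → 60/88 |
| PS  | everything else | — |

`sh_fraction` generalizes the "more than two-thirds of the cohort"
notion of a shared site; the unique bin never depends on it, so moving
the threshold only slides the SH/PS boundary. The per-prevalence
consensus (`prevalence_consensus()`) emits each level's regions minus
anything already emitted at a higher level, so levels partition the
occupied genome even if the site list contains nested regions.

## Enrichment statistics

* **Hypergeometric bin enrichment.** For a bin of n sites with x
  annotated out of K annotated among N total, we report the strict
  upper tail P(X > x). The strict form is the printed convention we
  follow; because it can never flag x = 0 and differs from the
  inclusive tail by one pmf term, the inclusive P(X ≥ x) is available
  via `inclusive = TRUE`. Both are validated against explicit
  `choose()` summation.
* **Mutation O/E.** Observed/expected = (mut_in/bp_in)/(mut_total/
  genome_bp). The Fisher test treats every base pair as a Bernoulli
  mutation trial (2 × 2 table of mutated/unmutated bp inside vs outside
  the regions); this matches the "mutation rate" framing and is exact
  for the sparse counts involved. Zero mutations overall is reported as
  O/E = NA, p = 1. Point mutations and SNPs are width-1 intervals.
* **Density-equality permutation test.** Gaussian-kernel densities of
  the two samples on a common `ngrid`-point grid (default 100) with one
  shared bandwidth — the normal-reference rule on the pooled sample,
  matching the "equal" model assumption in which both groups share a
  smoothing scale. The statistic is the integrated squared difference;
  group labels are permuted (default 1000 times) and
  p = (1 + #{perm ≥ obs})/(1 + n_perm), which is exact under
  exchangeability and never returns 0.
* **Two-sample comparisons.** Pooled-variance two-tailed t and
  two-sided KS with asymptotic p. Degenerate inputs are explicit: zero
  pooled variance with equal means gives NA (the statistic is 0/0);
  with unequal means the statistic is ±Inf and p = 0.

## Loop linking and CNA partitioning

A loop is kept when exactly one anchor overlaps a promoter; that anchor
assigns the gene(s) — a bidirectional promoter assigns the loop to both
genes — and the other anchor is the enhancer anchor.
Promoter–promoter loops are dropped by default (configurable), since
neither anchor is unambiguously the regulator. A gene's landscape is
the deduplicated set of universe sites overlapping its enhancer
anchors.

Copy-number exclusivity is evaluated **per gene**: a non-neutral
segment is gene-exclusive if it touches that gene's CDS and none of its
linked sites, enhancer-exclusive in the mirror case, and mixed
otherwise (excluded from both). Genome-wide exclusivity would let a
neighbor gene's elements veto a classification that is meaningful for
the gene under study, which is why the per-gene reading was chosen. The
expression reference for log2 fold changes is the median over
copy-neutral patients for that gene (patients with no non-neutral
segment touching its CDS or landscape); expression input is assumed
log2-scale. Gene dependency filtering uses a strict `score < -0.5`
cutoff, the conventional threshold for calling a CRISPR-screen
dependency.

## The occupancy–expression GLM

Per gene: `y = β0 + Σ_j β_j x_j + ε`, Gaussian, identity link, fitted
over patients with `x_j = log(score + 1)` and 0 for absent peaks.
Encoding absence as 0 (rather than dropping patients per site) keeps
one common design across all patients; the coefficient is then a
combined presence-and-dose effect, which is the quantity of interest
when asking whether an enhancer's occupancy tracks expression.

Numerical choices:

* Constant columns, and columns exactly collinear with the retained
  design (QR pivoting), are dropped and reported in
  `dropped_columns`; if more non-constant predictors remain than
  patients − 1 the fit errors with guidance rather than silently
  truncating the landscape.
* Interactor p-values are the two-sided t probabilities of the
  coefficient/SE ratios; the model p is the F test against the
  intercept-only model. Leverage and Cook's distance are returned so
  the linearity and single-point-influence assumptions can be checked
  per gene.
* Permutation p-values use the likelihood-ratio statistic
  n·log(RSS_reduced/RSS_full). Two modes are provided because the two
  natural references disagree on what to permute: `"model"` permutes
  the response against the intercept-only null; `"interactor"`
  (default) residualizes covariate j on the remaining design and
  permutes those residuals — the conditional-permutation scheme used by
  permutation-of-regressor GLM inference, which preserves the other
  enhancers' association structure. Neither is privileged; both are
  exposed. p = (1 + #{LR ≥ obs})/(1 + n_perm) with `n_perm = 1000` by
  default, so the smallest attainable p is 1/1001.
* The genome-wide scan uses raw p < 0.001 by default, matching the
  convention of reporting un-adjusted interactor significance;
  Benjamini–Hochberg is available behind `adjust = "BH"`. Genes are
  fitted independently, and the scan output is invariant to gene
  processing order.

## Outcome scoring

Each patient's universe sites are intersected with good- and
poor-outcome annotations; the good:poor count ratio classifies the
patient (> 1.2 good, < 0.8 poor, otherwise mixed). Ratios exactly at a
threshold fall to mixed: the strict inequalities on both sides leave
the boundary unassigned, and mixed is the only class that does not
overstate the evidence. A patient with poor-count 0 and positive
good-count is good (the ratio's limit); both counts 0 is NA. Group
composition is compared with the Freeman–Halton exact test (the r × c
extension of Fisher's exact test, two-sided by probability ordering).
Per-patient annotation counts can be restricted to the least-prevalent
fraction of the ranking (`stratum_fraction`, default off; the pipeline
config exposes 0.10 for bottom-decile analyses), and counting is per
universe site, not per raw peak — per-site counting is invariant to how
a patient's peak caller fragmented a region.

## The synthetic-cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. It
emulates:

* **Prevalence**: `1 + BetaBinomial(n − 1, 0.3, 2.0)` — most sites in
  very few patients, a thin shared tail (about 2–3 % of sites reach
  the 68 % threshold at n = 88). A point-mass option supports
  degenerate tests.
* **Geometry**: sites and 2 kb promoter windows are placed uniformly
  with rejection, non-overlapping and well separated (≥ 2.4 kb) on a
  150 Mb three-chromosome genome, so truth prevalence is unambiguous
  and TSS exclusion provably removes nothing. Carrier peaks are
  jittered around each site but always contain its midpoint; single
  linkage therefore reconstructs exactly one universe site per truth
  site, which makes universe-recovery checks exact.
* **Scores**: log-normal with mean log score `3 + 2 · prevalence/n`
  and sd 0.5 — positive, right-skewed, positively correlated with
  prevalence, as peak-caller significance scores are.
* **Expression**: `y = β0_g + Σ β x + N(0, 0.5)` over the gene's
  linked enhancers, with a configurable causal subset (fraction 0.25,
  or exactly `causal_per_gene`); effect size 1.5 per unit log score.
* **Mutations**: Poisson per site at `rate_bg · rr(bin) · width` with
  `rate_bg = 4 × 10⁻⁴`/bp — the order of magnitude of pooled
  primary-plus-metastatic somatic catalogs — and relative rates
  SH 5 / PS 2 / UN 1; background draws at `rate_bg` outside sites.
* **Outcome**: half the patients are cases; each case gains each
  metastasis-annotated site with extra probability 0.15. Met sites are
  sampled preferentially from low-prevalence sites; good/poor outcome
  sets are sampled uniformly, so per-patient good:poor ratios straddle
  the 1.2/0.8 thresholds and the three-class split is populated
  (prevalence-weighted outcome sets degenerate to a single class).

Identical seeds give bit-identical cohorts and byte-identical fixture
files; `write_fixtures()` uses full-precision (`%.17g`) numeric
formatting so a read-back reproduces the cohort exactly.

What the generator does **not** emulate: read-level signal, peak-caller
miscalls (every truth site is called in every carrier), linkage
disequilibrium, clonal structure, batch effects, or enhancer
cooperativity (effects are additive). Passing tests therefore
demonstrate correctness of the computations under a clean generative
model, not robustness to the technical noise of real cohorts.

## Validation strategy and problem sizes

The suite validates every exact statistic against independent
enumeration oracles (hypergeometric tails, 2 × 2 Fisher, 2 × 3
Freeman–Halton, KS D, brute-force overlap-graph components), and the
pipeline end to end against generator truth. The standard validation
sizes, chosen to exercise the study-scale regime while keeping the
suite quick, are: universe recovery on 5,000 sites × 88 patients; GLM
null calibration on 2,000 fitted genes (uniformity) and 500 genes ×
199 permutations (rejection rate at α = 0.05 inside the 95 % binomial
interval); causal recovery on 50 genes with one causal enhancer each
(β = 1.5, noise sd 0.5), requiring the causal site to attain the
landscape-minimum interactor p in ≥ 90 % of genes; mutation-rate
recovery of the 5× shared-site rate within 20 %. `scripts/acceptance.R`
recomputes all of these from scratch for any seed.

## Known limitations

* Single linkage can chain adjacent elements into one site in dense
  regions; a strict-intersection universe is deliberately out of scope.
* The GLM is linear and additive; saturating or cooperative enhancer
  effects are not modelled.
* Expression must arrive normalized (e.g. log TMM); no count-level
  processing is done.
* The Fisher mutation test assumes at most one mutation per base pair
  per catalog entry; recurrent positions count once per record.
* Asymptotic KS p-values are used throughout (ties in count data make
  exact p-values unavailable); with heavy ties the test is
  conservative.
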
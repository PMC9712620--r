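# cistromeHet

Transcription-factor cistromes — the genome-wide binding-site repertoires
measured by ChIP-seq — vary strikingly between patients with the same
tumor type. For the androgen receptor (AR) in primary prostate cancer,
only a small minority of binding sites are shared by most of a cohort,
while the bulk are seen in a handful of patients or in just one.
`cistromeHet` is an R package for quantifying that heterogeneity and
tracing its consequences: which sites are shared or private, where
somatic mutations concentrate along the sharing spectrum, which enhancers
actually drive expression of their looped target genes, and whether
heterogeneous site usage separates patients by clinical outcome.

It is aimed at computational genomicists working with multi-patient
ChIP-seq (or ATAC-seq) peak sets plus matched expression, chromatin-loop,
mutation, copy-number, and outcome data.

## What it computes

**Site universe and prevalence ranking.** Per-patient peak sets (after
removal of peaks within 1 kb of any TSS) are pooled and merged by single
linkage — peaks sharing ≥ 1 bp, possibly through a chain, form one
universe site. Each site's *prevalence* is the number of patients with at
least one overlapping peak. Sites are ranked by prevalence and binned:

- **SH** (shared): prevalence ≥ ⌈0.68 · n⌉ patients (60 of an 88-patient
  cohort),
- **UN** (unique): exactly one patient,
- **PS** (partially shared): everything in between.

**Enrichment along the ranking.** For an annotation set (cell-line
cistromes, tumor/normal/metastasis-associated sites, outcome sites,
super-enhancers, SNVs…) each bin is tested with the hypergeometric upper
tail P(X > x); somatic mutation burden is summarized as the
observed/expected rate ratio O/E = (mut_in/bp_in)/(mut_total/genome_bp)
with a two-sided Fisher exact test on per-bp counts; distribution
contrasts use pooled-variance t, two-sided Kolmogorov–Smirnov, or a
permutation test of kernel-density equality.

**Enhancer–gene landscapes and expression GLMs.** Loop anchor pairs with
exactly one anchor on a promoter link universe sites to genes. For each
gene, expression across patients is modelled as

```
y_p = β0 + Σ_j β_j · x_jp + ε_p,   x_jp = log(score_jp + 1)  (0 if absent)
```

a Gaussian identity-link GLM on the patients' log peak scores at the
linked sites. Per-enhancer ("interactor") p-values come from the
coefficient t ratio, with empirical permutation likelihood-ratio
p-values (response permutation for the whole model, conditional
covariate permutation per enhancer). A genome-wide scan collects all
(site, gene) pairs with interactor p below 0.001.

**CNA partitioning and outcome scoring.** Copy-number segments are
classified per gene as gene-exclusive (CDS only), enhancer-exclusive
(linked sites only) or mixed, with expression log2 fold change over
copy-neutral patients attached. Patients are classified by their ratio
of good- to poor-outcome sites (> 1.2 good, < 0.8 poor, else mixed) and
contrasted across outcome groups with the Freeman–Halton exact test; per-
patient annotation counts are compared case vs control with a KS test.

**Synthetic cohorts.** `cohort_spec()` / `generate_cohort()` simulate all
of the above with known ground truth: non-overlapping sites with
beta-binomial prevalence, log-normal peak scores rising with prevalence,
loops, causal-enhancer-driven expression, bin-dependent mutation rates,
CNA segments, and case/control labels with a metastasis-site excess in
cases. The whole pipeline is validated end to end against this truth.

## Worked example

```r
library(cistromeHet)

spec    <- cohort_spec(n_patients = 24, n_sites = 600, n_genes = 40, seed = 42)
cohort  <- generate_cohort(spec)
universe <- rank_and_bin(build_universe(cohort$peak_sets), sh_fraction = 0.68)
universe
#> site_universe: 600 sites across 24 patients
#>   bins (SH >= 17 patients): SH 15 | PS 365 | UN 220

met <- annotate_overlap(universe, cohort$annotations$met)
hypergeom_bin_enrichment(universe, met$flags)
#>   bin   N  K   n  x expected direction  p_value
#> 1  SH 600 60  15  0      1.5  depleted 7.98e-01
#> 2  PS 600 60 365 54     36.5  enriched 2.13e-08
#> 3  UN 600 60 220  6     22.0  depleted 1.00e+00

landscapes <- build_gene_landscapes(
  filter_promoter_loops(cohort$loops, cohort$promoters), universe)
scan <- genome_scan(landscapes, universe, cohort$expression, alpha = 0.001)
scan$n_significant_sites; scan$n_significant_genes
#> 54 sites / 29 genes significant

sh <- universe$sites[universe$sites$bin == "SH"]
mutation_rate_fisher(cohort$mutations, sh, sum(spec$chrom_sizes))
#> SH mutation O/E = 4.80 (p = 1.24e-05)
```

The metastasis-associated annotation (drawn preferentially from
low-prevalence sites) is enriched in PS sites and depleted from SH; the
scan recovers the simulated causal enhancers; the shared-site mutation
O/E is close to the simulated 5× relative rate.

`run_pipeline(pipeline_config(...))` chains all stages (simulate or
ingest → universe → enrichment → linking → GLM scan → outcome), writes
each stage's table plus a `manifest.json` with parameters, seed and
output hashes, and is byte-reproducible for a fixed config and seed.

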
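# dyadshare

Multi-cohort analysis of mother–infant gut microbiome sharing, from species
presence/absence down to strain-level vertical transmission.

## The scientific problem

The maternal gut is a major reservoir of the pioneering microbes that
colonize an infant's gut. Quantifying that contribution across cohorts
requires a chain of analyses on shotgun-metagenomic profiles of matched
mother–infant pairs (dyads):

* **Species sharing.** A species is *shared* in a dyad when its relative
  abundance is strictly positive in both the infant sample and the mother's
  delivery-window sample (postnatal days 0–7), irrespective of abundance.
  Species shared in at least one dyad of *every* study form the
  cross-cohort **core shared set**.
* **Strain-level transmission.** From each species' marker-gene SNP
  haplotypes (one dominant strain per sample), a neighbor-joining tree is
  built on p-distances; the **strain distance** between a mother and her
  infant is the patristic (branch-length) distance normalized by the
  maximum leaf-pair distance of that species' tree. A strain is called
  vertically transmitted when `d < 0.1` (strict inequality at the
  conservative threshold).
* **Cohort-aware testing.** Mother/infant contrasts use a study-blocked
  (van Elteren) Wilcoxon rank-sum test,
  `Z = sum_b (W_b − E[W_b]) / sqrt(sum_b Var[W_b])` with mid-ranks and
  tie-corrected variances, plus Benjamini–Hochberg FDR. Covariate effects
  on shared-species composition are screened per sampling-time bin by
  univariate PERMANOVA (Bray–Curtis, 1000 permutations, groups of < 3
  samples excluded), and per-feature covariate associations are additive
  linear models on arcsine-square-root transformed abundances (reported at
  FDR < 0.25).
* **Prediction.** Whether a target species/strain occurs shared in an
  infant is predicted from the *maternal* species profile with random
  forests (1000 trees) and stochastic gradient-boosted stumps, evaluated by
  leave-one-study-out (LOSO) AUC, with near-zero-variance and correlation
  feature filters computed on training folds only, mean-decrease-Gini
  feature rankings, top-k retraining curves, and delivery-mode-stratified
  refits.

Because the underlying sequencing cohorts are external, the package ships a
**synthetic dyad-cohort generator** (`generate_cohort()`) with known
ground-truth transmission events, multi-study structure, longitudinal
sampling and covariate effects; every analysis stage is tested against it.

## Worked example

```r
library(dyadshare)

cohort  <- generate_cohort(cohort_config(n_studies = 3, dyads_per_study = 20, seed = 42))
md      <- assign_time_bins(cohort$metadata)
pairing <- pair_dyads(md)                       # delivery-window pairing

sharing <- compute_sharing(cohort$species, pairing)
core    <- core_shared_set(sharing)
core
#> core shared set: 30 species across 3 studies (60 dyads)
head(sort(core$prevalence_across_dyads, decreasing = TRUE), 3)
#> ...s__Bifidobacterium_longum  0.567
#> ...s__Escherichia_coli        0.533
#> ...s__Bacteroides_uniformis   0.517

calls <- call_transmission(cohort$haplotypes, pairing, threshold = 0.1)
#> strain calls: 2408 evaluable pairs, 93.4% shared below 0.1

dyn <- shared_fraction_dynamics(
  list(species  = sharing,
       pathways = compute_sharing(cohort$pathways, pairing)), md)
dyn$by_bin[dyn$by_bin$time_bin %in% c("1 wk.", "12 mo."), ]
#>      kind time_bin n_pairs mean_fraction ci_lo ci_hi
#>   species    1 wk.      60         0.986 0.971 1.000
#>   species   12 mo.      60         0.644 0.614 0.675
#>  pathways    1 wk.      60         0.999 0.997 1.001
#>  pathways   12 mo.      60         0.955 0.947 0.963

shared_count_vs_age(sharing)$slope
#> 0.0066 shared species per day (p = 5.3e-09)
```

The core set here contains the highly transmitted, highly prevalent
species of the generator's pool (led by *Bifidobacterium longum*,
*Escherichia coli* and *Bacteroides uniformis*); shared-pathway fractions
dominate shared-species fractions in every time bin, reflecting the
species-to-function coupling of the generative model; and the number of
shared species rises with infant age.

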
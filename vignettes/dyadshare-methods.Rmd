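---
title: "Models and methods behind dyadshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyadshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dyadshare analyzes how much of an infant's early gut microbiome is shared
with — and vertically transmitted from — the mother, across several
independent sequencing cohorts at once. This vignette explains the models
each stage implements, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and the numerical and design choices made where more than one
reasonable option existed.

## Sharing and time structure

Sharing is presence/absence: a feature (species or pathway) is shared in a
dyad when its relative abundance is strictly positive in both members.
Strictness matters because MetaPhlAn-style profiles report exact zeros for
undetected clades, so `> 0` is the natural detection rule. Every
dyad-aware computation first pairs each infant sample with one maternal
sample from a *delivery window* (postnatal days 0–7 of infant age,
`pair_dyads()`); when several qualify the nearest in time is used, ties
going to the earliest. Each infant of a multiple birth forms its own dyad
with the shared mother.

Continuous sampling days are discretized by `assign_time_bins()` into
closed integer ranges: mothers into pregnancy (gestational days 189–224),
delivery (postnatal 0–7) and postpartum (8–480); infants into birth (0–1),
1 wk. (2–7), 1 mo. (8–30), 3 mo. (31–90), 6 mo. (91–180) and 12 mo.
(181–480). The `day_scale` column disambiguates gestational from postnatal
days, since maternal sampling mixes both scales. Samples outside every
range are labelled `unbinned` and excluded from bin-stratified analyses.

Shared fractions are infant-referenced by default
(`n_shared / infant_feature_count`): the scientific narrative is the
maternal contribution *to the infant*, so the infant's feature count is
the natural denominator; the mother-referenced fraction is also returned.
A species counts as shared for a dyad if it is shared in at least one
(mother delivery sample, infant sample) pair; per-sample records are
retained for the dynamics. The core shared set requires sharing in at
least `min_dyads_per_study` dyads (default 1) in *every* study, which
makes the set monotonically non-increasing in both the threshold and the
number of studies.

## Strain model

Each species contributes one dominant-strain SNP haplotype per sample: an
aligned sequence over A/C/G/T/gap. Similarity uses pairwise deletion —
only positions where *neither* sequence has a gap are compared — because
gaps in these haplotypes are missing SNP calls, not indels. Distances are
`1 − similarity` (p-distances).

Trees are built by Saitou–Nei neighbor joining on the p-distance matrix.
NJ was chosen over likelihood methods because it is deterministic,
dependency-free, and exactly distance-faithful on additive matrices, which
is the property the downstream thresholding needs; externally built
newick trees can be substituted anywhere a tree is accepted. NJ's
occasional negative branch lengths are clamped to zero with the residual
pushed onto the sibling branch.

The strain distance of a sample pair is the patristic distance divided by
a species-level normalization constant, by default the **maximum
leaf-pair patristic distance** of that species' tree. Max-pair
normalization bounds distances in [0, 1], which is what makes a fixed
threshold meaningful across species with very different marker-gene
divergence; total-branch-length and median-pair variants are selectable.
A pair is called transmitted when the normalized distance is strictly
below 0.1. Species with fewer than three haplotypes fall back to
p-distances normalized by the species' maximum pairwise p-distance, and a
species whose sampled haplotypes are all identical (zero constant) gets
distance 0.

Two caveats follow from the normalization, and both are visible in the
package's own tests. First, when a species' sampled haplotypes all come
from a single strain family (for example a single carrier mother), the
maximum pairwise distance is itself only measurement noise and the ratio
becomes uninformative; calls for such species should be treated with
caution. Second, the distance resolution is one substitution over the
alignment length, so short alignments make the 0.1 threshold coarse: with
1000 sites and ~5% between-strain divergence the threshold corresponds to
roughly ten substitutions, comfortably above the one-to-three
substitutions a faithful transmission chain accumulates at the default
within-strain rate.

## Blocked nonparametric testing

Cross-cohort contrasts must not let between-study composition differences
masquerade as mother/infant differences, so two-group comparisons use a
stratified (van Elteren) rank-sum statistic: within each block (study) the
group-1 mid-rank sum `W_b` is centred at its permutation expectation and
the blocks are combined as `Z = Σ(W_b − E_b) / sqrt(Σ Var_b)` with
tie-corrected variances. Blocks containing a single group contribute
nothing. With one block this is exactly the normal-approximation Wilcoxon
rank-sum test. The `exact = TRUE` option replaces the normal
approximation with the exhaustive within-block permutation distribution
(block distributions are convolved; mid-ranks are half-integers so the
convolution is exact in integer arithmetic). The k-group generalization
accumulates per-block rank-sum vectors and conditional covariances and
forms a chi-square quadratic form via an eigen pseudo-inverse; with one
block it reproduces the tie-corrected Kruskal–Wallis test, and with two
groups it coincides with the squared van Elteren Z.

PERMANOVA is delegated to vegan's `adonis2` (the same route the field
uses), wrapped to fix exactly 1000 unrestricted label permutations, the
`(1 + #{F* ≥ F}) / (1 + n_perm)` p-value convention, seed control,
removal of samples with missing covariates, and exclusion of covariate
groups smaller than three samples. Permutations are not restricted within
study by default; restricting them is a caller-level choice of the
distance matrix subsetting. Simpson diversity is reported as
Gini–Simpson (`1 − Σ p²`); the variant choice is otherwise arbitrary and
documented rather than hidden.

Multiple testing uses Benjamini–Hochberg throughout: 5% FDR for
differential-abundance scans, 25% for the covariate association models —
the lenient conventional threshold for multivariable microbiome
association screens.

## Covariate associations

`fit_associations()` fits, per feature, an ordinary linear model of
`asin(sqrt(abundance/100))` on the target covariate plus adjusters, all as
fixed effects with one-hot categorical coding against reference levels
(vaginal delivery, exclusive breastfeeding, normal BMI), so coefficient
signs read as the effect of the non-reference condition. The
boosting-based feature-selection step that some association toolchains
prepend is deliberately not reimplemented: it is a heuristic pre-filter,
and the reported quantity is the linear-model coefficient. This is a
documented fidelity gap, not an oversight.

## Prediction

The unit of prediction is the dyad: features are the maternal
delivery-window species abundances, the label is whether the target
species (or strain) is shared at any infant timepoint. Only *admissible*
targets — both classes present in every study — are evaluated, a
precondition of leave-one-study-out testing. Feature pre-processing is
the conventional near-zero-variance filter (zero variance, or frequency
ratio > 95/5 with ≤ 10% unique values) followed by greedy correlation
filtering at |r| > 0.9 (the member of the worst pair with the larger mean
absolute correlation is dropped; ties drop the lexicographically later
name). By default both filters are computed on the training folds only;
`pooled_filter = TRUE` reproduces the alternative of filtering once on the
pooled matrix, which leaks no labels but does leak held-out-study
marginals.

The random forest uses 1000 trees and default `mtry`; importance is mean
decrease in Gini, and `gini_top_k_curve()` retrains on the top-k features
ranked on the training fold only. The gradient-boosting route uses
xgboost's stochastic gradient-boosted stumps with the conventional GBM
settings (depth 1, 100 trees, shrinkage 0.1, bag fraction 0.5); the
minimum terminal-node size of 5 *observations* is translated to
`min_child_weight = 1.25` because the logistic hessian contributes at
most 0.25 per observation — copying "5" verbatim would forbid any split
on small training folds. Cross-validated tree-count selection is not
performed; the tree count is fixed at 100. AUC is the rank-based
Mann–Whitney statistic with ties counted one half, so it is invariant
under monotone transforms of the scores.

## The synthetic cohort generator

`generate_cohort()` emulates the four inputs of a multi-study dyad
meta-analysis with known ground truth. Its generative model, per species:

* Mothers carry the species with probability `prevalence_mother`;
  carriage is constant across a mother's timepoints, but her dominant
  strain is replaced by an unrelated population strain with probability
  `mother_strain_replacement` (default 0.3) between consecutive
  timepoints. Infant strains are stable.
* A circulating population of `n_population_strains` (default 200)
  strains per species is generated by mutating a species ancestor at
  `between_strain_divergence` (default 0.05) per site; every sampled copy
  of a strain receives independent noise at `within_strain_mut_rate`
  (default 0.001). The two rates must be separated — this is checked at
  generation — and with the defaults the mother–infant p-distance
  distributions of transmitted and unrelated pairs are empirically
  disjoint.
* At birth, each mother-carried species seeds the infant with probability
  `transmission_prob`, multiplied by `delivery_effect` for C-section
  births; the infant haplotype is then a mutated copy of the mother's
  delivery-sample haplotype. Otherwise the species may still colonize the
  infant environmentally (probability `prevalence_infant_base`, times
  `feeding_effect` for non-exclusively breastfed infants) with a uniform
  onset age, so richness and species-level sharing grow with age.
* Continual exposure: an environmental acquisition of a mother-carried
  species copies the *mother's* strain with probability
  `late_transmission_prob × transmission_prob` (default 0.5 × p). These
  events are vertical transmission, are recorded in the ground truth, and
  are what makes shared-*strain* counts grow with infant age. Calibration
  experiments that estimate the single birth-transmission rate set
  `late_transmission_prob = 0` so the configured rate is the estimand.
* Abundances are log-normal with per-study intercepts (studies are
  distinguishable, as real cohorts are), renormalized to percent per
  sample. For C-section infants, species with `delivery_effect ≠ 1` get
  an abundance multiplier that decays linearly to 1 by day 365 — the
  delivery-mode signature is strongest in early bins and fades, which is
  the profile the covariate variance scan is expected to recover.
* Pathways are derived from species through a species→pathway weight map,
  so a pathway is present wherever any carrier species is. This
  redundancy forces the shared-pathway fraction to dominate the
  shared-species fraction, the qualitative functional-overlap phenomenon.
* Covariates other than delivery mode and feeding (antibiotics, BMI
  class, sex, ...) are assigned independently of composition, which is
  what makes them usable as negative controls in the variance scan.

The default pool of 32 species mirrors the taxa that dominate
mother–infant studies: Bacteroides and Bifidobacterium as prevalent,
highly transmitted, C-section-suppressed lineages; skin/hospital taxa
(Staphylococcus, Klebsiella, Veillonella, Haemophilus, Rothia,
Clostridium) as C-section-enriched, rarely transmitted early colonizers;
and adult-gut commensals common in mothers but rarely transmitted.
Delivery mode is Bernoulli per dyad (P(C-section) = 0.3) and feeding per
infant (P(exclusive) = 0.6), so both strata are populated for stratified
analyses. Defaults for sampling: six infant timepoints (days 1, 5, 21,
60, 120, 330, one per time bin) and two maternal timepoints (gestational
day 200, postnatal day 3).

What the generator does *not* emulate — and hence what green tests do not
establish about real data: sequencing reads and profiling error (presence
is noiseless, so detection-limit effects on sharing are absent),
within-sample strain mixtures, recombination, temporal strain replacement
beyond i.i.d. mutation, compositional correlations between species, body
sites other than the gut, and realistic species richness (a 32-species
pool makes absolute shared fractions much higher than in real cohorts;
only their ordering and dynamics are meaningful).

## Numerical choices and degenerate inputs

Haplotypes default to 1000 sites so the p-distance resolution (0.001) sits
well below the threshold scale. Mid-ranks are used everywhere ties occur.
All-zero profiles have richness 0 and diversity defined as 0; a pair of
all-zero profiles has no defined Bray–Curtis dissimilarity and errors.
Zero-variance features are dropped (with a message) from association
models; rank-deficient designs rely on R's least-squares aliasing.
Infants are guaranteed at least one colonizer from birth (a pioneer
species drawn by colonization propensity) so no sample is empty and
percent renormalization is always defined. Every stochastic operation
takes an explicit seed; identical configuration and seed give
byte-identical written cohorts.

The package's own verification uses deliberately sized problems: unit
tests run on cohorts of 2–3 studies × 8–15 dyads with 60–500-site
haplotypes; the transmission-recovery and effect-recovery checks use 3
studies × 50 dyads with 1000-site haplotypes; null calibrations use 100
PERMANOVA repetitions at 1000 permutations and a few dozen
label-shuffled LOSO fits.

## Known limitations

The blocked tests are asymptotic unless the exact option is feasible;
`adonis2` R² profiles from univariate scans do not partition variance
jointly; the association models have no random effects, so repeated
samples per subject are treated as independent (matching the original
analysis choice, but a real limitation); xgboost stands in for classical
GBM with a fixed tree count; and the max-pair strain-distance
normalization is only meaningful when a species' alignment spans more
than one strain family.
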
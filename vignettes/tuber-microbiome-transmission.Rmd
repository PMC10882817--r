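---
title: "Quantifying vertical transmission of seed tuber microbiota"
author: "tuberTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertical transmission of seed tuber microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberTrace)
```

## The problem

Potatoes are propagated vegetatively: seed tubers grown in one production
field are planted the next season in another. The tuber surface carries a
dense microbial community assembled in the field of production, and part
of that community may travel with the tuber — an inoculum that the
emerging daughter plant inherits. tuberTrace quantifies this
intergenerational inheritance from amplicon sequence variant (ASV) count
tables: which taxa of the parent community reappear on the daughter
tubers, roots and sprouts, which are lost, which are newly acquired from
the resident soil, and how much of the offspring community each category
represents.

The central objects are occupancy sets. A **detection set** is the set of
ASVs considered present in a named group of samples under an explicit
rule (at least `minCount` reads in at least `minSamples` samples; the
default is one read in one sample, applied to filtered, rarefied tables).
All downstream quantities are set algebra over detection sets plus
relative-abundance accounting:

* **Field-unique ASVs** — present in the focal production field's samples
  and in no other field's samples of the same variety, sample type and
  marker. These act as tracers: an ASV unique to Field 1 that reappears
  on a daughter tuber can only have come with the seed tuber.
* **Shared / lost / acquired** — the exclusive categories of a
  source-to-destination comparison (present in both, source only,
  destination only). "Unique-unique" is the subset of shared ASVs that is
  field-unique on both sides; it is nested inside shared and never
  double-counted.
* **Source attribution** — for sprouts germinated in a soil-free system,
  the presence pattern of each sprout ASV across the five seed tuber
  compartments (adhering soil, peel, heel end, eye, flesh). Because
  sprout-unique and compartment-derived ASVs partition the sprout
  community, their cumulative relative abundances are exact complements.

## Preprocessing model

Raw feature tables are cleaned in a fixed order, which the pipeline logs:

1. **Off-target removal.** For 16S tables, ASVs annotated as mitochondria
   or chloroplast, or not assigned to Bacteria, are dropped; for ITS
   tables, ASVs annotated as Viridiplantae or Protista, or not assigned
   to Fungi. Annotation flags are case-insensitive substring matches on
   the semicolon-separated lineage ranks; the domain rule inspects the
   top rank only, so a phylum such as *Proteobacteria* never satisfies
   the "bacteria" rule by accident.
2. **Rare-ASV filter.** An ASV is removed when its total read count is
   below 30 *or* it occurs in fewer than 3 samples. The bounds are
   strict "fewer than", so a total of exactly 30, or presence in exactly
   3 samples, is retained. Prevalence counts samples with at least one
   read; no higher per-sample floor is imposed.
3. **Rarefaction.** Each sample is subsampled without replacement
   (multivariate hypergeometric) to a common depth — 10,000 reads for the
   bacterial generation tables, 4,000 for fungal, 8,000 for compartment
   tables are the depths used in the motivating design. Samples below
   depth are dropped and listed in the run report. The RNG seed is a
   required argument and recorded, so every rarefied table is exactly
   reproducible.

Whether off-target removal precedes or follows the rare-ASV filter is a
convention (the order affects totals near the filter boundary); tuberTrace
fixes off-target removal first and records the order in the pipeline log.

## Community statistics

Bray–Curtis dissimilarity, principal coordinates analysis and PERMANOVA
are implemented from first principles in the package (the test suite
cross-checks them against vegan and classical MDS, which are never used
as the implementation).

* **Bray–Curtis**: `d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`.
* **PCoA**: Gower double-centering `B = -1/2 J D^2 J`,
  `J = I - 11'/N`, eigendecomposition, coordinates scaled by the square
  root of positive eigenvalues. Negative eigenvalues (expected for
  non-Euclidean dissimilarities) are reported, not corrected; proportion
  explained is computed over the positive spectrum. Eigenvalues below
  `1e-8` times the spectral radius are treated as null axes.
* **PERMANOVA**: `SS_T = (1/N) sum_{i<j} d_ij^2`,
  `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, `SS_A = SS_T - SS_W`,
  `F = (SS_A/(a-1)) / (SS_W/(N-a))`, `R2 = SS_A/SS_T`. The permutation
  p-value uses free random relabelling,
  `p = (1 + #{F_perm >= F_obs})/(1 + nPerm)` with 999 permutations by
  default; no restricted permutation strata are offered because the
  analyses it supports report one factor at a time. An `exact = TRUE`
  mode enumerates all `N!` relabellings for tiny designs (`N <= 8`),
  which the tests use to verify the sampled p-value against complete
  enumeration. Permuted statistics are compared with a `1e-12` slack so
  ties (e.g. fully equidistant designs) count as exceedances.
* **Richness and evenness**: observed ASV count per sample on the
  rarefied table, compared across groups with the standard
  Kruskal–Wallis test (mid-ranks, tie correction). Evenness, where
  requested, is Pielou's `J = H'/ln(S)`; this index is a convention of
  the package, chosen because no specific index is mandated by the
  analyses it mirrors.

One-way ANOVA with Tukey's HSD (Tukey–Kramer pooling for unequal group
sizes) compares the agglomerated abundance of a fixed ASV set across
sample types. The compact letter display is built by insert-and-absorb
from the pairwise rejections, so two groups share a letter exactly when
Tukey does not separate them at the chosen level. When the between-group
sum of squares is zero to machine precision the test degenerates to
`F = 0, p = 1` rather than `0/0`.

## The synthetic generator

Because the motivating study's raw reads live in an external archive, the
package ships a generator that reproduces the *structure* the analysis
assumes, with recorded ground truth (`SyntheticTruth`): a shared
log-normal core community; field-specific ASV sets, pairwise disjoint and
disjoint from the core; a multiplicative genotype effect on a random ASV
subset; a next-generation expectation
`pi * seed profile + (1 - pi) * soil profile` against a dominant
trial-field soil community; nested compartment pools with decreasing
retention (adhering soil down to flesh), producing the expected richness
gradient; and a sprout expectation that mixes the five compartment
profiles and amplifies a small favored set.

Counts are Dirichlet-multinomial: composition drawn from
`Dirichlet(theta * profile)`, reads multinomial at the configured depth.
Key defaults and the reasoning behind them:

* `nFields = 3`, `nVarieties = 2`, `nSamples = 4`, `depth = 10000` —
  the replication and sequencing effort of the seed tuber design the
  package mirrors.
* `pi = 0.2` — by default 80% of the expected next-generation abundance
  is environment-acquired, echoing the observation that roughly three
  quarters of daughter communities come from the trial field. This is a
  default, not a claim; it is the generator's dial for transmission
  strength.
* `theta = 500` — overdispersion of replicate samples. The samples being
  emulated are composites (peels of 6 tubers pooled per replicate, 50
  tubers per compartment sample), which averages single-tuber
  variability; a moderately high concentration is therefore realistic.
  The slot is exposed for studies of noisier designs.
* `compartmentRetention = (1, 0.8, 0.6, 0.4, 0.2)` — a linear richness
  gradient from adhering soil to flesh, the qualitative pattern reported
  for tuber compartments.
* `sproutFavoredN = 18`, `sproutSelection = 50` — mirrors the roughly
  eighteen sprout-dominant taxa; a 50-fold amplification puts their
  cumulative share near 80–90% of the sprout community. Favored ASVs are
  drawn from the 60th–90th abundance percentile of the flesh pool
  (present in every compartment by nesting): modestly abundant on the
  tuber, so that the selection factor rather than the base-abundance
  lottery determines sprout dominance, matching the observation that
  sprout-favored microbes are lowly abundant in all tuber compartments.
  Mixture-then-selection is the chosen generative order; the biology
  motivates selection on whatever arrives, not arrival of pre-selected
  taxa.

The generator validates the pipeline, and its limits should be kept in
mind: it has no spatial structure, no phylogenetic signal, no
compositional interactions between taxa, identical soil for all groups,
and field-unique sets that are exactly disjoint by construction. Passing
recovery tests therefore demonstrates correctness of the accounting
machinery under the assumed model, not performance on real sequencing
data.

`recoverTransmissionFraction()` is a validation estimator for the
generator (closed-form least-squares projection of the mean destination
profile onto the seed–soil segment, clipped to `[0, 1]`), not an
inference method for field data.

## Numerical conventions

* Printed percentages use half-up rounding (`percentHalfUp()`), integer
  by default and one decimal where the mirrored analyses print one; raw
  fractions are always carried alongside.
* Destination abundance of transmission categories is the unweighted
  mean of per-sample cumulative relative abundances (scale-invariant
  across samples); a pooled-reads mode is available behind
  `mode = "pooled"` since the choice between the two is not dictated by
  the design.
* "Most abundant" ASVs are ranked by mean relative abundance across the
  sprout replicates, strictly above the 1% threshold.
* Detection defaults to one read in one sample on the filtered, rarefied
  table, and the rule is recorded in every `DetectionSet`.

## Problem sizes used in validation

The shipped tests and the acceptance script run the generator at reduced
but structurally faithful sizes — typically 60–300 core ASVs, 25–120
field-unique ASVs per field, soil communities of 80–500 ASVs, depths of
2,000–50,000 reads — chosen so the whole validation suite completes on a
single CPU in a few minutes while keeping every recovery margin wide
(transmission-fraction error bounded by 0.05 at depth 50,000 with 8
samples; field-unique sensitivity above 0.9 for ASVs expected at more
than 5 reads per sample). Published worked-example counts (overlap
region sizes, group totals) are used directly as inputs where the
quantity under test is pure set arithmetic.

## Known limitations

* Off-target screening trusts the provided lineage strings; misannotated
  taxa pass through.
* PERMANOVA is one factor at a time; sequential multi-factor
  decompositions are out of scope.
* The Venn/UpSet and Sankey outputs are tabular; graphics are left to
  dedicated plotting packages.
* Set-based transmission accounting cannot distinguish true vertical
  transmission of cosmopolitan taxa from independent acquisition — only
  field-unique tracers carry that information, which is precisely why
  the package centers on them.
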
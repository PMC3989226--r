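---
title: "Colour spaces for discrete melanic patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour spaces for discrete melanic patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanospace)
```

## The problem

Colour variation in many aposematic insects is variation in *melanisation*:
discrete black patterns on each body part expand or contract between
populations, producing named colour morphs that have long confused
taxonomy. Direct colour measurement from photographs is unreliable for
pinned museum material (curved sclerites, reflectance, fading), so the
practical unit of observation is a semi-quantitative one: each body part
is scored on a small set of discrete pattern states — *modalities* —
ordered from lightest to darkest by an expert. This package provides the
full analysis chain for such data: ordination of specimens into a colour
space, validation against morph labels, quantification of phenotypic
integration and modularity, and congruence testing of colour structure
against genetic, geographic and climatic structure.

## Fuzzy coding and the colour space

### Dual-extreme coding

A character with $n$ ordered modalities is represented by two
complementary variables — membership in the lightest extreme and in the
darkest extreme. A modality of rank $r$, counting from 0 at the extreme
*not* described by the variable, scores $r/(n-1)$; the complementary
variable scores $1 - r/(n-1)$. Consequences that the package tests as
invariants:

* extremes score exactly 0 and 1, intermediates are equally spaced;
* light + dark = 1 in every cell, so every specimen has an identical row
  margin of $K$ (the number of characters) and therefore identical mass —
  equal weight — in the correspondence analysis;
* the coding is invertible: the light value times $n - 1$ recovers the
  integer modality rank;
* within a character, the light value is strictly monotone in the
  ordination of modalities.

The reference character set (`velutina_characters()`) has 23 characters
over five body regions with 2–5 modalities each, 72 modalities in total.
Modality order is supplied by the user and treated as authoritative; the
package does not attempt to infer light-to-dark polarity. Missing codings
are rejected by default (`on_missing = "error"`), because silently
imputing or dropping cells would distort the constant CA margin; an
explicit `"drop"` mode removes incomplete specimens and reports the count.
Characters that are (nearly) constant are a data-preparation concern:
`character_frequency_filter()` reports per-character variant frequencies
against a threshold (default 0.05) but nothing is filtered silently.

### Correspondence analysis

`correspondence_analysis()` implements the standard CA contract directly:
the matrix is scaled to a correspondence table $P$, row and column masses
are its margins, and the standardized residuals
$(P - rc^\top)/\sqrt{rc^\top}$ are decomposed by SVD. Squared singular
values are the eigenvalues; their sum — the total inertia — equals the
Pearson chi-square statistic of the table divided by its grand total,
which is the oracle the unit tests check to $10^{-10}$. Rows and columns
are placed at mass-scaled principal coordinates, so that Euclidean
distances between row coordinates reproduce chi-square distances between
row profiles (also tested against a brute-force double loop).

Numerical choices:

* singular values below $10^{-10}$ times the largest are trivial and
  dropped; with variation in every character the colour space has exactly
  $K$ non-trivial dimensions, because the centred dark column of each
  character is the negation of its centred light column;
* an input with a single distinct row is *degenerate*, not an error: the
  result carries zero dimensions, zero inertia and a `degenerate` flag;
* all-zero rows or columns in a non-degenerate input are errors — they
  indicate an upstream coding problem rather than a numerical accident.

The multiple-correspondence variant applies the identical engine to the
one-hot indicator matrix (one binary column per modality), trading the
linear per-character directions of the fuzzy coding for a finer but less
interpretable space; the package exposes it for comparison, and the tests
assert the two engines agree exactly on a shared input.

### Morph cross-validation

`crossvalidate_morphs()` uses leave-one-out canonical variate analysis:
for each held-out specimen the group centroids and pooled within-group
covariance are re-estimated, and the specimen is assigned to the nearest
centroid in canonical space — equivalently, under the pooled Mahalanobis
metric. Details the method needed to fix (none of which are standardized
in the literature):

* the pooled covariance is ridge-regularized ($\lambda = 10^{-8}
  \,\mathrm{tr}(W)/p$) whenever its smallest eigenvalue falls below
  $10^{-10}$ of the largest; this covers the common case of a character
  that is constant within every group, which otherwise leaves a
  numerically random direction dominating the metric;
* ties are broken towards the alphabetically first morph label;
* morphs with a single specimen cannot contribute a within-group
  covariance and are excluded with a warning;
* by default all non-trivial dimensions are used (`n_dims` configures a
  truncated space).

One property worth knowing when interpreting accuracies near chance: with
$g$ equiprobable groups the LOO estimate is slightly *below* $1/g$ on
average, because the held-out specimen's own group centroid is estimated
from $n_g - 1$ points and is therefore noisier than the other centroids.
The acceptance test for chance-level behaviour references the observed
accuracy to the label-permutation null of the same estimator rather than
to a naive binomial around $1/g$. Both the specimen counts and the
fraction correct are reported, so that published percentages can be
checked against either convention.

### Integration and modularity

Light and dark vectors of one character are antipodal in column space, so
the direction of melanisation variation of each character is fully
described by its light variable. `character_vector_correlations()`
correlates the column principal coordinates of the light variables across
all non-trivial dimensions. Pearson correlation on *principal* (singular-
value-scaled) coordinates is the default: it weights dimensions by their
explained inertia, which matches the dominance of the global melanisation
axis; cosine similarity is available as an option, and the choice of all
dimensions versus a truncated space is configurable (the default is all).

`integration_summary()` counts positive correlations over the strict
upper triangle — a predominance of positive values is the signature of
integrated, body-wide melanisation — and lists the negative pairs.
`modularity_clusters()` cuts an average-linkage hierarchical clustering of
$1 - \mathrm{correlation}$ into a requested number of modules; average
linkage was chosen because it is the least sensitive of the standard
linkages to single aberrant character pairs, and the result is
deterministic given its input.

## Distance layers

* **DAS (shared-allele distance).** For each pair and each locus scored
  in both individuals, the shared-allele count is
  $\sum_a \min(c_{ia}, c_{ja}) \in \{0, 1, 2\}$; the locus similarity is
  half that, and DAS is one minus its mean over commonly scored loci
  (pairwise deletion). The per-locus-mean variant was chosen over pooled
  allele counts; it is the common reading of the shared-allele literature.
  A pair with no commonly scored locus is an error in strict mode and a
  flagged `NA` in permissive mode, and `locus_missingness()` supports
  wholesale locus filtering, which is left to the user.
* **Haplotype distances.** Pairwise counts of differing sites over
  positions where both sequences carry an unambiguous base; gaps and `N`
  are missing, compared sites are counted per pair, and `mode = "p"`
  divides by them. The implementation is a base-encoded matrix product
  (exact, no approximation) and is tested against `ape::dist.dna` as an
  independent reference.
* **Neighbor joining.** `ape::nj` provides the Saitou–Nei agglomeration;
  the package post-processes negative branch lengths by clamping to zero
  and transferring the excess to the longest adjacent branch, with a
  message. On additive matrices (where NJ is exact and branch lengths are
  non-negative) the tests require exact recovery of topology and branch
  lengths up to 12 taxa.
* **Geography.** Haversine great-circle distances on a sphere of mean
  radius 6371.0088 km. A spherical model errs below 0.5% of ellipsoidal
  geodesics, immaterial at the continental scale of between-population
  comparisons.
* **Climate.** Variables (eight BIOCLIM-style summaries in the reference
  design, any number in practice) are centred and scaled by their
  standard deviation before PCA. Centring is a deliberate addition: PCA
  convention requires it, and distances over all components then equal
  standardized Euclidean distances on the raw variables, which is the
  invariance the tests assert (per-variable affine rescaling changes
  nothing). Truncation to leading components is configurable; the default
  keeps all.

## Congruence testing

Principal coordinates require Euclidean-embeddable distances, which DAS,
haplotype and great-circle matrices generally are not. The Lingoes
correction adds the smallest constant $c = -\lambda_{\min}$ (the most
negative Gower eigenvalue) to all squared off-diagonal distances; the
corrected matrix provably passes the embeddability check
($\lambda \ge -10^{-8}\lambda_{\max}$, verified on random non-metric
inputs) and the map preserves the ordering of distances. `pcoa()` then
embeds the matrix, keeping all axes with positive eigenvalues — the
default for how many axes feed the RV comparison, configurable.

The RV coefficient is computed from centred cross-product matrices. Its
significance is assessed by an explicit Monte-Carlo permutation of row
order (default 9999 permutations, seeded, add-one p-value estimator
$p = (1 + \#\{RV^\ast \ge RV\})/(1 + B)$, so $p$ is never zero and is
exactly reproducible). An explicit permutation was preferred over the
moment-based normal-theory approximation used by some libraries because
it is exact in distribution, seedable, and testable: the suite verifies
the empirical type-I error at $\alpha = 0.05$ over 200 independent null
pairs stays within the 95% binomial interval.

Population-level comparisons aggregate individuals by averaging scores
(colour, climate), coordinates (geography: distances between mean
coordinates), or pairwise distances (DAS, haplotype: mean over all
between-population pairs, zero diagonal). The pairwise summary of all
layers is a neighbor-joining tree on $1 - RV^2$ — reusing the same tested
NJ code path as the genetics module — and the per-individual
haplotype-versus-colour structure is visualised as a profile-correlation
heatmap: cell $(i, j)$ correlates $i$'s distance profile in one matrix
with $j$'s in the other, both profiles excluding the pair's own two
entries (the exclusion rule is not standardized; excluding both is the
symmetric choice and is what the permutation oracle in the tests pins
down). The flanking dendrograms are complete-linkage clusterings of the
two raw distance matrices. This computation is $O(n^3)$; the pipeline
driver skips it above 150 individuals by default.

## The synthetic-study generator

`simulate_study()` exists so that every stage is testable end-to-end with
known ground truth. It emulates the statistical structure the analysis
assumes:

* **Sampling shape.** 18 populations in two deep lineages, 1–68 specimens
  each (448 in total), with regional centroids and 30 km of within-
  population geographic scatter — the shape of a realistic, strongly
  unbalanced museum sampling.
* **Mitochondria.** A random 658 bp root sequence mutated along a star
  topology: 16 fixed differences between the two lineage ancestors
  (emulating a split of more than 15 mutations), up to 5 population-
  private mutations, and an occasional specimen-private mutation, at
  disjoint site blocks. Consequently between-lineage distances always
  exceed within-lineage ones — an invariant the tests verify by direct
  enumeration. Star topologies were chosen over a coalescent because the
  pipeline only consumes pairwise distances; the simpler model keeps the
  oracle exact.
* **Microsatellites.** Per locus, a common allele-frequency vector is
  drawn once and each population's frequencies are Dirichlet-resampled
  around it with concentration $(1-f)/f$ for drift parameter $f$
  (default 0.15); genotypes are random unions of gametes. No linkage,
  migration or selection.
* **Colour.** Each population has a melanisation target $\mu \in [0,1]$;
  each character's modality probabilities follow a Gaussian kernel
  (width 0.2 by default) over the equally spaced light-to-dark positions,
  giving labile within-population variation around the population's
  morph. In the *congruent* scenario $\mu$ differs by lineage (dark
  mainland, light islands, with a small within-lineage gradient); in the
  *convergent* scenario one dark and one light profile are planted
  alternately in populations of *both* lineages.
* **Climate.** Eight named variables are linear gradients in latitude and
  longitude mixed with Gaussian noise so that each variable's correlation
  with its gradient equals the coupling parameter (default 0.8).

Every layer draws from its own seeded stream, so the congruent and
convergent members of a pair share bit-identical genetic, geographic and
climatic data — the colour scenario is the only difference, which is what
makes the paired comparison sharp. Regeneration under the same
configuration is bit-identical, and `write_study()` followed by
`read_study()` is a pure round trip through the public file formats.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: substitution-model structure (no
transition/transversion bias, no rate variation), recombination and
linkage, migration and admixture, scoring error in colour codings, and
any ecological dependence of colour on climate. The congruence machinery
is validated on the *structure* of the problem (does colour track the
genetic split or not), not on a process model of hornet evolution.

## Problem sizes and runtime choices

The test suite and the examples run at deliberately modest sizes: CA
oracles on 8–14-row random tables, NJ consistency on 6–12 taxa (50
replicates), RV calibration on 200 null pairs of 15 individuals with 999
permutations, and the paired congruent/convergent comparison on 20
replicate studies at the full 448-specimen sampling shape. These sizes
give stable pass/fail behaviour at interactive runtimes; all of them are
parameters of ordinary function arguments, not hidden constants, so
heavier runs only require larger values.

## Known limitations

* The CVA reports a single pooled accuracy; per-morph error rates are in
  the confusion table but no multiple-testing machinery is attached.
* The RV permutation test permutes rows of one layer, which assumes
  exchangeable units; aggregated population-level rows of very unequal
  sample sizes stretch that assumption.
* The profile-correlation heatmap is quadratic in memory and cubic in
  time; it is meant for the tens-to-low-hundreds of individuals for which
  it is interpretable.
* `dist_matrix` enforces symmetry, non-negativity and a zero diagonal but
  not the triangle inequality; none of the downstream methods require it.
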
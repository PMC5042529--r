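---
title: "Methods: trajectory-aware differential expression across brain development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-aware differential expression across brain development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devtraj)
```

devtraj analyzes bulk expression cohorts sampled across postnatal
development — the motivating design is prefrontal-cortex RPKM profiles
from autism cases and controls plus chimpanzee and macaque cohorts — and
asks three questions: which genes change their *developmental
trajectory* with disease status; how those changes organize into
co-expression patterns; and whether the affected patterns coincide with
expression features unique to the human lineage, and with candidate
upstream regulators. This vignette documents the models, the tunable
parameters, the synthetic-cohort generator that makes the pipeline
testable offline, and the numerical and design choices a maintainer
should know about.

## The age scale

All fitting happens on the fourth-root age scale,
$t = (\text{age in days} + 1)^{1/4}$ (`age_transform()`). The fourth
root expands infancy, where expression change is fastest, and compresses
adulthood; the one-day offset keeps the transform finite-sloped at birth
(newborns, age 0 d, are present in the design). The offset is a
parameter of `age_transform()` but there is no reason to move it.

## Trajectory fitting

Per gene, `fit_polynomial_family()` fits polynomials of degree 0–3 in
$t$ and keeps the member maximizing adjusted $R^2$,
$\bar R^2 = 1 - \frac{RSS/(n-p)}{TSS/(n-1)}$, breaking exact ties
(within $10^{-9}$) toward the lower degree — so a noiseless quadratic
selects degree 2 even though the cubic also fits exactly. Degrees 0–3
are the default family: cubic matches the flexibility of the 3-df
spline used for interpolation, and with ~60–75 samples higher degrees
mostly fit noise; the family is an argument everywhere it matters.

For interpolation and curve comparison, `fit_spline3df()` fits a natural
cubic regression spline with three degrees of freedom (interior knots at
age quantiles, boundary knots at the observed range).
`interpolate_curve()` evaluates a fit on `n_points = 15` equally spaced
points of the transformed-age range, endpoints included, and refuses to
extrapolate: every cross-species or cross-platform comparison is
restricted to the shared observed range. `curve_correlation()` is the
plain Pearson correlation of two same-length curves; a constant curve
has no defined correlation and returns `NA` with a warning rather than a
silent zero.

## The trajectory ANCOVA

`ancova_group_test()` / `devex_test()` test whether two groups (cases
vs. controls; or two species) follow different trajectories. The
polynomial degree $d$ is selected on the *pooled* data — pooled
selection keeps the degrees of freedom honest and makes the selection
invariant under group-label permutations, which the permutation FDR
exploits. The null model shares all $d+1$ coefficients between groups;
the alternative gives each group its own intercept and age terms. With
$RSS_0$ and $RSS_1$ the residual sums of squares,

$$F = \frac{(RSS_0 - RSS_1)/(d+1)}{RSS_1/(n - 2(d+1))},$$

and $p$ comes from the $F_{d+1,\,n-2(d+1)}$ distribution. If the
alternative fits exactly ($RSS_1 = 0$, e.g. a noiseless constant
offset), $p$ is reported as 0 with a `degenerate` flag. The response is
raw RPKM by default, mirroring the headline analysis this package
reimplements; `response = "log2"` tests $\log_2(\text{RPKM}+1)$
instead. On log-normal expression noise the raw-scale F-test is mildly
anticonservative (we measure ~6–7% rejections at the nominal 5% on null
cohorts) while the log2 scale is calibrated; calibration experiments in
the tests and the acceptance script therefore run on the log2 scale,
and the permutation FDR — whose permuted counts inherit the same
miscalibration as the observed ones — is the primary error control on
either scale.

## Age-stratified permutation FDR

`permutation_fdr()` estimates the false-discovery rate of the gene set
passing `p < threshold` (default 0.01) by permuting disease labels
**within age strata** — `make_age_strata()` builds `k = 8`
equal-count (quantile) intervals of transformed age, merging an
interval with its neighbour when one group is absent — so the age
structure of the cohort is preserved under the null. The estimate is

$$\widehat{FDR} = \frac{\text{mean}_b\,\#\{p^{(b)} < \theta\}}{\#\{p < \theta\}},$$

e.g. 100 observed significant genes against a mean of 7.8 permuted ones
gives 0.078 (`fdr_estimate()`). Zero observed discoveries yield `NA`,
never 0. Quantile strata (not equal-width) are used because the cohort
is heavily skewed toward infancy; equal-width strata would leave late
intervals with one or two samples and no permutations to do. Because
pooled degree selection and the null-model fit are label-invariant,
permutations only refit the group-specific model, which keeps
$B = 1000$ permutations on a 12k-gene cohort inexpensive.

Two properties of this estimator are worth knowing. On fully null
cohorts it is approximately unbiased (estimates near 1 when nothing is
going on). In the presence of *strong* true effects it is conservative:
a within-stratum label permutation retains a residual correlation with
the true labels (standard deviation ≈ 0.125 with 8 strata of ~9
samples), and a 3-sd effect diluted by that correlation is still
detectable at $n = 74$, so roughly 12% of strong effect genes leak into
the permuted counts. In our planted-truth experiments the estimate
exceeds the realized false-discovery proportion by a factor of ~2.5–3.
The estimator is exactly the one the reimplemented study prescribes, so
we document the bias rather than re-derive a different estimator; read
reported FDRs as upper bounds when effects are large.

## Cohort summaries

`variance_components()` partitions expression variation among age (the
pooled-selected polynomial), diagnosis, sex, RNA quality and batch by
sequential sums of squares in that order, aggregated over genes as
$\sum_g SS_{\text{factor}} / \sum_g SS_{\text{total}}$. Sequential
attribution is order-dependent; the order is part of the output and the
report labels it. `mds_embedding()` embeds samples by classical MDS on
$1-r$ correlation distance with a deterministic sign convention (the
largest-magnitude coordinate of each axis is positive).
`severity_divergence()` measures, per case, $1-r$ between the sample's
standardized expression vector and the control 3-df spline predictions
at the sample's age, and correlates that distance with clinical
severity (ADI-R) scores; the distance definition is this package's
formalization of "distance from the control trajectory", which the
source material does not define formulaically.

## Co-expression clustering and the tree-cut sweep

Significant genes are standardized per gene over the combined case +
control samples (`standardize_rows()`; constant genes are flagged and
excluded, never coerced to zero correlation), distanced by $1-r$
(`correlation_distance()`), and clustered by complete linkage
(`hierarchical_complete()`, backed by `stats::hclust`). Flat clusters
come from cutting the tree at a height (`cut_and_filter()`); clusters
with fewer than `min_size = 40` genes are discarded.

When no height is given, `select_height_by_enrichment()` sweeps heights
2.0 down to 0.3 in steps of 0.1 (the grid contains both endpoints and
the 1.4 working value of the motivating study) and, per height, tests
every retained cluster against every annotation term (one-sided
hypergeometric against the expressed-gene universe, BH-adjusted within
the height) and counts the **distinct** terms significant at adjusted
p < 0.05. The height with the most terms wins; ties go to the larger
(coarser) height. Counting distinct terms rather than (cluster, term)
pairs matters: pair counting would reward splitting one coherent
cluster in two, since the same term then counts twice, and the sweep
would always run to the finest heights. The BH scope (within height,
across all cluster–term pairs) is a documented choice; the source
material does not state its multiplicity scope.

## Lineage-specific expression

`pairwise_species_test()` compares two species' trajectories: each
species' transformed ages are min–max rescaled onto the reference
species' range — aligning developmental spans of species with unequal
lifespans — and the trajectory ANCOVA runs with species as the group.
The "reference" semantics of the original two-run procedure are not
published in detail; reference-anchored min–max scaling is this
package's reconstruction, chosen because it reproduces the stated
two-run structure and is symmetric when ranges coincide. Each pair is
tested twice (either species as reference) and a gene is differentially
expressed if either run passes (`pairwise_species_call()`).
`classify_lineage()` then applies the boolean rule: human-specific
⟺ different from chimpanzee *and* macaque but chimpanzee ≍ macaque;
chimpanzee-specific by the mirrored rule. `species_permutation_fdr()`
permutes species labels within `k = 6` age intervals (six for the
species design, eight for the disease design, both arguments) and
reruns the whole pipeline. `platform_consensus()` keeps genes called on
either of two platforms whose concatenated 15-point interpolated curves
(all species) correlate above $r = 0.5$ across platforms.

## Gene-set overlap machinery

`hypergeom_enrichment()` gives the one-sided $P(X \ge \text{overlap})$;
`fisher_overlap()` builds the 2×2 table over a universe (infinite odds
ratios are capped and flagged, not silently corrected);
`bh_adjust()` validates and applies Benjamini–Hochberg.
`overlap_permutation_test()` supports three nulls: `uniform` (random
same-size sets from the universe), `cluster_label` (permute the full
cluster-assignment vector, preserving every cluster size
simultaneously), and `length_matched` (random sets drawn within decile
bins of the tested cluster's gene-length distribution, which removes
enrichment driven purely by gene length). Empirical p-values use the
plus-one convention $(1+k)/(1+B)$ and are never zero.
`mutation_index_test()` compares the mean mutation index of tested
genes with equally sized random draws from the *remaining* genes —
excluding the tested genes, so a gene carrying the genome-wide maximum
attains exactly $1/(B+1)$. `paired_difference_cluster_test()` takes
per-gene expression- and chromatin-mark-difference vectors over
age-matched case-control pairs (built by `match_pairs()`, greedy
minimal transformed-age matching, and `difference_vectors()`), computes
per-gene Pearson correlations between the two, and compares a cluster's
correlations with the background's by a one-sided Wilcoxon rank-sum
test (cluster greater — the scientific question is an excess of
*positive* coupling).

## TF regulator screen

`conservation_filter()` keeps predicted binding sites with ≥ 80% of
bases carrying a defined conservation score and a mean (over defined
bases) ≥ 0.6, then rebuilds the TF→target map. `tfbs_enrichment()`
tests each TF's surviving targets for over-representation in a cluster
against the union of the other clusters (one-sided hypergeometric);
`tfbs_enrichment_empirical()` compares the number of nominally enriched
TFs with the counts over random same-size gene sets drawn from all
differentially expressed genes. `tf_target_correlation_test()` computes
Pearson correlations of TF expression with in-cluster and out-of-cluster
targets *within each disease group's samples separately* and compares
the two distributions by a one-sided MWU (in-cluster greater; the
direction follows the screened hypothesis of positive regulation, and a
two-sided switch exists). `regulator_screen()` flags a TF when it is
enriched and BH-adjusted-significant in both groups.
`chipseq_promoter_targets()` validates predictions against ChIP-seq
peaks: a gene is a target when some peak midpoint lies within ±2 kb of
its TSS (midpoint containment is the least ambiguous reading of "peaks
within the promoter region" and an any-overlap variant would only be
more permissive).

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage above can be tested with
recorded ground truth and no downloads. Its defaults are the study
conditions the pipeline targets: 40 controls (0–62 y), 34 cases
(2–60 y), 39 chimpanzees (0–43 y), 36 macaques (0–21 y); ~2,000
expressed genes; ages drawn log-uniformly in days so the fourth-root
design is well covered near birth; Gaussian noise with sd 0.5 on
$\log_2(\text{RPKM}+1)$, back-transformed (RPKM are heteroskedastic;
the log scale is where the robustness analyses live); small sex, batch
and RNA-quality confounder loadings.

Six archetypes structure the disease signal: five affected patterns —
rising/up-shifted, **delayed-peak control with early decline in autism**
(the synaptic pattern), falling/down-shifted, U-shaped/late-rise,
S-shaped/amplitude-gain — plus a null class (75% by default) with
gene-specific random cubic trajectories and no deviation. Archetype
curves are loadings on a basis of cubic age polynomials and their
disease (case-only) contrasts, **orthonormalized empirically over the
realized human samples**, with loadings centered across archetypes so
every between-archetype full-profile correlation is ≤ 0 under the
realized age distribution. This construction is deliberate: under the
infancy-heavy age distribution, analytically orthogonal curves (e.g.
Legendre shapes) are far from orthogonal empirically, between-archetype
correlations drift positive, and complete-linkage clusters merge
unpredictably — separability must be a controlled function of effect
size and noise, not an accident of the age sampling. The
autism-minus-control deviation curve is calibrated so its rms over the
case samples equals `disease_effect × noise_sd` exactly (nominal "3 sd"
means 3 sd), optionally scaled per case by a severity factor that is
also recorded as an ADI-R-like score. An `independent_effects` switch
replaces the shared archetype deviations with per-gene random deviation
directions, for calibration experiments where between-gene dependence
is unwanted.

Lineage structure: 9% of genes are human-specific and 3%
chimpanzee-specific (the ~3:1 ratio of the motivating results), with
half of the human-specific genes drawn from the synaptic archetype
(planting the cluster/lineage overlap the pipeline should find). The
shift itself is a constant expression offset in the shifted species
plus a small delayed-peak time shift of the shared curve — both
invisible to within-human clustering (a constant over human samples
drops out of correlations) yet detectable by the species ANCOVA, and
the normalized developmental position is defined on each species'
realized age span, so *unshifted* genes align exactly under the
min–max rescaling the species test applies. Planted annotation terms
contain 70% of their archetype's genes plus background (null-class)
genes, ~0.35 × `n_genes` per term: at that dilution a term sits at its
chance overlap in a two-archetype merged cluster but is strongly
enriched in its own pure cluster, which is what makes the height sweep
informative. A disease gene set is enriched in the synaptic archetype
threefold. TF structure: 21 TF genes, the first of which tracks the
synaptic archetype's full (control + deviation) signal at a planted
correlation of 0.7 and receives predicted targets concentrated in that
archetype (60%) with spill-over into the other affected archetypes; the
20 decoys get random trajectories and random targets. ~10% of predicted
binding sites fail the conservation rule, exercising the filter.
Companion generators `simulate_h3k4me3_differences()` (paired
difference vectors with per-archetype coupling) and
`simulate_mutation_index()` (log-normal indices, elevated genes' mean
shifted by a fold) cover the epigenome and mutation stages.

What the generator does *not* emulate: count-level sampling noise,
gene–gene correlation beyond the archetype structure, batch × age
interactions, platform-specific measurement models, or the real
cohort's exact covariance. Passing tests therefore demonstrate that the
algorithms do what they claim under a controlled model of the data, not
that the biological conclusions of any particular cohort are correct.

## Problem sizes and expected results

The test suite and `scripts/acceptance.R` use desk-scale experiments:
null calibration on 2,000 genes × 74 samples; FDR calibration with 10%
planted 3-sd effects at B = 200 stratified permutations;
cluster recovery on ~540 planted genes across six archetypes (including
a 39-gene group that the min-size filter must discard); a regulator
screen with one planted regulator among 20 decoys over seeded
replicates; oracle equivalence against exhaustive enumeration
(hypergeometric for universes ≤ 12, rank permutations for 4-vs-4 MWU,
an $O(n^3)$ complete-linkage reimplementation for n ≤ 8). Typical
outcomes at these sizes: type-I error within ±1.5% of nominal (log2
scale), planted-partition ARI = 1, regulator recovery in ≥ 9/10
replicates with zero decoy flags, null-cohort FDR estimates near 1, and
the conservative factor of ~2.5–3 between the permutation FDR and the
realized FDP under strong effects discussed above.

## Known limitations

- The permutation FDR is conservative under strong effects (documented
  above); it is the prescribed estimator, not an optimal one.
- The raw-RPKM ANCOVA is anticonservative under multiplicative noise;
  use `response = "log2"` when per-gene p-values matter outside the
  permutation framework.
- Sequential variance attribution is order-dependent by construction.
- The reference-anchored min–max age scaling assumes the sampled age
  ranges span comparable developmental stages; cohorts truncated at
  very different stages would need a biologically informed alignment.
- `platform_consensus()` treats curve correlation > 0.5 as support, not
  as a formal test; no uncertainty is attached to interpolated curves
  beyond the residual sd of their spline fits.
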
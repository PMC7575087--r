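---
title: "Methods: calling Ss4R ohnologue pairs and measuring their regulatory divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling Ss4R ohnologue pairs and measuring their regulatory divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnodiverge)
```

# The problem

Salmonids carry the residue of a lineage-specific whole-genome duplication
(Ss4R, roughly 100 million years ago) on top of the earlier vertebrate and
teleost rounds. Many circadian clock genes are therefore present as
*ohnologue pairs* — duplicates born in the genome doubling rather than by
tandem duplication. Whether the two members of such a pair remain
interchangeable or have diverged in their regulation is an empirical
question with three observable faces: where the copies are expressed
(tissue specificity), when they are expressed (diel/circadian rhythmicity
and developmental trajectories), and how they respond to environmental
challenges such as the freshwater-to-seawater transition. `ohnodiverge`
implements that analysis end to end: pair identification from gene-tree
topology plus duplicated-block synteny, rediploidization dating from
residual sequence similarity, and a battery of divergence statistics — all
exercised against a seeded synthetic-data generator with recorded ground
truth, so that every stage is testable without any external download.

# Ohnologue pair calling

A pair is accepted only when all four conditions hold on its orthogroup's
rooted gene tree and the focal-species genome:

1. the two focal-species genes sit in a **monophyletic clade containing
   only salmonid genes**;
2. that clade's **sister lineage is Northern pike** (*Esox lucius*), the
   closest relative that diverged before the Ss4R;
3. the duplication is **conserved in at least one other salmonid**: by
   default a second salmonid species must contribute one gene to each of
   the clade's two duplicate sub-clades (a *mirrored* pair). A relaxed
   mode (`conservation_mode = "any2"`) accepts any two genes of that
   species anywhere in the clade;
4. the two genes fall in the two intervals of one **Ss4R collinear
   block** (synteny support).

Two readings of criterion 2 are exposed: `sister_mode = "exact"` (default)
requires the sister subtree's species set to be exactly `{pike}`; a
`"contains"` mode tolerates additional lineages in the sister, which can be
appropriate when taxon sampling is patchy. Unrooted trees are rejected
rather than silently midpoint-rooted, because the sister criterion is
meaningless without an explicit root. Clades holding more than two
focal-species genes (tandem duplication inside the Ss4R clade) are reported
as *ambiguous* rather than resolved by guesswork, and every focal gene not
in a called pair appears in the singleton table together with the first
criterion it failed.

Pair records are canonical: `gene1` is the copy whose locus sorts first
under numeric-aware chromosome ordering, then start coordinate, so calling
with the genes swapped yields byte-identical output. All coordinates are
1-based inclusive and strand is ignored.

**Rediploidization class.** Residual percent identity in 1-Mbp windows
along the supporting block dates the regional return to disomic
inheritance: the mean window identity `m` maps to *late* (`m > 95`), *mid*
(`90 <= m <= 95`) or *early* (`m < 90`). Published figures give colour bands
rather than hard thresholds, so the boundaries (90, 95) are configurable;
the mid class is closed on both ends.

# Expression containers and normalization

Counts travel as an `expression_bundle`: a genes-by-samples integer matrix
plus one metadata row per sample (`tissue`, `condition`, `time`,
`replicate`). Normalization is the standard count pipeline: counts per
million over the effective library size (column sum times a TMM scaling
factor), low-expression filtering at **>= 1 cpm in >= 5 libraries**, and
TMM factors computed by `edgeR::calcNormFactors()` with the method's
published trim fractions (30% of M-values, 5% of A-values) — the factors'
geometric mean is 1. When a log scale is requested, a half-count offset is
added before division and recorded in the matrix's provenance attribute.
The multi-tissue atlas stage is normalized the same way (TMM-cpm); this is
a package choice, recorded here, as tissue-atlas normalization admits
several defensible conventions.

# The rhythm screen

Rhythmicity per gene, tissue and condition is tested nonparametrically: the
statistic is the **maximum over candidate peak phases of the Kendall tau-b
correlation** between the observed series and a cosine reference waveform
`cos(2*pi*(t - phase)/24)` evaluated at the sample times and reduced to
ranks. The phase grid equals the 4-h sampling resolution (6 candidate
phases per 24-h period); the period is fixed at 24 h (no period scanning by
default). Because the statistic is a maximum over templates, its null
distribution is computed for the *maximum*, by permutation, so the
phase-grid search does not inflate the type-I error.

**Exchangeability choice.** Two permutation backends exist.
`exchange = "observations"` (default) permutes all observations: in the
emulated designs every replicate is a separate animal sampled destructively
once, so observations are independent under the null and this is the valid,
non-conservative choice — it also matches how rank-based rhythm tests treat
replicates, as tied observations at their timepoint.
`exchange = "blocks"` permutes whole replicate blocks across timepoints, a
deliberately conservative variant appropriate for repeated measures of the
same subjects; with few timepoints all `T!` block permutations are
enumerated, enabling an exact null (`null = "exact"`). We initially made the
block scheme the default and found its effective sample size (the number of
timepoints, not of observations) too small to reach useful power at
realistic amplitudes, while observation permutation is calibrated (null
rejection near 0.05) and powerful; the measured numbers are in
`scripts/acceptance.R` output and `tests/testthat/test-acceptance.R`.

Sampled permutation p-values are `(1 + #exceedances)/(n_perm + 1)`, with
permutations drawn independently per block of 50 genes so genome-wide error
rates do not inherit shared permutation noise. Zero-variance series are
flagged (`tau = NA`, `p = 1`). Benjamini-Hochberg adjustment is applied
within each tissue-by-condition stratum. The statistical windows follow the
emulated sampling scheme: diel analyses use ZT5 through the following ZT5
(both endpoints kept, hence a deliberately duplicated clock time), constant
conditions CT9 through CT29.

**Phase, amplitude, mesor.** The reported phase is not the tau-grid argmax
but the continuous least-squares cosinor phase (the `atan2` of the sin/cos
regression coefficients), with amplitude and mesor from the same fit. The
grid argmax is quantised to 4 h and under noise lands in a neighbouring
cell often enough to spoil phase accuracy; the cosinor estimator is
strictly better and exact on noise-free cosines. The per-phase tau values
remain available via `tidy()` on a `rhythm_test()` fit.

# Divergence statistics

**EDI.** The expression divergence index of a pair in a tissue is
`|log2(expr1/expr2)|` on mean TMM-cpm. When either value is exactly zero a
0.5-cpm offset is added to *both* members (only then), keeping the index
finite, symmetric, and zero exactly when the two inputs are equal. Pair
summaries are medians across the tissue panel.

**Profile divergence.** Two copies' temporal profiles are compared by an
extra-sum-of-squares F test on **sixth-order centred polynomials**: each
series is first divided by its own mean (ratio-scale normalization "to the
group mean"), then fitted separately and jointly;
`F = ((RSS_shared - RSS_separate)/(p)) / (RSS_separate/df_separate)` with
`p = order + 1` shared coefficients. The polynomial is linear in its
coefficients, so ordinary least squares is exact; the centred time axis is
additionally scaled to `[-1, 1]` for conditioning (the F statistic is
invariant to that rescaling). The design must offer at least `order + 1`
distinct timepoints and more than `2*(order+1)` observations; numerically
identical fits (e.g. literally identical series) return `F = 0`, `p = 1`
through an explicit tolerance guard rather than a 0/0 ratio.

**Seawater interaction.** For each pair, a two-way ANOVA of
`log2(cpm + 0.5)` on gene-copy, condition (FW/SW) and their interaction;
the interaction p-value is the divergence evidence. The response scale is a
package choice (the source analyses do not name one). Published reports of
this analysis use both 0.05 and 0.01 as the significance level; the default
is `alpha_interaction = 0.05` and the report carries flags at both levels
rather than resolving the discrepancy.

**Clustering.** Significant developmental genes are clustered on
standardized per-stage mean profiles with distance `1 - Pearson r`, average
linkage, tree cut at `k = 5`. Five clusters mirrors the number of distinct
developmental patterns the motivating analysis observed; it is a default,
not an inference — no automatic `k` selection is attempted. Genes are
processed in id order and `stats::cutree()` numbering makes the assignment
deterministic; zero-variance profiles are excluded with a warning.

**The per-pair report.** Each assay context (developmental time course,
seawater challenge, rhythm screen) is classified per pair: *one-copy-
regulated* when exactly one copy is significant; *different-dynamics* when
both are significant but their dynamics differ (different clusters,
divergent profiles, or a significant copy-by-condition interaction); *none*
otherwise. The overall mode is the combination, with *both* reserved for
pairs showing the two kinds of divergence in different assays. Profile and
interaction p-values are BH-adjusted across pairs inside the report, so a
fixed per-pair threshold does not accumulate false flags as the pair list
grows.

# Count-based differential expression

The two screens named in the motivating analysis are implemented over a
common negative-binomial core with a **single common dispersion** (no
tagwise shrinkage — the focal gene sets are small, and this is recorded as
a limitation):

* `estimate_common_dispersion()` maximises the sum-constrained
  (conditional) NB likelihood over a log-spaced dispersion grid refined by
  golden-section search. Counts are first equalized to the geometric-mean
  effective depth by simple rescaling — an analytic stand-in for
  quantile-based pseudo-counts that is testable against enumeration and
  behaviourally equivalent at these depths. The conditional likelihood
  includes its dispersion-free combinatorial terms so the Poisson limit
  (`phi = 0`, a multinomial conditional likelihood) is comparable and is
  returned when it dominates.
* `nb_exact_test()` (FW vs SW) conditions each gene on the total of the
  equalized counts: the two group sums are NB with sizes proportional to
  group size, and the two-sided p sums all conditional splits no more
  probable than the observed one. Dispersions at or below `1e-8` use the
  exact Poisson-limit conditional (a binomial split) — both because it is
  the correct limit and because `dnbinom` with the astronomically large
  size parameter implied by such dispersions cannot resolve tied outcomes.
  Group sums are rounded to integers after equalization.
* `timecourse_test()` (T1-T6) fits per gene an NB log-linear model with a
  stage factor against an intercept-only model (log effective-library
  offsets, fixed common dispersion) and refers the likelihood-ratio
  statistic to chi-square with `n_stages - 1` degrees of freedom.
* FDR control is Benjamini-Hochberg within each contrast, mirroring
  per-experiment reporting.

# The synthetic-data generator

`sim_config()` fixes the study conditions; the generator is the package's
test bed, not a tuning dial. It emulates, with recorded ground truth:

* **Gene trees** — one rooted tree per orthogroup over three salmonids
  (focal Atlantic salmon, plus rainbow trout and Arctic charr as
  mirroring species), Northern pike, and outgroups. With probability
  `1 - p_loss_post_wgd` (default retention 0.8) the focal species keeps
  both copies in a correctly structured clade; losses leave one focal gene
  and are labelled with a randomly chosen topology violation. Extra
  per-criterion negative controls (two focal copies violating exactly one
  criterion, including a synteny decoy) exercise caller precision.
* **Synteny** — duplicated chromosome pairs carved into blocks of up to
  five 1-Mbp gene slots; window identities are drawn inside the assigned
  class band (late 95.5-99, mid 90.2-94.8, early 85.5-89, centred near the
  canonical ~87%).
* **Expression** — negative-binomial counts (`nb_dispersion` default 0.05,
  a typical bulk RNA-seq value) around log-uniform library sizes within
  2-fold of one million reads, exercising normalization. Baseline log2 cpm
  is `N(5, 1.5)` per gene, copies of a pair correlated. Per design:
  4-h circadian sampling with `n = 3` over diel ZT5-ZT29 / LL CT9-CT29 /
  DD CT1-CT29 in optic tectum, saccus vasculosus and gill; six
  developmental stages with `n = 6`; FW/SW groups with `n = 6`; an
  11-tissue atlas. Planted cosine amplitudes are log-normal with median 2
  log2 units; constant-condition amplitudes are multiplied by a per-tissue
  damping factor whose default (OT 0.8, SV 0, gill 0) reproduces the
  qualitative biology of a light-coupled brain oscillator and arrhythmic
  peripheral tissues. Developmental effects follow five fixed archetype
  curves with a 2-log2-unit swing; seawater induction is `N(2, 0.5)` log2
  units on a planted subset, with divergent pairs planted either as
  one-copy-responsive or as both-responsive with opposite-sign effects.
* **Background genes** (`n_background`, default 500) carry baseline
  expression only. They emulate the transcriptome context in which
  normalization and FDR control actually operate: in a real experiment the
  clock genes are a tiny minority of ~34k genes, so inducing a third of
  them cannot bias the scaling factors. Without background, planted
  induction of a large fraction of a small focal set visibly distorts
  TMM factors and produces spurious down-regulation — a real compositional
  effect, not an artifact, but not the regime the analysis targets.

Reproducibility: each artifact (trees, synteny, expression) draws from its
own stream derived from the master seed by fixed offsets, so adding one
stage never changes another's output, and identical configs give
byte-identical files end to end.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: no sequences are simulated (no alignment or
tree-estimation error, no orthogroup mis-assignment), gene trees are
clean realizations of the criteria rather than noisy ML estimates with
bootstrap uncertainty, expression noise is exactly NB with a single
dispersion (no outlier samples, batch effects, or mean-dispersion trend),
rhythms are perfect cosines, and developmental profiles come from five
shapes rather than a continuum. Performance numbers on this substrate are
upper bounds for real data.

# Problem sizes used in the checks

The bundled acceptance checks run at sizes chosen to make the Monte-Carlo
bands informative while staying desk-scale: 200 orthogroups (plus 10
negative controls) for the caller; 500 pairs by 11 tissues for EDI
exactness; 1000 null genes and a 500-gene power fixture (200 rhythmic,
amplitude 2, noise sd 0.5, 7 timepoints by 3 replicates, `n_perm = 1000`)
for the rhythm screen; 1000 simulated null pairs for the profile test's
size; 2000 genes for dispersion recovery; a ~1600-gene smolt fixture for
DE sensitivity; 200 profiles in 5 archetypes for clustering; and the
bundled 30-orthogroup pipeline config, run twice, for byte-level
determinism.

# Known limitations

* Criterion 2 assumes the pike orthologue was retained; lineage-specific
  pike loss makes a true pair uncallable (the strict mode errs toward
  precision, as intended).
* Common-dispersion NB tests understate gene-specific overdispersion;
  with large gene sets a tagwise/shrinkage approach would be preferable.
* The exact test's depth equalization is a first-order correction; at
  extreme library-size ratios the conditional NB model for rescaled sums
  is approximate (calibration at 2-fold spread is verified in the tests).
* The rhythm screen fixes the period at 24 h; genuinely non-24-h signals
  reduce to whatever power their 24-h projection retains.
* EDI on mean expression ignores within-tissue variance; it is a
  descriptive index, not a test.
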
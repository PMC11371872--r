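---
title: "Quantitative neuropathology and MTL morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative neuropathology and MTL morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlquant)
```

## The problem

Postmortem studies of neurodegeneration ask how the burden of specific
proteinopathies — here phosphorylated tau (p-tau) in Alzheimer's disease
neuropathologic change and phosphorylated TDP-43 in LATE-NC — relates to
antemortem atrophy of the medial temporal lobe (MTL). Two measurement
traditions exist: semi-quantitative ordinal ratings assigned by
neuropathologists (absent 0, rare 0.5, mild 1, moderate 2, severe 3), and
quantitative burden scores computed from classifier attention heatmaps on
digitised histology slides. `mtlquant` implements the analysis chain that
connects the two to regional MRI morphometry:

1. **Heatmap quantification** — summarise a per-pixel activation map over a
   sampling box into a scalar burden measure via contiguous, approximately
   equal-area segments and a quantile statistic.
2. **Pathology summaries** — pool box-level values into anatomical-ROI
   measures and a rule-based hippocampal summary, recalibrated to the 0–3
   rating scale.
3. **Rating validation** — one-sided Mann–Whitney AUC between adjacent
   rating categories and staging levels; Spearman correlations; a
   summary-statistic selection experiment.
4. **Association models** — standardized OLS of regional volume/thickness on
   pathology burden with nuisance covariates, one-sided inference, and
   AICc/BIC comparison of quantitative versus semi-quantitative predictors.
5. **Surface inference** — pointwise GLM on a template surface with
   cluster-level familywise correction by Freedman–Lane permutation of
   maximum cluster surface area.

A synthetic-data module generates all inputs with known ground truth, so
every stage is testable without access to slides or scans.

## Segment-based heatmap quantification

A sampling box is partitioned into `k = max(1, round(area / target))`
edge-connected segments with `partition_roi()`; the default target is
200 × 200 µm². The rationale for segments is spatial averaging at the scale
of an inclusion neighbourhood: per-pixel activations are noisy, whole-box
averages drown focal pathology, and quantiles over segment means capture
"how bad are the worst neighbourhoods" with a controllable tail.

The partitioner treats the invariants — pairwise disjoint, union equals the
mask, each segment edge-connected, sizes within ±20% of target — as the
contract, not any particular heuristic. It works on the 4-neighbour pixel
graph: within each connected component it peels balanced BFS prefixes grown
from a geodesically peripheral pixel (a BFS prefix from one source is always
connected), absorbs small frontier fragments into adjacent units, and
finishes with a Kernighan–Lin-style boundary refinement that moves single
pixels between adjacent segments when the donor stays connected. The
algorithm is deterministic; masks smaller than one target yield a single
segment, and disconnected masks are partitioned per component.

Quantiles use linear interpolation between closest order statistics
(position `p(n-1)`), the default convention of mainstream numeric stacks.
An empty segment-value vector yields a missing value, never zero. The eight
candidate statistics are mean, median, maximum and the 25th, 75th, 90th,
95th and 99th percentiles; the 99th percentile is the package default
because it is the statistic that most consistently separates adjacent
expert rating categories in the selection experiment
(`statistic_selection()` ranks candidates by mean adjacent-pair AUC, with
minimum AUC as tiebreaker).

## Hippocampal summary rules

`hippocampal_summary()` averages ROI-level burden over seven subfields
(CA1, CA2, CA3, CA1/subiculum, subiculum/presubiculum, dentate hilus,
dentate granular cell layer). Two rules matter:

* For the **threads** class the dentate hilus is excluded before averaging,
  because mossy fibres there are systematically misread as threads.
* The summary is missing unless at least **three** regions are available,
  with the two dentate subregions jointly counting as one region (their
  values still both enter the average). The count is taken *after* the
  hilus exclusion for threads; the alternative ordering is not stated
  anywhere authoritative, so the choice is explicit and local to one
  function.

`rescale_summary()` regresses the semi-quantitative MTL rating on the raw
quantitative summary by OLS and maps raw values through the fitted line,
putting summaries roughly on the 0–3 scale. The direction (rating on raw,
not the reverse) is chosen because the goal is to express the raw measure
in rating units. A positive-slope affine map cannot change rank order,
correlations, or standardized regression coefficients, which the tests
verify to 1e-10; a negative slope is warned about but still applied. The
fit is per pathology (p-tau and pTDP-43 separately), matching the pairing
of each quantitative summary with its own rating scale.

`late_stage()` implements hierarchical LATE-NC staging from regional
pTDP-43 ratings (amygdala → stage 1; dentate/CA1-subiculum/ERC → stage 2;
middle frontal gyrus → stage 3; positivity is a rating ≥ 1). Cases whose
positivity pattern skips a stage are staged by the hierarchical rule and
flagged `noncontiguous` rather than guessed at; a missing amygdala rating
makes the stage indeterminate.

## Rating validation statistics

`adjacent_auc()` computes `AUC = (wins + 0.5 × ties) / (n1 n2)` from
exhaustive pair counting (via midranks) and a one-sided p-value for "upper
group stochastically greater". The p-value is exact — full enumeration of
group-label assignments — when `n1 × n2 ≤ 100`, where enumeration is cheap
even in the balanced worst case, and otherwise uses the normal
approximation with tie correction (no continuity correction). Stage
comparisons always test "higher stage greater"; the AUC itself is reported
regardless of direction, so a reversed effect shows as AUC < 0.5 with a
large p.

## Association models

`fit_region_model()` fits OLS per region with the outcome (AH/PH volume in
mm³, ERC/BA35/BA36/PHC median thickness in mm) and all continuous
predictors z-scored, so pathology coefficients are standardized betas.
Binary covariates (sex, field strength) enter as 0/1 and are not
interpreted as standardized contrasts — a convention that keeps the
pathology betas well-defined without inventing a "standardized" effect for
a two-level factor. Intracranial volume joins the covariates only for the
volume outcomes, since head size predicts hippocampal volume but not
cortical thickness. Missing data are handled by listwise deletion per
model, with `n` and residual df reported per fit. One-sided p-values test
the negative direction by default (pathology is expected to reduce volume
and thickness); positive and two-sided alternatives are available by flag.

Information criteria use the Gaussian RSS form with constants omitted:
`AIC = n log(RSS/n) + 2k`, `AICc = AIC + 2k(k+1)/(n−k−1)`,
`BIC = n log(RSS/n) + k log(n)`, with `k` the coefficient count (including
intercept) plus one for the error variance. Dropping the shared constants
is legitimate because only differences between models fitted to identical
data are interpreted; the tests confirm the deltas equal `stats::AIC`/`BIC`
deltas. AICc is flagged undefined when `n ≤ k + 1`. `compare_models()`
reports quantitative-minus-semi-quantitative differences in adjusted R²,
L1 prediction error (sum of absolute residuals), AICc and BIC; negative
ΔBIC favours the quantitative model, and |ΔBIC| > 2 / 6 / 10 grades the
evidence as positive / strong / very strong.

## Surface cluster inference

`fit_pointwise()` fits the shared design at every vertex (vectorised normal
equations; a per-vertex `lm` loop is the test oracle) and returns the
contrast t-map. Vertices with zero residual variance get `t = 0` with a
flag. `extract_clusters()` thresholds the signed map (default `t > 2.0` on
`−t` for negative contrasts, matching the convention that atrophy effects
are negative associations) and takes connected components over the mesh
edge graph.

Cluster surface area uses fractional triangle attribution: each
suprathreshold vertex contributes a third of every incident triangle's
area. This makes total suprathreshold area equal the sum of cluster areas
exactly and varies continuously with the t-map; the all-or-nothing rule
(count a triangle only when all three vertices are suprathreshold) is
available by flag since the convention is not standardised across tools.

`freedman_lane_null()` builds the null of maximum cluster area by the
two-step Freedman–Lane procedure: fit the nuisance-only model, permute its
residual rows at the subject level (one shared permutation per iteration,
never per-vertex), reconstruct pseudo-data as nuisance fit plus permuted
residuals, refit the full model, and record the maximum suprathreshold
cluster area (zero when nothing survives). With an intercept-only nuisance
design this reduces exactly to permuting response rows, which the tests
verify to numerical identity on the same seed stream. Row permutation
(rather than sign flipping) is used because exchangeability of
nuisance-model residuals is the assumption Freedman–Lane is built on and it
requires no symmetry assumption on the errors.

`corrected_p()` reports, for each observed cluster, the share of
permutations whose maximum cluster area exceeds the cluster's area; a
cluster larger than every null maximum gets p = 0. On meshes with
continuous-valued areas (real cortical templates) ties never occur and the
definition is unambiguous. On a regular grid template, cluster areas
concentrate on a few discrete values — an interior singleton always has
area exactly one spacing unit — and the handling of null maxima *equal* to
the observed area then decides the test's calibration. Null diagnostics on
the default template (200 datasets × 500 permutations per rule) put the
strictly-larger rule at roughly twice the nominal 5% familywise rate
(the tied mass is discarded, so entirely typical observations collect
small p-values), full tie counting at roughly half of it
(over-conservative), and the mid-p convention — ties count half — at the
nominal level. Mid-p is therefore the default, with `ties = "count"` and
`ties = "ignore"` available, plus an add-one smoothing option
(`(b+1)/(n_perm+1)`) for p-values bounded away from zero. All three rules
coincide on tie-free data.

## The synthetic-data module

`generate_heatmap()` plants a homogeneous Poisson number of Gaussian-profile
blobs (expected count = `blob_rate(severity) ×` box area in mm²; profiles
truncated at 3σ; overlaps combine by maximum so activations stay in [0,1])
plus clipped Gaussian background noise. The analytic blob rate is the point:
the generator's expected component count is checkable against an
independent connected-component oracle.

`generate_cohort()` emulates an Alzheimer's-continuum brain-donor cohort
with antemortem MRI. Covariates: age ~ N(75, 8) years, sex ~ Bernoulli(0.5),
3T field ~ Bernoulli(0.7), antemortem interval ~ U(0, 10) years,
ICV ~ N(1.4 × 10⁶, 1.5 × 10⁵) mm³ — chosen once as realistic for this kind
of autopsy cohort; no distributional claims beyond that are intended.
Latent tau severity is Gamma(2, 1) and TDP-43 severity Exponential(1);
quantitative measures are noisy monotone transforms of the latents, and
regional outcomes are linear combinations of the *measured* z-scored
predictors plus Gaussian noise, so a planted beta is exactly the
standardized coefficient a correctly specified model should recover. The
default residual sd is set so the z-scale outcome has approximately unit
variance (planted R² ≈ 0.28 for the default effects: tangles −0.4,
threads 0, MTL pTDP-43 rating −0.3).

Stage labels are derived by thresholding the latents, with cutpoints fixed
so the expected composition matches the study conditions this cohort
emulates: Braak V/VI prevalence 85/140, LATE-NC ≥ 1 prevalence 31/140,
LATE ≥ 2 at 10%, LATE 3 at ~3%. Two features of the ordinal p-tau rating
are deliberate: its cutpoints saturate for a majority of advanced-stage
subjects (the documented ceiling effect of ordinal burden ratings in severe
disease — the quantitative measure keeps varying where the rating is pinned
at 3), and the latent severity receives sd-0.35 rater noise before
coarsening (ordinal ratings are subjective consensus reads, not noiseless
functions of burden). Both are what make quantitative-versus-ordinal model
comparison a meaningful experiment rather than a tautology.

`generate_validation_boxes()` builds the statistic-selection testbed:
segment values carry a box-level baseline (slide-to-slide staining
variation), a small fraction (3%) of segments elevated in proportion to the
true burden rating (focal inclusions), and two saturated artifact segments
per box. Central statistics mostly see the baseline, the maximum is
corrupted by artifacts, and the 99th percentile tracks burden — the
structure under which a high quantile is the right summary.

`generate_surface_dataset()` plants an edge-connected thickness-deficit
disk on a planar triangulated template (default 64 × 64 cells, 4,225
vertices, 8,192 triangles — the simulation template throughout):
`thickness = baseline − effect × z(pathology)` inside the cluster plus unit
Gaussian vertex noise, so `effect` is the standardized per-vertex effect
size.

**What the generator does not emulate:** histology appearance or stain
chemistry (only activation-map statistics), spatially correlated vertex
noise or registration error on the surface (noise is i.i.d. across
vertices), longitudinal change, and any dependence between tau and TDP-43
latents (they are independent by default). Passing tests therefore
demonstrate correctness of the statistical machinery under the planted
model, not robustness to every artefact of real data.

## Problem sizes and numerical choices

The simulation suites use sizes chosen to make Monte-Carlo error small
relative to the property being checked: 200 replicate cohorts of n = 140
for parameter recovery (standard error of the mean ≈ 0.01 against a ±0.05
bias band), 200 null surface datasets × 500 permutations for familywise
error (binomial 95% band ≈ [0.02, 0.08] around 0.05), 100 replicates for
cluster power, and 500 simulated nulls for type-I error of the one-sided
regression test. Exact Mann–Whitney enumeration switches to the normal
approximation at `n1 × n2 > 100`. Ties in ranks use midranks throughout.
Degenerate inputs fail loudly: zero-variance columns, rank-deficient
designs (the collinear columns are named), empty masks, non-manifold
meshes, and empty rating groups are errors, while empty summaries propagate
missing values.

## Limitations

* The partitioner is a heuristic; it guarantees the partition invariants
  but not any optimality of boundary smoothness, and very thin or fractal
  masks can push segment sizes toward the ±20% edge of the balance band.
* The permutation test's exchangeability assumption is inherited from
  Freedman–Lane; heavy heteroscedasticity across subjects is not modelled.
* ROI measures assume heatmaps and masks are already aligned at the box
  level; slide registration is out of scope.
* Cluster areas depend on the attribution rule near boundaries; both rules
  are provided and the default is stated, but results at coarse meshes
  differ slightly between them.
* The cohort generator plants linear effects with Gaussian noise; it is not
  a model of biological dose-response, and its stage-prevalence calibration
  reflects one study's composition rather than population epidemiology.
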
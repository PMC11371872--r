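# mtlquant

Quantitative neuropathology to antemortem MRI morphometry, as an R package.

Neurodegenerative pathology in the medial temporal lobe (MTL) is classically
measured with semi-quantitative ordinal ratings (absent 0, rare 0.5, mild 1,
moderate 2, severe 3) assigned by neuropathologists, or with global staging
systems (Braak for tau, LATE-NC for TDP-43). Classifier attention heatmaps
on digitised histology slides offer a quantitative alternative. `mtlquant`
is for researchers who want to (a) turn such heatmaps into ROI-level and
hippocampus-level burden scores, (b) validate those scores against expert
ratings and staging, (c) relate them to regional MRI volume and thickness,
and (d) test whether quantitative scores model atrophy better than ordinal
ratings.

## What it computes

**Heatmap quantification.** A sampling box mask is partitioned into
contiguous, approximately equal-area segments (default 200 × 200 µm²) on the
4-neighbour pixel graph; the heatmap is averaged per segment, and a quantile
statistic across segments — the 99th percentile by default — gives the box
burden. ROI measures pool segment averages across all boxes sampling the
ROI. A rule-based hippocampal summary averages seven subfields (threads
exclude the dentate hilus; at least three regions required, the two dentate
subregions counting once), then a linear recalibration puts it on the 0–3
rating scale.

**Validation.** One-sided Mann–Whitney AUC between adjacent rating
categories or staging levels, `AUC = (wins + ½ ties)/(n₁n₂)`, with exact
enumeration for small comparisons; Spearman correlations; and a
statistic-selection experiment ranking eight candidate summaries by mean
adjacent-pair AUC.

**Association models.** For each region r with morphometry outcome y_r
(volume for anterior/posterior hippocampus, median thickness for ERC, BA35,
BA36, PHC), ordinary least squares on z-scored variables:

    z(y_r) = β₁ z(tangles) + β₂ z(threads) + β₃ z(pTDP rating)
             + γ' covariates + ε

with age, sex, field strength and antemortem interval as nuisance
covariates (plus ICV for the volume outcomes), one-sided p-values for
negative pathology effects, a Bonferroni threshold of 0.05/6 regions, and
quantitative-vs-semi-quantitative model comparison by ΔR²adj, L1 prediction
error, ΔAICc and ΔBIC (|ΔBIC| > 2/6/10 = positive/strong/very strong
evidence).

**Surface inference.** Pointwise GLM t-maps on a template mesh, clusters at
t > 2.0 over the edge graph, cluster surface area by fractional triangle
attribution, and familywise correction from the Freedman–Lane permutation
null of maximum cluster area.

**Synthetic data.** Generators for heatmaps (Poisson Gaussian blobs with an
analytic rate), ordinal ratings, cohorts with planted standardized effects
and stage labels, expert-rated validation boxes, and surface datasets with
a planted thickness-deficit cluster — so the full pipeline runs and is
tested without any external data.

## Worked example

```r
library(mtlquant)

cohort <- generate_cohort(140, seed = 3)
fit <- fit_region_model(cohort, "ERC",
                        c("tangles_q", "threads_q", "mtl_ptdp_sq"))
print(fit)
#> ROI model: ERC (thickness), n = 140, residual df = 132
#>   adj. R^2 = 0.211, AICc = -21.98, BIC = 3.12
#>   pathology contrasts (standardized beta, one-sided negative p):
#>     tangles_q      beta = -0.192  t =  -1.32  p = 0.0949
#>     threads_q      beta = -0.140  t =  -0.97  p = 0.166
#>     mtl_ptdp_sq    beta = -0.321  t =  -4.22  p = 2.21e-05
```

`n = 140` subjects leave 132 residual degrees of freedom for the thickness
model (8 coefficients; the volume models add ICV and leave 131). Betas are
standardized: this draw attributes the planted tau effect across the two
correlated tau measures, while the pTDP-43 rating shows its planted −0.3
association with entorhinal thickness (one-sided p = 2.2e-05, well past the
Bonferroni threshold `bonferroni_threshold(0.05, 6)` = 0.00833).

```r
covs <- c("age", "sex", "field_strength", "antemortem_interval", "mtl_ptdp_sq")
fq <- fit_region_model(cohort, "ERC", c("tangles_q", "threads_q"), covariates = covs)
fs <- fit_region_model(cohort, "ERC", "mtl_ptau_sq", covariates = covs)
compare_models(fq, fs)
#> Model comparison (ERC): quantitative - semi-quantitative
#>   dR2adj = +0.070  dPredErr = -5.329  dAICc = -10.62  dBIC = -7.96
#>   evidence: strong (favours quantitative)
```

Negative ΔBIC favours the quantitative model: here the continuous tau
measures beat the ordinal rating (which saturates at 3 for most
advanced-stage subjects) by about 8 BIC points — strong evidence.

```r
mesh <- planar_grid_mesh(32, 32)
surf <- generate_surface_dataset(60, mesh = mesh,
                                 pathology = cohort$tangles_q[1:60],
                                 effect = 0.8, seed = 2)
sg <- surface_glm(surf$thickness, cbind(tangles = surf$pathology),
                  "tangles", mesh, n_perm = 1000, seed = 3)
head(summary(sg), 4)
#>   cluster n_vertices area_mm2    peak_t p_corrected
#> 1       1        199      199 -9.526171       0.000
#> 2       2          2        2 -2.313290       0.473
#> 3       3          1        1 -2.483365       0.895
#> 4       4          1        1 -2.478409       0.895
```

The planted thickness-deficit cluster is recovered as a 199-vertex cluster
whose area exceeds every permutation maximum (corrected p = 0); the
scattered single-vertex noise clusters are correctly non-significant.

`run_pipeline(pipeline_config(seed = 1))` executes every stage end to end
and writes CSV tables, a PLY t-map mesh, and a JSON run manifest.

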
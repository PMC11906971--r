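# atroprop

Region-wise statistics for cortical atrophy progression in ageing and
Alzheimer's disease cohorts, working entirely from parcellated tables
(one value per cortical region per subject per scan). The package
covers the full analysis arc used in familial-risk studies of AD that
compare healthy controls (HC), cognitively normal subjects with a
family history of AD (FHAD), and clinical AD:

- **Normative W-score maps.** Per region, a least-squares reference
  `value ~ age + sex` is fitted on HC baseline scans;
  `W = (observed − predicted) / residual SD` expresses each subject's
  baseline atrophy in control-SD units (higher W = more atrophy than
  expected for age and sex).
- **Atrophy progression maps.** Per region, a linear mixed model with
  random intercept and age slope per subject (unstructured 2×2
  covariance, REML via lme4):
  `y ~ group*age + sex + education + BMI + APOE4 + APOE4:age +
  (1 + age | subject)`.
  The group×age interaction coefficient β (units/year) is the regional
  atrophy-progression estimate; the omnibus group×age F map is
  controlled by Benjamini–Hochberg FDR across regions, with post hoc
  contrasts (FHAD−HC, AD−HC, AD−FHAD) split by β sign.
- **Spatially constrained null models.** Variogram-matched surrogate
  maps preserve a map's spatial autocorrelation while destroying its
  topography; map-to-map correlations (e.g. β vs receptor density, or
  β vs tau-PET SUVR) are tested against the surrogate null ("spin
  test"), which stays calibrated where naive parametric Pearson
  p-values are anticonservative.
- **Connectome neighbor-spread statistic.** The correlation across
  regions between a map and the mean of each region's structurally
  connected neighbors — positive under the network-spread hypothesis —
  with the non-connected counterpart as a specificity contrast, and
  group-consensus construction of binary structural connectomes from
  subject matrices.
- **Receptor colocalization and correlation comparisons.** Z-scored,
  sample-size-weighted receptor/transporter maps; Fisher-z comparison
  of correlations from independent samples; Zou modified-asymptotic
  confidence intervals for differences of dependent correlations.
- **A synthetic cohort generator** with known ground truth (a
  connectome-diffused pathology pattern seeded at a bilateral
  epicenter, group-specific age slopes proportional to it, PET-like
  and receptor maps coupled to it), so every stage is validated
  end-to-end without access-restricted imaging data.

## Worked example

```r
library(atroprop)

co <- simulate_cohort(sim_config(rng_seed = 11))
co
#> <sim_cohort> R = 200 regions
#> <longitudinal_dataset> 410 scans, 150 subjects, 200 regions
#>   subjects per group: AD=50, FHAD=50, HC=50

# region-wise progression maps
pm <- progression_maps(co$dataset)
pm
#> <progression_fit> 200 regions, 410 scans, 150 subjects
#>   omnibus group x age FDR: 190 significant regions at q = 0.05

cor(coef(pm, "AD_vs_HC"), as.numeric(co$truth$true_beta$AD),
    method = "spearman")
#> [1] 0.9713913

# neighbor-spread test of the estimated progression map
D <- distance_matrix(co$connectome$coordinates)
spread_test(coef(pm, "AD_vs_HC"), co$connectome, D,
            n_surr = 1000, rng_seed = 7)
#> <spread_result> 200 regions used (0 excluded)
#>   connected neighbors:    r = 0.879, p_spin = 0.000999
#>   non-connected regions:  r = -0.86, p_spin = 0.00999
```

The progression fit recovers the generator's true β map almost
perfectly in rank order, and the estimated map correlates strongly
with its connected-neighbor average (and anti-correlates with the
non-connected average), as expected when pathology follows
connections. `run_pipeline(sim_config(), out_dir)` chains
simulate → wscore → progression → spread → colocalize into TSV
outputs plus a JSON run manifest with per-stage seeds and digests.

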
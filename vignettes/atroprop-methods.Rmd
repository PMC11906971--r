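---
title: "Methods: atrophy-progression mapping, spatial nulls, and the synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atrophy-progression mapping, spatial nulls, and the synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in
`atroprop`, the reasoning behind the tunable parameters and the
synthetic-data generator, and the numerical choices that a user of the
package should know about. All quantitative claims made here are the
ones computed by the package's test suite and by
`scripts/acceptance.R`; none are asserted from outside sources.

## The data model

Everything operates post-parcellation: a regional map is one scalar
per cortical region of a fixed parcellation, and a longitudinal
dataset is one row per scan with subject metadata (group, age at scan,
sex, education, BMI, APOE4 allele count, site, visit index) and one
column per region. Region identity is an ordered id vector, and every
multi-input operation verifies exact id agreement instead of silently
reindexing — misalignment between morphometry, PET, connectome and
receptor maps is the classic silent failure in this kind of analysis.
Missing regional values are carried as `NA` and propagate to
pairwise-complete handling in correlations; the package never imputes.

The deformation measure is oriented at load time so that larger values
mean more atrophy. All formats are delimited text (TSV by default,
comma accepted): datasets and maps as tables, adjacency as a dense 0/1
matrix, coordinates in mm.

## W-scores

The normative reference is a per-region least-squares fit on HC
baseline scans only:

$$y_i = \beta_0 + \beta_{age}\,\mathrm{age} + \beta_{sex}\,\mathrm{sex} + \varepsilon,
  \qquad \hat\sigma_i^2 = \mathrm{RSS}_i/(n-3),$$

with sex coded M = 0, F = 1 (the coding is stored in the serialized
model). The residual SD uses denominator $n-3$ — three fitted
parameters — for unbiasedness. W-scores are
$(y - \hat y)/\hat\sigma_i$; exactly age and sex enter the reference,
no other covariates. In-sample HC W-scores are mean-zero per region by
construction (asserted to $10^{-10}$). Ages more than 10 years outside
the reference range trigger an extrapolation warning.

A practical caveat verified by simulation: with $n$ held-out controls,
the per-region mean W has standard error $1/\sqrt{n}$ *by
construction* (W is standardized), and subject-level components shared
across regions (random intercepts, covariates not in the reference
model, site shifts) make the per-region means strongly correlated, so
the whole map's mean W wobbles around zero with an SD near 0.1 at
n = 100. Distributional checks on held-out W should therefore be read
map-wide, not region-by-region; the test suite asserts the
across-region average mean and SD, plus bulk per-region fractions.

## Region-wise progression mixed models

Per region, with age centered at the pooled baseline mean (centering
aids conditioning and leaves β in units/year):

```
y ~ group * age_c + sex + education_y + bmi + apoe4 + apoe4:age_c +
    (1 + age_c | subject_id)
```

fitted by REML through lme4, with HC as the reference level. The
group×age coefficients are the atrophy-progression estimates
(FHAD−HC and AD−HC directly; AD−FHAD as their difference, with SE from
the coefficient covariance — the linear contrast identity
β(AD−FHAD) = β(AD−HC) − β(FHAD−HC) holds exactly and is asserted).
The omnibus group×age test is a Wald F on the two interaction
coefficients with denominator df = n_obs − p; at the cohort sizes this
package targets the difference from a subject-level df is negligible
(checked against Satterthwaite during development).

Numerical policy for hundreds of independent fits:

- One template fit per random-effects structure is cached and each
  region is a `refit` of the template (the model matrices are
  identical across regions; only the response changes). A refit that
  raises a convergence warning or a nonzero optimizer code is retried
  as a fresh fit of the same structure, so results do not depend on
  which region seeded the template — region-order invariance is
  asserted in the tests.
- Fallback ladder on persistent non-convergence: unstructured 2×2
  random covariance → diagonal → intercept-only, each flagged in the
  result. Regions failing all three are excluded and logged.
- Finite-difference derivative checks (`calc.derivs`) are disabled:
  they dominate runtime across hundreds of fits and their warnings on
  these well-conditioned designs are almost always spurious;
  optimizer-level convergence codes are still checked per fit.

FDR control is Benjamini–Hochberg at q = 0.05 over the omnibus p map.
Post hoc contrast p-values are corrected *within* the
omnibus-significant set by default; whether the original analyses
corrected within that set or over all regions is not documented
anywhere we could check, so the alternative (`posthoc_scope = "all"`)
is exposed as a flag. Subjects with missing covariates are dropped,
not imputed.

Within one cohort the region-wise p-values share the subjects' random
slopes and are strongly dependent; calibration statements (uniform p
under the null, FDR rejection fractions) are therefore made across
independent simulated cohorts, and the suite sizes are: 50 null
cohorts for the FDR rejection rate, one region per cohort for the
KS-uniformity checks (30–50 cohorts). The spec-scale pooled check
(200 regions × 200 replicates) would add tens of minutes of runtime
for no extra information, given the dependence structure.

## Smaller procedures

- `partial_spearman`: all variables (score, network W, covariates) are
  rank-transformed, score and W ranks are residualized on the
  covariate ranks, and the residuals are correlated; two-sided p from
  a t reference with n − 2 − k df. Invariance to strictly monotone
  transforms is asserted.
- `compare_pet_groups`: region-wise OLS of SUVR on group plus
  age/sex/education/BMI/APOE4 for a two-group baseline PET dataset,
  one scan per subject, BH-FDR over regions. The whole region set is
  fitted in one QR decomposition.
- `chi_square_2x2` uses Pearson's χ² without continuity correction
  (the convention that reproduces published cohort-composition
  statistics); `scan_count_test` is the tie-corrected Kruskal–Wallis H
  on per-subject scan counts.

## Variogram-matched surrogate maps

Map–map correlations across cortical regions cannot be tested against
an i.i.d. permutation null: both maps are spatially smooth, so the
effective sample size is far below R and naive p-values are
anticonservative (the acceptance suite measures a >10% false-positive
rate for naive Pearson at α = 0.05 on independent 20 mm fields, versus
2–9% for the surrogate test). The null model reimplemented here
generates surrogates that preserve the empirical variogram:

1. Permute the map values.
2. For each candidate neighborhood size k, smooth the permuted map by
   distance-weighted averaging over each region's k nearest neighbors
   with an exponential kernel `exp(-d / d_k)` truncated at the k-th
   neighbor distance.
3. Regress the source variogram on the candidate's variogram
   (affine least squares over the distance bins) and keep the k with
   the smallest SSE.
4. Surrogate = √|β|·smoothed + √|α|·N(0, 1) noise.
5. Rank-remap the surrogate onto the source map's exact value multiset
   (default on; asserted exactly).

The empirical variogram uses 25 equal-width bins spanning distances up
to the 75th percentile, Gaussian-kernel smoothed across bins with
bandwidth two bin widths; empty bins are merged into their nearest
nonempty neighbor with a logged message. The candidate grid is
k ∈ {0.02, 0.05, 0.1, …, 0.9}·R: the two fractions below 0.1 matter
because short-correlation-length fields (~20 mm on a whole-cortex
geometry) need very local smoothing — with the grid floored at 0.1·R
the selector saturates at the floor and variogram fidelity drops below
0.9. All grid and bin parameters are exposed.

The spin test correlates the y map with each surrogate of the x map;
p is two-sided with the +1 permutation correction, so it is floored at
1/(n_surr + 1) and never zero. Which map is surrogated is a real
choice: this implementation always surrogates the *first* argument
(the atrophy/progression map in every pipeline use). One- versus
two-sided was also open; two-sided is used throughout and recorded in
the result object. A `surrogate_context` precomputes everything that
depends only on the distance matrix (bin pair indices, smoothing
matrices), which is what makes 500-test calibration suites affordable;
an ensemble built once can be reused across many y maps.

## Neighbor-spread statistic

For binary adjacency A (the package's connectomes are binary; a
weighted option exists but is off by default), the connected neighbor
mean of region i is the average of the map over `{j ≠ i : A_ij = 1}`,
and the non-connected counterpart averages over `{j ≠ i : A_ij = 0}`.
The spread test correlates map and neighbor means across regions and
builds the null by passing each surrogate *through the same neighbor
operator* — surrogating only one side would break the joint structure
under test. Regions with no connected neighbors are excluded listwise
from both contrasts so the paired comparison uses identical samples
(exclusion versus imputation is a package convention; the alternative
is not documented in the literature this follows). Matrix-arithmetic
neighbor means are asserted equal to a brute-force loop to 1e-12
(BLAS summation order differs from `mean()` at the last ulp, so
"exact" means exact to numerical precision).

The group-consensus connectome retains an edge present in at least
`retain_fraction` (default 0.5 — the group-averaging literature states
no parameter, so it is exposed) of subject matrices; a distance-binned
variant preserves the subject-mean edge count per edge-length bin,
counteracting the short-edge bias of naive consensus.

## Correlation comparisons

Between groups (independent samples) the Fisher-z test applies. Within
a sample, differences of dependent correlations get Zou
modified-asymptotic CIs: each correlation gets a Fisher-z CI, and the
corner combination is adjusted by the asymptotic correlation between
the two estimates — the shared-variable (overlapping) formula when the
two correlations share a map, the Pearson–Filon four-variable
covariance when they do not. With zero cross-correlations the
non-overlapping interval reduces algebraically to the
independent-samples corner formula (all four covariance products
vanish); this reduction is asserted exactly, and coverage is validated
by simulation (95% ± 2% at n = 448 over 2000 four-variate normal
datasets, and separately for the overlapping case). Within-group
tau-vs-amyloid comparisons are treated as dependent-overlapping
(shared atrophy map); between-group comparisons as independent — this
mirrors the data structure. The implied correlation structure is
checked for positive semidefiniteness and rejected otherwise.

## The synthetic cohort generator

The generator exists so that every stage has a ground truth. Per
subject j in group g, region i, scan at age t:

$$y = a_i + u_j + (s_0 + s_g\,p_i + v_j)\,t + \gamma^\top c_j +
  \mathrm{site}_j + \varepsilon$$

with spatially autocorrelated regional intercepts $a_i$ (exponential
covariance `exp(-d/λ)` via Cholesky factorization, λ = 20 mm — this is
what gives the null-model machinery something real to match), random
intercepts/slopes $u_j, v_j$, small nonzero covariate effects (so
covariate adjustment is actually exercised), site shifts (site is
deliberately *not* in the analysis model: the pipeline ingests
harmonized tables, and the generator's site effect only tests
robustness), and the ground-truth pattern $p$ scaled to unit maximum.

Geometry and connectome: R points on two mirrored 60 mm hemispheric
shells; edges drawn with probability ∝ `exp(-d/20 mm)` rescaled to a
target density of 0.1 (the scale constant is solved exactly; the
construction errors out if matching the target would saturate more
than half the pairwise probabilities, since the exponential profile
would be destroyed). Components holding under 10% of regions are
attached through their shortest link so neighbor statistics are
defined everywhere.

The pattern is degree-normalized network diffusion,
$\sum_{k\le K}\delta^k (D^{-1}A)^k s$ (degree normalization keeps
values bounded and hub-independent), seeded at a *bilateral epicenter*:
a random region plus its contralateral mirror point, 10 spatially
nearest regions each, with K = 8 and δ = 0.9. The epicenter choice is
both the biologically faithful one — AD pathology emerges focally and
roughly symmetrically — and the statistically necessary one: scattered
seeds put every region within one hop of a seed, producing a bimodal
pattern whose near-tied background destroys rank-order recovery at any
plausible cohort size.

Default condition parameters: 50 subjects per group, baseline ages
uniform on 66–80 y, up to 3 annual scans with 10% per-visit dropout,
normal-ageing slope 0.005/year, extra group slopes 0.008 (FHAD) and
0.02 (AD) units/year times the pattern. Noise defaults were set by a
power calculation, not by realism claims: the group×age SE at these
sizes is ≈ √(2(σ_e²/S_xx + σ_s²)/50), and for the region-wise map to
be recoverable in rank order the SE must sit well below the
between-region spread of true β (0.02 × SD(pattern) ≈ 0.006). That
fixes measurement noise σ_e = 0.002 and slope heterogeneity
σ_s = 0.003 (σ_s is also kept above the per-subject slope noise
σ_e/√S_xx so the REML slope variance does not sit at the boundary,
which would deflate the Wald SEs). These are optimistic but not absurd
for smoothed log-Jacobian deformation measures; what passing tests
show is that the *pipeline* is correct and calibrated under a
detectable-signal regime, not that real cohorts carry this much
signal. Features of real data the generator does not emulate: spatial
noise correlations beyond the exponential family, visit-schedule
irregularity, covariate–age dependence, scanner drift within site, and
any amyloid–tau interaction kinetics.

PET maps are per-subject baselines `1 + gain_g · p + smooth field +
iid noise` with group gains (AD ≫ FHAD > HC = 0); receptor targets are
`c_t · z(p) + √(1-c_t²) · z(smooth field)`, z-scored, with couplings
in [−0.6, 0.6] and some targets contributed by two tracers with
sample-size weights. Subject connectomes flip 5% of edges around the
group matrix. Everything is bit-reproducible from one seed; the
pipeline expands a global seed into per-stage seeds as
`seed + 1000·stage`.

## Problem sizes used by the validation suites

Recovery and calibration claims are computed at: R = 200 regions,
50/group for the recovery map; 50 independent all-null cohorts for the
FDR rate; 500 spin tests at 200 surrogates for spin calibration; 100
pattern seeds and 200 smooth-field replicates for spread power and
specificity; 100 surrogates for variogram fidelity; 2000 datasets at
n = 448 for Zou coverage; KS-uniformity across 30–50 independent
cohorts (one region each, see above). These sizes keep the full suite
within tens of minutes on one CPU while leaving every rate estimate
with a Monte-Carlo error comfortably below the margin it is checked
against.

## Known limitations

- The Wald/F inference uses a residual-df approximation rather than
  Satterthwaite or Kenward–Roger; fine at n ≥ 100 subjects, not
  recommended below ~30.
- The surrogate model matches the variogram, not the full spatial law;
  strongly anisotropic or non-stationary maps may be imperfectly
  matched (the fidelity statistic in the ensemble object makes this
  checkable per analysis).
- True spherical-rotation nulls are out of scope: the data model
  carries volumetric centroids, not sphere-registered parcels.
- Longitudinal W-scores are deliberately not provided (W applies at
  baseline); harmonization (ComBat-style) is upstream of this package.
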
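---
title: "Methods: pharmacokinetic similarity networks for TSPO PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacokinetic similarity networks for TSPO PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfp)
```

## Scope and model

`netfp` turns dynamic TSPO PET regional time-activity curves (TACs) into
single-subject inter-regional similarity networks and analyzes those
networks for reliability, covariate sensitivity, disease classification and
individual fingerprinting. This vignette documents the model, its
assumptions, the tunable parameters, the synthetic-data generator, and the
design decisions taken where the problem was genuinely open.

### Regional features

Each region of a fixed 87-region parcellation receives four features:
standardized uptake values at 1.25, 13.5 and 50 minutes post-injection, and
the influx rate K1 of a **single irreversible one-tissue compartment
model**. "Irreversible" means the efflux rate is zero, so the tissue curve
is $C_T(t) = K_1 \int_0^t C_p(\tau)\,d\tau$ and $K_1$ is a one-parameter
least-squares regression **through the origin** (not a Patlak fit with an
intercept) of the frame-midpoint TAC samples on the cumulated plasma input.
The estimate is clipped at zero. Assumptions this encodes:

* TACs are **decay-corrected upstream** (input contract; no correction is
  applied);
* the input function is consumed as a curve (no metabolite or plasma-free-
  fraction modelling);
* the tracer is effectively trapped over the fit window. Real TSPO tracers
  show some efflux; the resulting $K_1$ is then an apparent uptake rate.
  This is acceptable because the feature enters a *similarity contrast*
  between regions, not an absolute quantification.

### Tunable parameters (kinetics)

| parameter | default | units | why |
|---|---|---|---|
| `suv_times_minutes` | 1.25, 13.5, 50 | min | early delivery, intermediate, late retention sampling of the TAC |
| `k1_fit_window_minutes` | (0, 50) | min | matches the latest SUV time; identical across 60- and 90-min protocols |
| `idif_integration` | trapezoid | — | exact for piecewise-linear inputs; integration grid is the union of IDIF samples and frame midpoints |

The common time grid is the **frame midpoints** with linear interpolation —
the standard frame-time convention; interpolation is then exact on native
frames. The fit window and the SUV times are configurable because neither is
uniquely determined by the problem; the defaults keep the fit support
identical across the acquisition protocols the package emulates.

### Standardization and similarity

Features are pooled over all region × scan values **within a tracer group**
and standardized with a robust z-score, $(x - \mathrm{median})/\mathrm{MAD}$
with the **raw** MAD (no 1.4826 consistency constant — the constant would
rescale all distances jointly and cancel in any rank-based statistic).
Pooling regions preserves the between-region contrast that the similarity
depends on; per-region standardization would erase exactly the signal being
measured. A zero MAD is an error ("degenerate feature dispersion"), never a
silent epsilon. Then

$$S_{ij} = \frac{1}{1 + d_{ij}}, \qquad
  d_{ij} = \lVert x_i - x_j \rVert_2 ,$$

a similarity kernel with $S_{ii}=1$, symmetric, range $(0,1]$, strictly
decreasing in distance. The canonical edge vector is the row-major upper
triangle in registry order (3741 edges for 87 regions); all statistics
operate on it.

### Parcellation registry

The registry fixes 87 regions: 68 bilateral Desikan–Killiany cortical
regions, 16 subcortical regions, bilateral cerebellar cortex, brainstem.
The 16 subcortical regions are not uniquely dictated by the problem; the
package adopts the standard bilateral set {thalamus, caudate, putamen,
pallidum, hippocampus, amygdala, accumbens, ventral diencephalon}, which is
consistent with the subcortical structures that matter downstream
(putamen, pallidum, thalamus, accumbens, caudate). The canonical order
(left cortical, right cortical, left subcortical, right subcortical,
cerebellum L/R, brainstem) is fixed by the registry, **not** by input file
order, so edge indices are reproducible across runs and sites.

### Harmonization

Multi-site PET edges carry technical and biological covariate effects. Each
edge gets an OLS model on batch (one-hot, reference = alphabetically first
level, for determinism), sex, TSPO genotype, age and dose/weight (continuous
covariates centered on the fit subset). Correction subtracts the fitted
covariate effects but **keeps the intercept**, so corrected values stay on
the similarity scale. In the disease pipeline the model is fitted **only on
healthy controls of the training split** and applied to everyone: patient
rows never inform the correction, which preserves disease-related variance
and prevents leakage. Linearity of covariate effects is an acknowledged
simplification (no empirical-Bayes shrinkage); it is what makes HC-only
estimation feasible at modest sample sizes.

Cohen's *d* summaries of a covariate's edgewise effect use a model fitted
with z-scored predictors *and* outcomes (both, since the convention is not
otherwise fixed — documented choice), $d = \mathrm{mean}(\beta)/
\mathrm{SD}(\beta)$ over edges, with a percentile bootstrap CI over edges
(default 10,000 resamples). Edges are treated as exchangeable units.

### Reliability

* **Blocking**: per-scan statistic = median of the strict upper triangle;
  one-tailed Wilcoxon signed-rank test (post > pre). Zero differences are
  dropped (signed-rank convention); the null is exact for n ≤ 25 untied
  pairs and normal with continuity correction above. With six uniformly
  positive differences the exact one-tailed p is $2^{-6} = 0.015625$.
* **Test-retest**: per-subject Spearman ρ between edge vectors; edgewise
  ICC(3,1) from the two-way mixed-effects mean squares,
  $(MS_R - MS_E)/(MS_R + MS_E)$ for two sessions.
* **Identification**: rank retest scans by Spearman ρ against each test
  scan; exact ties go to the first index with a warning (ties have
  probability zero in continuous data).

### Classification

L1-regularized logistic regression on the (harmonized, train-z-scored)
edges. Penalty grid: 15 log-spaced values in $[10^{-3}, 10^2]$, chosen by
repeated stratified 10-fold CV (10 × 10 by default) maximizing mean average
precision, with the fold count reduced so every fold holds at least one
positive; score ties resolve to the **stronger** penalty. Test-set AP and
ROC AUC carry percentile bootstrap CIs (1,000 resamples of test items). AP's
chance level is the test-set positive prevalence. No class weights —
imbalance is handled by reporting AP, not by reweighting. Regional
importance is $\sum |\beta|$ over a region's edges, so
$\sum_{\mathrm{ROI}} \mathrm{score} = 2 \sum_{\mathrm{edges}} |\beta|$
always. Overlap between two tasks' coefficient vectors is Kendall's τ by
default (Spearman available), reflecting the two conventions in circulation.

Covariate prediction (batch / sex / genotype) first residualizes the *other*
covariates (batch prediction: sex/genotype/age/DW removed; sex or genotype:
batch removed), then grid-searches elastic-net logistic regression and
k-nearest neighbours by 10-fold CV on balanced accuracy. **SVMs are not
included**: no SVM implementation exists in the supported dependency set,
so the model family is the two remaining classifiers. This narrows the model
menu, not the measured question (is the covariate decodable from the
edges?).

Patient fingerprinting assigns each patient the diagnosis of their
maximum-Spearman neighbour (self excluded) and reports the confusion matrix,
per-group recall, and balanced accuracy (= mean recall; chance level $1/k$
for $k$ groups).

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses assume:

* **input function**: tri-exponential bolus
  $C_p(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
  A_3 e^{-\lambda_3 t}$, clipped at 0, $C_p(0)=0$ — the classic arterial
  bolus shape with standard parameter values;
* **regional kinetics**: $C_r(t) = s\,(K_1^{(r)} \int_0^t C_p + f_v^{(r)}
  C_p(t))$ — irreversible trapping plus a small fast vascular/free
  component ($f_v \sim U(0.02, 0.08)$) that decorrelates early SUVs from
  K1 across regions, as in real data;
* **regional template**: $K_1$ drawn once per design (log-normal around
  0.12 mL·cm⁻³·min⁻¹, log-SD 0.25 — a plausible between-region spread for
  TSPO tracers); subjects perturb the template log-normally
  (`subject_sd = 0.10`), giving each subject a persistent network identity;
* **frames**: frame values are **frame averages** of the true curve (how
  PET frames integrate counts); the midpoint-interpolating reader then
  incurs realistic, bounded model error. A `"midpoint"` sampling mode
  exists for exact-recovery tests;
* **noise**: Gaussian with SD $= \kappa \sqrt{C/\Delta t}$ per frame — the
  standard count-statistics surrogate for reconstructed PET, giving early
  short frames the largest relative noise;
* **batch and covariates**: batch multiplies all TAC values; sex, genotype,
  age and dose/weight enter as multiplicative modulations of regional
  uptake, so they propagate through the kinetics into the features, where
  the harmonization model sees them as (approximately linear) edge effects;
* **disease**: localized multiplicative change of $K_1$ and $f_v$ in
  designated regions;
* **sessions**: retest redraws measurement noise (optionally jitters
  parameters); blockade shrinks the regional parameter dispersion toward
  the subject median by `blockade_factor` (default 0.5) — it reproduces the
  observable consequence of target blockade (flatter regional profile,
  higher median similarity) without claiming an occupancy pharmacology
  model.

`simulate_edge_cohort()` generates edge tables directly (base pattern +
per-tracer perturbation + multiplicative batch scale + additive covariate
effects + group signatures in noise-SD units + iid Gaussian noise). It is
the generator for the harmonization/classification/fingerprinting property
suites, whose effect sizes are *stated in edge units* ("k noise-SDs on m
designated edges"); routing those through TAC space would make the stated
effect size unverifiable.

**What the simulator does not emulate** — and hence what a green test does
not establish: image-space effects (partial volume, scanner resolution,
reconstruction artifacts), non-linear covariate effects, efflux kinetics,
genotype-by-tracer affinity interactions, realistic spatial correlation of
edge noise. Green property tests establish that the *pipeline* recovers
what it assumes; they are not a reproduction of clinical effect sizes.

## Numerical choices and degenerate inputs

* Interpolation outside the frame-midpoint support is an error naming the
  offending time; SUV times later than the scan end are an error naming the
  time.
* An all-zero plasma integral is an error ("degenerate input function");
  all-zero TACs yield zero features (valid limit).
* Zero MAD and zero beta-SD are errors, not epsilons.
* Rank-deficient harmonization designs error with the collinear column
  names; single-level factors are reported as such.
* Identification and KNN ties resolve to the first index, deterministically.
* All randomness is seed-parameterized; child seeds are derived from the
  run seed (kept below $2^{31}$), and RNG state is restored after use, so
  no function perturbs the caller's stream.

## Scaling decisions in the acceptance suite

The simulation-based acceptance criteria (classification power/null,
fingerprinting analogue) run on a 30-region head of the registry (435
edges) with single-pass CV and 50-resample CIs, keeping the 100-seed loops
within a 1-CPU desk budget. The *stated world* — 50 affected edges at 3
noise-SDs, n = 60/60; five disjoint 40-edge signatures at 3 noise-SDs — is
unchanged. For the importance-recovery property, the 50 affected edges are
drawn from the edges *among* a designated 11-region set (C(11,2) = 55 ≥
50), the natural construction for a regionally localized disease: every
affected edge then credits importance to designated regions, making "top-5
importance regions ⊂ designated set" the correct recovery criterion.

## Known limitations

* K1 from a blood-free IDIF inherits IDIF biases; only relative, not
  absolute, interpretation is supported.
* Linear harmonization cannot remove non-linear batch effects; strongly
  batch-confounded diagnoses (a disease present in only one batch) can be
  over- or under-corrected, which is why the uncorrected fingerprinting
  variant exists as a sensitivity analysis.
* The multiclass and covariate classifiers share the leakage-safe pipeline
  but have no SVM arm (environment constraint, see above).
* Balanced accuracy of fingerprinting is estimated on all patients jointly
  (no held-out split); it measures nearest-neighbour structure, not
  generalization of a fitted model.
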
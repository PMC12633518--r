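# netfp — PET pharmacokinetic similarity networks and disease fingerprinting

`netfp` builds **single-subject inter-regional similarity networks** from
dynamic TSPO PET data and uses them for reliability analysis, disease
classification, and individual-level diagnostic fingerprinting.

Conventional TSPO PET quantification reduces each brain region to a binding
magnitude and ignores the *spatial organization* of the neuroinflammatory
signal. `netfp` instead characterizes, for every scan, how similar each pair
of regions is in its tracer pharmacokinetics, producing a subject-specific
network whose edges are the analysis features. The package is aimed at PET
methodologists and neuroimaging statisticians working with multi-site
regional time-activity curve (TAC) data.

## The model

For each scan, every region *i* of a fixed 87-region parcellation
(bilateral Desikan–Killiany cortex, bilateral subcortical structures,
cerebellar cortex, brainstem) gets a 4-element feature vector

> x_i = ( SUV(1.25 min), SUV(13.5 min), SUV(50 min), K1 )

where SUV(t) = C(t) / (dose/weight) and K1 is the blood-to-brain influx rate
of a **single irreversible one-tissue compartment model** fitted against an
image-derived input function C_p:

> C_T(t) = K1 · ∫₀ᵗ C_p(τ) dτ  (least squares through the origin)

Features are standardized per tracer group with a **robust z-score**
(x − median)/MAD, and each pair of regions receives the
**inverse-Euclidean similarity**

> S_ij = 1 / (1 + d_ij),  d_ij = ‖x_i − x_j‖₂  ∈ (0, 1]

The R(R−1)/2 = 3741 upper-triangle edges are then:

- **harmonized** with per-edge linear models (batch, sex, TSPO genotype,
  age, dose/weight), fitted on healthy controls only so that disease-related
  variance is preserved;
- assessed for **reliability**: test-retest Spearman ρ, edgewise ICC(3,1),
  retest identification, and a one-tailed Wilcoxon signed-rank test for
  pharmacological blocking (blockade flattens the regional profile and
  *raises* median similarity);
- fed to **L1-regularized logistic regression** (penalty chosen by repeated
  stratified 10-fold CV maximizing average precision) for disease
  classification, with per-region importance = Σ|β| over the edges touching
  the region;
- used for **patient fingerprinting**: each patient is assigned the
  diagnosis of their maximum-Spearman neighbour (chance level 1/k groups).

A **synthetic cohort simulator** (tri-exponential bolus input, one-tissue
kinetics, frame-duration-dependent noise, multiplicative batch effects,
covariate and localized disease effects, retest and blockade sessions)
provides ground truth for every analysis.

## Worked example

```r
library(netfp)

design <- cohort_design(
  groups = list(
    list(name = "HC",  n = 12, affected_rois = character(0), effect = 0),
    list(name = "TBI", n = 8,
         affected_rois = c("L_lateralorbitofrontal", "R_lateralorbitofrontal",
                           "L_medialorbitofrontal",  "R_medialorbitofrontal"),
         effect = 0.2)),
  batches = data.frame(name = c("siteA", "siteB"),
                       tracer = "PBR28", scale = c(1.00, 1.08)),
  n_retest = 5, noise_kappa = 0.3, seed = 42)

cohort <- simulate_cohort(design)            # 25 scans (incl. 5 retests)
nets   <- build_cohort_networks(cohort$scans)
dim(nets$edges)
#> [1]   25 3741

cov <- scan_covariates(cohort$scans)
hc  <- cov$diagnosis == "HC" & cov$session == "baseline"
round(cohort_consistency(nets$edges[hc, ], cov$tracer[hc])$global, 3)
#> median    mad
#>  0.589  0.031
```

Inter-subject consistency (median Spearman ρ ± MAD over HC pairs) shows the
shared network backbone. Test-retest reliability and identification:

```r
rt   <- cov$session == "retest"
subj <- cov$subject_id[rt]
te <- nets$edges[cov$scan_id[cov$session == "baseline" &
                             cov$subject_id %in% subj], ]
re <- nets$edges[cov$scan_id[rt], ]
icc <- edgewise_icc(te, re)
c(icc$median, icc$mad)
#> [1] 0.914 0.065
identify_subjects(te, re)$accuracy
#> [1] 1
```

Disease classification with HC-only confound correction:

```r
bl <- cov$session == "baseline"
rep1 <- classify_disease_binary(
  nets$edges[bl, ], cov$diagnosis[bl], cov[bl, ],
  classification_config(n_repeats = 2, n_boot = 500,
                        harmonization_design = c("batch", "sex", "age")),
  seed = 7)
rep1
#> <classifier_report> TBI vs HC
#>   test AP 1.000 [1.000, 1.000] (chance 0.333); ROC AUC 1.000 [1.000, 1.000]
#>   lambda 0.1389; 7 nonzero edges
head(sort(rep1$importance, decreasing = TRUE), 3)
#> L_medialorbitofrontal  R_parstriangularis  R_medialorbitofrontal
#>             0.915                0.915                0.545
```

The test-set average precision (1.0, chance = positive prevalence 0.33) and
the top-importance regions — dominated by the orbitofrontal regions the
simulation actually perturbed — show the pipeline recovering a localized
disease signature from network edges.

## Command line

```sh
Rscript inst/cli/netfp.R simulate  --out-dir demo --seed 11
Rscript inst/cli/netfp.R run-all   --seed 11 --out-dir demo_run
Rscript inst/cli/netfp.R classify  --manifest demo/manifest.json \
                                   --out-dir demo_cls --seed 11
```

(after installation the script lives at
`system.file("cli/netfp.R", package = "netfp")`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
assumptions, all tunable parameters with defaults and units, what the
simulator does and does not emulate, and the numerical design choices.
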
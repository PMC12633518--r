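test_that("input function: shape, zero, linearity", {
  idif <- simulate_input_function(grid = seq(0, 90, 0.05))
  cp <- idif$concentrations
  expect_equal(cp[1], 0)
  peak <- which.max(cp)
  expect_lt(idif$times[peak], 5)           # single early peak
  expect_true(all(diff(cp[peak:length(cp)]) <= 1e-12))  # monotone decay after

  p0 <- feng_params(A1 = 0, A2 = 0, A3 = 0)
  expect_true(all(simulate_input_function(p0, 0:60)$concentrations == 0))

  p2 <- feng_params(A1 = 2 * 851.1, A2 = 2 * 21.88, A3 = 2 * 20.81)
  cp2 <- simulate_input_function(p2, seq(0, 90, 0.05))$concentrations
  expect_equal(cp2, 2 * cp, tolerance = 1e-12)
})

test_that("simulate_scan: determinism, noise scaling, zero-noise recovery", {
  reg <- subset_registry(8)
  k1 <- seq(0.08, 0.15, length.out = 8)
  s1 <- simulate_scan("a", "p", k1 = k1, registry = reg,
                      noise_kappa = 0.4, seed = 99)
  s2 <- simulate_scan("a", "p", k1 = k1, registry = reg,
                      noise_kappa = 0.4, seed = 99)
  expect_identical(s1$scan$tacs, s2$scan$tacs)

  # doubling kappa doubles the empirical frame-residual SD (~200 frames)
  resid_sd <- function(kappa, seed) {
    sim <- simulate_scan("a", "p", k1 = k1, registry = reg,
                         noise_kappa = kappa, seed = seed)
    r <- sim$scan$tacs - sim$truth$noiseless_frames
    # restrict to high-count frames where the 0-clip never binds
    keep <- sim$truth$noiseless_frames > 0.25 * max(sim$truth$noiseless_frames)
    sd(r[keep] / sqrt(sim$truth$noiseless_frames[keep]))
  }
  ratios <- vapply(1:8, function(s) resid_sd(0.4, s) / resid_sd(0.2, s + 100),
                   numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.2)

  # zero noise, no fast component: K1 to 1e-6, SUV profile from ground truth
  s0 <- simulate_scan("z", "p", k1 = k1, fv = rep(0, 8), registry = reg,
                      frame_sampling = "midpoint", seed = 1)
  f <- extract_features(s0$scan)
  expect_lt(max(abs(f[, "k1"] - k1) / k1), 1e-6)
})

test_that("simulate_cohort: manifest, retest duplication, determinism", {
  reg <- subset_registry(10)
  design <- cohort_design(
    groups = list(list(name = "HC", n = 10, affected_rois = character(0),
                       effect = 0),
                  list(name = "DIS", n = 10,
                       affected_rois = reg$name[1:2], effect = 0.2)),
    registry = reg, schedule = toy_schedule(), noise_kappa = 0.1, seed = 77)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(design, out_dir = dir)
  expect_length(sim$scans, 20)
  expect_silent(reloaded <- load_cohort(sim$manifest, registry = reg))
  expect_length(reloaded, 20)

  sim2 <- simulate_cohort(design)
  expect_identical(sim2$scans[[1]]$tacs, sim$scans[[1]]$tacs)
  expect_identical(sim2$scans[[20]]$tacs, sim$scans[[20]]$tacs)

  # retest with zero within-subject noise duplicates the session exactly,
  # so downstream identification is perfect
  design_rt <- cohort_design(
    groups = list(list(name = "HC", n = 6, affected_rois = character(0),
                       effect = 0)),
    registry = reg, schedule = toy_schedule(), n_retest = 6,
    retest_sd = 0, noise_kappa = 0, seed = 5)
  sim_rt <- simulate_cohort(design_rt)
  nets <- build_cohort_networks(sim_rt$scans)
  cov <- scan_covariates(sim_rt$scans)
  te <- nets$edges[cov$session == "baseline", ]
  re <- nets$edges[cov$session == "retest", ]
  expect_equal(identify_subjects(te, re)$accuracy, 1)
})

test_that("disease effects land on the designated regions", {
  reg <- subset_registry(10)
  hit <- reg$name[3:4]
  design <- cohort_design(
    groups = list(list(name = "HC", n = 1, affected_rois = character(0),
                       effect = 0),
                  list(name = "DIS", n = 1, affected_rois = hit,
                       effect = 0.5)),
    registry = reg, schedule = toy_schedule(), noise_kappa = 0,
    subject_sd = 0, covariate_coefs = list(sex_M = 0, genotype_MAB = 0,
                                           age = 0, dw = 0),
    batches = data.frame(name = "B1", tracer = "PBR28", scale = 1),
    seed = 13)
  sim <- simulate_cohort(design)
  t_hc <- sim$truth[["sub001_baseline"]]$k1_true
  t_d <- sim$truth[["sub002_baseline"]]$k1_true
  idx <- match(hit, reg$name)
  expect_equal(t_d[idx], 1.5 * t_hc[idx], tolerance = 1e-12)
  expect_equal(t_d[-idx], t_hc[-idx], tolerance = 1e-12)
})

test_that("simulate_edge_cohort: determinism and injected structure", {
  args <- list(n_regions = 10, groups = c(HC = 20, DIS = 20),
               affected_edges = list(DIS = 1:5), effect_size = 3,
               noise_sd = 0.02, seed = 55)
  a <- do.call(simulate_edge_cohort, args)
  b <- do.call(simulate_edge_cohort, args)
  expect_identical(a$edges, b$edges)
  expect_identical(a$covariates, b$covariates)

  d <- colMeans(a$edges[a$covariates$diagnosis == "DIS", 1:5]) -
    colMeans(a$edges[a$covariates$diagnosis == "HC", 1:5])
  expect_equal(mean(d), 3 * 0.02, tolerance = 0.35)
  expect_error(simulate_edge_cohort(groups = c(HC = 5)), "explicit seed")
})
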
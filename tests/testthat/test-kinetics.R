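test_that("interpolate_to_grid: midpoint identity, linearity, support", {
  sched <- frame_schedule(c(0, 2, 4), c(2, 4, 6))   # midpoints 1, 3, 5
  expect_equal(interpolate_to_grid(rep(5, 3), sched, c(1, 2.5, 4.9)),
               rep(5, 3))
  expect_equal(interpolate_to_grid(c(1, 7, 3), sched,
                                   frame_midpoints(sched)), c(1, 7, 3))
  # (t=1, v=0) and (t=3, v=4): query t=2 -> 2
  expect_equal(interpolate_to_grid(c(0, 4, 4), sched, 2), 2)
  expect_error(interpolate_to_grid(c(1, 2, 3), sched, 6.5),
               "t=6.5.*outside")
})

test_that("compute_suv closed forms and rescaling invariance", {
  sched <- frame_schedule(c(0, 2), c(2, 4))
  expect_equal(compute_suv(c(10, 10), sched, 500, 70, 2), 1.4)
  expect_equal(compute_suv(c(0, 0), sched, 500, 70, 2), 0)
  # C(t) equal to dose[kBq]/weight[g] gives SUV 1
  expect_equal(compute_suv(rep(500 * 1000 / 70000, 2), sched, 500, 70, 2), 1)
  # simultaneous rescaling of dose and activity leaves SUV unchanged
  expect_equal(compute_suv(c(8, 2) * 3.7, sched, 400 * 3.7, 70, 3),
               compute_suv(c(8, 2), sched, 400, 70, 3))
  expect_error(compute_suv(c(1, 1), sched, 0, 70, 2), "dose and weight")
})

test_that("estimate_k1 recovers constructed irreversible kinetics", {
  # Feng-style input, TAC = 0.12 * cumulative plasma integral
  toy <- toy_irreversible_tac(0.12)
  k1 <- estimate_k1(toy$tac, default_schedule(), toy$idif, c(0, 50))
  expect_lt(abs(k1 - 0.12) / 0.12, 1e-6)

  # constant Cp = 1: integral is t, TAC = 0.1 * t at midpoints
  sched <- toy_schedule()
  mid <- frame_midpoints(sched)
  idif <- input_function(seq(0, 60, 0.5), rep(1, 121))
  expect_equal(estimate_k1(0.1 * mid, sched, idif, c(0, 60)), 0.1,
               tolerance = 1e-12)

  # linearity: doubling the TAC doubles K1 exactly
  expect_equal(estimate_k1(0.2 * mid, sched, idif, c(0, 60)),
               2 * estimate_k1(0.1 * mid, sched, idif, c(0, 60)))

  # degenerate input
  idif0 <- input_function(c(0, 30, 60), c(0, 0, 0))
  expect_error(estimate_k1(0.1 * mid, sched, idif0, c(0, 60)),
               "degenerate input function")
  expect_error(estimate_k1(c(1, 2), frame_schedule(c(0, 1), c(1, 2)),
                           idif, c(0, 2)),
               "fewer than 3 frames")
})

test_that("K1 integration error shrinks as the IDIF grid is refined", {
  sched <- default_schedule()
  mid <- frame_midpoints(sched)
  # reference: near-exact integral on a very fine grid
  ref <- toy_irreversible_tac(0.12,
    idif = simulate_input_function(grid = sort(unique(c(seq(0, 90, 0.002),
                                                        mid)))))
  err <- vapply(c(1, 0.05), function(dt) {
    idif <- simulate_input_function(grid = seq(0, 90, dt))
    abs(estimate_k1(ref$tac, sched, idif, c(0, 50)) - 0.12)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2] / 0.12, 1e-3)
})

test_that("extract_features: simulator ground truth, errors, degenerate", {
  reg <- subset_registry(6)
  k1_true <- seq(0.06, 0.16, length.out = 6)
  sim <- simulate_scan("s1", "p1", k1 = k1_true, fv = rep(0, 6),
                       registry = reg, frame_sampling = "midpoint", seed = 1)
  f <- extract_features(sim$scan)
  expect_equal(unname(f[, "k1"]), k1_true, tolerance = 1e-9)
  # SUVs at frame midpoints are exact (interpolation identity)
  mids <- frame_midpoints(sim$scan$schedule)
  cfg <- kinetics_config(suv_times_minutes = mids[c(3, 12, 20)])
  f2 <- extract_features(sim$scan, cfg)
  expected <- sim$truth$noiseless_frames[, c(3, 12, 20)] *
    sim$scan$weight / sim$scan$dose
  expect_equal(unname(f2[, 1:3]), unname(expected), tolerance = 1e-12)

  # scan ending before the latest SUV time
  short <- frame_schedule(seq(0, 36, 4), seq(4, 40, 4))
  tacs <- matrix(1, 6, 10, dimnames = list(reg$name, NULL))
  scan40 <- scan_record("s", "p", "PBR28", "B", 400, 70, 40, "M",
                        tacs = tacs, schedule = short,
                        idif = simulate_input_function(grid = seq(0, 40, 0.5)),
                        registry = reg)
  expect_error(extract_features(scan40), "t=50")

  # all-zero TACs give all-zero features
  tsched <- toy_schedule()
  scan0 <- scan_record("s0", "p", "PBR28", "B", 400, 70, 40, "M",
                       tacs = matrix(0, 6, n_frames(tsched),
                                     dimnames = list(reg$name, NULL)),
                       schedule = tsched,
                       idif = simulate_input_function(grid = seq(0, 60, 0.5)),
                       registry = reg)
  expect_true(all(extract_features(scan0) == 0))
})

test_that("noisy K1 recovery is approximately unbiased (short MC)", {
  reg <- subset_registry(2)
  base <- simulate_scan("b", "p", k1 = c(0.12, 0.12), fv = c(0, 0),
                        registry = reg, seed = 1)
  cmax <- max(base$truth$noiseless_frames)
  f_peak <- which.max(apply(base$truth$noiseless_frames, 2, max))
  dt_peak <- base$scan$schedule$frame_end[f_peak] -
    base$scan$schedule$frame_start[f_peak]
  kappa <- 0.05 * sqrt(cmax * dt_peak)   # SD at the peak frame = 5% of peak
  rel_err <- vapply(1:10, function(s) {
    sim <- simulate_scan("n", "p", k1 = c(0.12, 0.12), fv = c(0, 0),
                         registry = reg, noise_kappa = kappa, seed = s)
    f <- extract_features(sim$scan)
    abs(f[1, "k1"] - 0.12) / 0.12
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})
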
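# helper: covariate table with controllable structure
make_cov <- function(n, batches = c("A", "B"), seed = 1) {
  withr::with_seed(seed, {
    cov <- data.frame(
      scan_id = sprintf("s%03d", 1:n),
      subject_id = sprintf("s%03d", 1:n),
      tracer = "PBR28",
      batch = c(rep_len(batches, min(n, 2 * length(batches))),
                sample(batches, max(0, n - 2 * length(batches)),
                       replace = TRUE)),
      dose = rnorm(n, 400, 40), weight = rnorm(n, 75, 10),
      age = runif(n, 20, 80),
      sex = c("M", "F", sample(c("M", "F"), n - 2, replace = TRUE)),
      genotype = c("HAB", "MAB",
                   sample(c("HAB", "MAB"), n - 2, replace = TRUE)),
      diagnosis = "HC", session = "baseline",
      stringsAsFactors = FALSE)
    cov$dw <- cov$dose / cov$weight
    cov
  })
}

make_linear_edges <- function(cov, E = 40, betas, seed = 2) {
  withr::with_seed(seed, {
    X <- cbind(batch_B = as.numeric(cov$batch == "B"),
               sex_M = as.numeric(cov$sex == "M"),
               genotype_MAB = as.numeric(cov$genotype == "MAB"),
               age = cov$age, dw = cov$dose / cov$weight)
    base <- matrix(runif(E, 0.3, 0.8), nrow(cov), E, byrow = TRUE)
    edges <- base + X %*% betas
    dimnames(edges) <- list(cov$scan_id, paste0("e", 1:E))
    edges
  })
}

test_that("zero-noise linear edges residualize to constants", {
  cov <- make_cov(40)
  betas <- withr::with_seed(3, matrix(rnorm(5 * 40, 0, 0.02), 5, 40))
  edges <- make_linear_edges(cov, 40, betas)
  m <- fit_edgewise_model(edges, cov)
  corrected <- residualize(m, edges, cov)
  # every edge column collapses to a constant
  spread <- apply(corrected, 2, function(x) max(x) - min(x))
  expect_lt(max(spread), 1e-10)
})

test_that("rank-deficient designs are rejected with names", {
  cov <- make_cov(30, batches = "A")
  edges <- withr::with_seed(1, matrix(rnorm(30 * 10), 30, 10,
                                      dimnames = list(cov$scan_id,
                                                      paste0("e", 1:10))))
  expect_error(fit_edgewise_model(edges, cov),
               "covariate 'batch' has a single level")
  # collinear continuous column
  cov2 <- make_cov(30)
  cov2$dw <- cov2$age * 2
  edges2 <- edges
  expect_error(fit_edgewise_model(edges2, cov2,
                                  design = c("age", "dw")),
               "collinear column")
  # too-small fit subset
  cov3 <- make_cov(30)
  expect_error(fit_edgewise_model(edges, cov3,
                                  fit_subset = cov3$scan_id[1:5]),
               "fit subset too small")
})

test_that("injected sex effect is recovered within stated bounds", {
  cov <- make_cov(100, seed = 8)
  betas <- matrix(0, 5, 200)
  betas[2, ] <- 0.02   # sex_M on all edges
  edges <- make_linear_edges(cov, 200, betas, seed = 9) +
    withr::with_seed(10, matrix(rnorm(100 * 200, 0, 0.01), 100, 200))
  m <- fit_edgewise_model(edges, cov)
  expect_gt(median(m$coefficients["sex_M", ]), 0.015)
  expect_lt(median(m$coefficients["sex_M", ]), 0.025)
})

test_that("residualize: OLS orthogonality, identity, effect preservation", {
  cov <- make_cov(60, seed = 5)
  edges <- make_linear_edges(cov, 50,
                             withr::with_seed(6, matrix(rnorm(250, 0, .02),
                                                        5, 50)),
                             seed = 7) +
    withr::with_seed(8, matrix(rnorm(60 * 50, 0, 0.01), 60, 50))
  m <- fit_edgewise_model(edges, cov)
  corrected <- residualize(m, edges, cov)
  # corrected edges are uncorrelated with each continuous covariate
  for (v in c("age")) {
    r <- abs(cor(corrected, cov[[v]] - mean(cov[[v]])))
    expect_lt(max(r), 1e-10)
  }
  r_sex <- abs(cor(corrected, as.numeric(cov$sex == "M")))
  expect_lt(max(r_sex), 1e-10)

  # all-zero coefficients: identity transform
  m0 <- m
  m0$coefficients[] <- 0
  expect_equal(residualize(m0, edges, cov), edges)

  # idempotence: refitting on residualized data gives ~zero coefficients
  m2 <- fit_edgewise_model(corrected, cov)
  expect_lt(max(abs(m2$coefficients[-1, ])), 1e-8)

  # disease offset not in the design survives HC-only residualization
  cov_d <- make_cov(120, seed = 11)
  cov_d$diagnosis <- rep(c("HC", "PAT"), each = 60)
  edges_d <- make_linear_edges(cov_d, 100,
                               withr::with_seed(12, matrix(rnorm(500, 0, .02),
                                                           5, 100)),
                               seed = 13) +
    withr::with_seed(14, matrix(rnorm(120 * 100, 0, 0.01), 120, 100))
  hit <- 1:50
  edges_d[cov_d$diagnosis == "PAT", hit] <-
    edges_d[cov_d$diagnosis == "PAT", hit] + 0.05
  m_hc <- fit_edgewise_model(edges_d, cov_d,
                             fit_subset = cov_d$scan_id[cov_d$diagnosis == "HC"])
  # leakage guard: no patient in the fit subset
  expect_length(intersect(m_hc$fit_scan_ids,
                          cov_d$scan_id[cov_d$diagnosis == "PAT"]), 0)
  corr_d <- residualize(m_hc, edges_d, cov_d)
  diffs <- colMeans(corr_d[cov_d$diagnosis == "PAT", hit]) -
    colMeans(corr_d[cov_d$diagnosis == "HC", hit])
  expect_lt(abs(mean(diffs) - 0.05) / 0.05, 0.10)
})

test_that("summarize_effect: spot value, null CI, degeneracy", {
  fake <- function(betas) {
    structure(list(spec = list(standardized = TRUE),
                   coefficients = rbind(`(Intercept)` = 0, b = betas)),
              class = "harmonization_model")
  }
  eff <- summarize_effect(fake(c(1, 2, 3)), "b", n_boot = 100, seed = 1)
  expect_equal(eff$d, 2)

  sym <- withr::with_seed(2, rnorm(500))
  eff0 <- summarize_effect(fake(sym), "b", n_boot = 1000, seed = 3)
  expect_lt(abs(eff0$d), 0.15)
  expect_lt(eff0$ci[1], 0)
  expect_gt(eff0$ci[2], 0)

  expect_error(summarize_effect(fake(rep(1, 10)), "b"),
               "degenerate beta distribution")
  # standardized-fit requirement
  m <- fake(1:3); m$spec$standardized <- FALSE
  expect_error(summarize_effect(m, "b"), "standardized = TRUE")
})

test_that("standardized fit produces standardized betas and a sane d", {
  ec <- simulate_edge_cohort(n_regions = 12, groups = c(HC = 80),
                             covariate_coefs = list(sex_M = 0.03),
                             noise_sd = 0.02, seed = 21)
  m <- fit_edgewise_model(ec$edges, ec$covariates,
                          design = c("sex", "age"), standardized = TRUE)
  eff <- summarize_effect(m, "sex", n_boot = 500, seed = 4)
  expect_gt(eff$d, 0)        # injected positive male effect
  expect_gt(eff$ci[1], 0)
})

test_that("harmonization model serializes and round-trips", {
  cov <- make_cov(40)
  edges <- make_linear_edges(cov, 20,
                             withr::with_seed(1, matrix(rnorm(100, 0, .02),
                                                        5, 20)))
  m <- fit_edgewise_model(edges, cov)
  stem <- file.path(withr::local_tempdir(), "model")
  write_harmonization_model(m, stem)
  m2 <- read_harmonization_model(stem)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(residualize(m2, edges, cov), residualize(m, edges, cov),
               tolerance = 1e-12)
})
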
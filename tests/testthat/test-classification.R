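test_that("perfectly separable toy data give AP = AUC = 1", {
  # disjoint edge supports: positives load on edges 1:10, controls on 11:20
  n <- 40
  reg <- subset_registry(10)
  E <- length(edge_labels(reg))
  edges <- withr::with_seed(1, matrix(rnorm(n * E, 0, 0.05), n, E,
    dimnames = list(sprintf("s%02d", 1:n), edge_labels(reg))))
  lab <- rep(c("HC", "DIS"), each = n / 2)
  edges[lab == "DIS", 1:10] <- edges[lab == "DIS", 1:10] + 2
  rep_ <- classify_disease_binary(edges, lab, covariates = NULL,
                                  config = fast_config(), seed = 3)
  expect_equal(rep_$ap, 1)
  expect_equal(rep_$auc, 1)
  expect_true(all(rep_$ap_ci == 1))
  expect_equal(rep_$ap_chance, mean(lab[match(rep_$test_ids,
                                              rownames(edges))] == "DIS"))
})

test_that("binary classifier validates inputs", {
  edges <- matrix(rnorm(60), 10, 6,
                  dimnames = list(paste0("s", 1:10), paste0("a|b", 1:6)))
  expect_error(classify_disease_binary(edges, rep("HC", 10)),
               "exactly 2 classes")
  expect_error(classify_disease_binary(edges, c(rep("HC", 9), "D")),
               "at least 2 positive")
})

test_that("no leakage: test rows never influence fit or hyperparameters", {
  ec <- simulate_edge_cohort(n_regions = 12, groups = c(HC = 24, DIS = 24),
                             affected_edges = list(DIS = 1:15),
                             effect_size = 2, noise_sd = 0.02, seed = 5)
  cfg <- fast_config()
  r1 <- classify_disease_binary(ec$edges, ec$covariates$diagnosis,
                                ec$covariates, cfg, seed = 11)
  # perturb only test rows; split depends on labels + seed so is unchanged
  edges2 <- ec$edges
  edges2[r1$test_ids, ] <- edges2[r1$test_ids, ] +
    withr::with_seed(1, matrix(rnorm(length(r1$test_ids) * ncol(edges2)),
                               length(r1$test_ids)))
  # harmonization must also ignore test rows: restrict to HC-train fitting
  r2 <- classify_disease_binary(edges2, ec$covariates$diagnosis,
                                ec$covariates, cfg, seed = 11)
  expect_identical(r2$test_ids, r1$test_ids)
  expect_equal(r2$lambda, r1$lambda)
  expect_equal(r2$coefficients, r1$coefficients, tolerance = 1e-10)
})

test_that("regional importance: spot values and conservation", {
  beta <- c("A|B" = 0.5, "A|C" = -0.25, "B|C" = 0)
  sc <- regional_importance(beta)
  expect_equal(unname(sc[c("A", "B", "C")]), c(0.75, 0.5, 0.25))

  expect_true(all(regional_importance(beta * 0) == 0))

  reg <- build_default_registry()
  b <- withr::with_seed(7, rnorm(3741))
  names(b) <- edge_labels(reg)
  sc2 <- regional_importance(b, reg)
  expect_lt(abs(sum(sc2) - 2 * sum(abs(b))), 1e-12)
  expect_identical(names(sc2), reg$name)
})

test_that("coefficient overlap: identity, inversion, sparse null", {
  b <- withr::with_seed(8, rnorm(100))
  expect_equal(coefficient_overlap(b, b)$estimate, 1)
  expect_equal(coefficient_overlap(b, -b)$estimate, -1)
  expect_error(coefficient_overlap(b, b[1:10]), "equal length")

  small <- vapply(1:30, function(s) {
    withr::with_seed(s, {
      E <- 3741
      b1 <- b2 <- numeric(E)
      nz <- round(0.05 * E)
      b1[sample(E, nz)] <- rnorm(nz)
      b2[sample(E, nz)] <- rnorm(nz)
      abs(coefficient_overlap(b1, b2)$estimate)
    })
  }, numeric(1))
  expect_gte(mean(small < 0.05), 0.9)
})

test_that("multiclass classifier separates well-separated groups", {
  reg <- subset_registry(12)
  E <- length(edge_labels(reg))
  n_per <- 12
  groups <- paste0("G", 1:5)
  lab <- rep(groups, each = n_per)
  edges <- withr::with_seed(9, matrix(rnorm(60 * E, 0, 0.05), 60, E,
    dimnames = list(sprintf("s%02d", 1:60), edge_labels(reg))))
  for (g in seq_along(groups)) {
    idx <- ((g - 1) * 10 + 1):(g * 10)
    edges[lab == groups[g], idx] <- edges[lab == groups[g], idx] + 2
  }
  mc <- classify_multiclass(edges, lab, covariates = NULL,
                            config = fast_config(), seed = 2)
  expect_equal(mc$balanced_accuracy, 1)
  expect_true(all(diag(as.matrix(mc$confusion)) == rowSums(mc$confusion)))
})

test_that("patient fingerprinting: duplicates, chance level, invariance", {
  E <- 200
  a <- withr::with_seed(10, runif(E)); b <- withr::with_seed(11, runif(E))
  edges <- rbind(a, a, a, b, b, b) +
    withr::with_seed(12, matrix(rnorm(6 * E, 0, 1e-4), 6, E))
  rownames(edges) <- paste0("p", 1:6)
  lab <- rep(c("G1", "G2"), each = 3)
  fp <- patient_fingerprint(edges, lab)
  expect_equal(fp$balanced_accuracy, 1)
  expect_true(all(fp$recall == 1))
  expect_equal(sum(fp$confusion), 6)
  expect_equal(as.numeric(rowSums(fp$confusion)),
               as.numeric(table(lab)))

  # balanced accuracy invariant under a monotone transform of all vectors
  fp2 <- patient_fingerprint(exp(3 * edges), lab)
  expect_equal(fp2$balanced_accuracy, fp$balanced_accuracy)

  expect_error(patient_fingerprint(edges, rep("G1", 6)), ">= 2 diagnostic")
})

test_that("predict_covariate: batch signal detected, single class rejected", {
  ec <- simulate_edge_cohort(n_regions = 12, groups = c(HC = 60),
                             batches = c("A", "B"),
                             batch_scale = c(A = 1, B = 1.1),
                             noise_sd = 0.02, seed = 14)
  pv <- predict_covariate(ec$edges, "batch", ec$covariates,
                          config = fast_config(), seed = 15)
  expect_gt(pv$balanced_accuracy, 0.9)

  cov1 <- ec$covariates
  cov1$batch <- "A"
  expect_error(predict_covariate(ec$edges, "batch", cov1,
                                 config = fast_config()),
               "single class")
})

test_that("predict_covariate on a null target stays near chance", {
  ec <- simulate_edge_cohort(n_regions = 10, groups = c(HC = 60),
                             noise_sd = 0.02, seed = 16)
  pv <- predict_covariate(ec$edges, "sex", ec$covariates,
                          config = fast_config(), seed = 17)
  # no injected sex effect: balanced accuracy should sit near 0.5
  expect_lt(pv$balanced_accuracy, 0.75)
  expect_gt(pv$balanced_accuracy, 0.25)
})
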
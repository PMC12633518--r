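# Disease and covariate classification on network edge vectors, regional
# importance scoring, coefficient overlap across tasks, and individual-level
# diagnostic fingerprinting.
#
# Leakage discipline: the train/test split happens first; harmonization is
# fitted on healthy-control training rows only; feature z-scoring and
# penalty selection see training rows only. Everything downstream of the
# split is a deterministic function of the training data and the run seed.

#' Classification settings
#'
#' @param n_repeats repeats of the stratified k-fold CV (default 10)
#' @param n_folds folds (default 10; automatically reduced so every fold
#'   holds at least one positive)
#' @param lambda_grid L1 penalty grid (default 15 log-spaced values in
#'   [1e-3, 1e2]); ties in CV score go to the stronger penalty
#' @param n_boot bootstrap resamples of the test set for CIs (default 1000)
#' @param train_frac training fraction of the stratified split (default 0.7)
#' @param conf confidence level for bootstrap CIs
#' @param hc_label label identifying healthy controls (harmonization fit
#'   subset)
#' @param harmonization_design covariates removed before classification;
#'   NULL disables harmonization
#' @return a config list
#' @export
classification_config <- function(n_repeats = 10, n_folds = 10,
                                  lambda_grid = 10^seq(-3, 2,
                                                       length.out = 15),
                                  n_boot = 1000, train_frac = 0.7,
                                  conf = 0.95, hc_label = "HC",
                                  harmonization_design = c("batch", "sex",
                                                           "genotype", "age",
                                                           "dw")) {
  list(n_repeats = n_repeats, n_folds = n_folds,
       lambda_grid = sort(lambda_grid, decreasing = TRUE),
       n_boot = n_boot, train_frac = train_frac, conf = conf,
       hc_label = hc_label, harmonization_design = harmonization_design)
}

# Repeated stratified CV over the lambda grid; returns mean score per lambda
# (AP for binary, balanced accuracy for multinomial). Called inside a seed
# context.
.cv_lambda <- function(x, y, config, family = "binomial") {
  lam <- config$lambda_grid
  n_pos <- if (family == "binomial") sum(y == 1) else min(table(y))
  n_folds <- max(2, min(config$n_folds, n_pos))
  scores <- matrix(NA_real_, nrow = config$n_repeats * n_folds,
                   ncol = length(lam))
  row <- 0
  for (rep_i in seq_len(config$n_repeats)) {
    fold <- .stratified_folds(y, n_folds)
    for (f in seq_len(n_folds)) {
      row <- row + 1
      tr <- fold != f
      te <- !tr
      if (family == "binomial" && (sum(y[te] == 1) == 0 ||
                                   length(unique(y[tr])) < 2)) next
      # small folds trip glmnet's class-size warning by construction
      fit <- suppressWarnings(
        glmnet::glmnet(x[tr, , drop = FALSE],
                       if (family == "binomial") y[tr] else factor(y[tr]),
                       family = family, alpha = 1, lambda = lam,
                       standardize = FALSE))
      if (family == "binomial") {
        pr <- stats::predict(fit, x[te, , drop = FALSE], s = lam,
                             type = "response")
        scores[row, seq_len(ncol(pr))] <-
          apply(pr, 2, average_precision, labels = y[te])
      } else {
        pr <- stats::predict(fit, x[te, , drop = FALSE], s = lam,
                             type = "class")
        scores[row, seq_len(ncol(pr))] <- apply(pr, 2, function(cl) {
          confusion_report(y[te], cl)$balanced_accuracy
        })
      }
    }
  }
  colMeans(scores, na.rm = TRUE)
}

# Pick lambda maximizing the CV score; ties to the stronger penalty (grid is
# stored in decreasing order, so the first maximum wins).
.pick_lambda <- function(cv_scores, lambda_grid) {
  lambda_grid[which.max(cv_scores)]
}

# Bootstrap percentile CI of metric(scores[idx], labels[idx]) over test rows.
.bootstrap_ci <- function(metric, scores, labels, n_boot, conf, seed) {
  n <- length(labels)
  alpha <- (1 - conf) / 2
  boots <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(scores[idx], labels[idx])
  }, numeric(1)))
  unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
}

# Shared front end: split, HC-only harmonization, train z-scoring.
.prepare_split <- function(edge_table, labels, covariates, config, seed) {
  split <- .with_seed(seed, .stratified_split(labels, config$train_frac))
  tr <- split$train
  te <- split$test
  if (length(unique(labels[tr])) < 2 || length(unique(labels[te])) < 2) {
    stop("a class is absent from the train or test split; try another seed")
  }
  x <- edge_table
  harm <- NULL
  if (!is.null(covariates) && !is.null(config$harmonization_design)) {
    hc_train <- rownames(edge_table)[tr][labels[tr] == config$hc_label]
    fit_ids <- if (length(hc_train) > 0) hc_train else rownames(edge_table)[tr]
    # drop covariates that are degenerate on the fit subset (e.g. a single
    # batch); fit_edgewise_model stays strict when called directly
    cov_fit <- covariates[match(fit_ids, covariates$scan_id), , drop = FALSE]
    design <- intersect(config$harmonization_design,
                        .usable_covariates(cov_fit))
    design <- .coverable_design(design, cov_fit, covariates)
    design <- .shed_design(design, cov_fit)
    if (length(design) > 0) {
      harm <- fit_edgewise_model(edge_table, covariates,
                                 fit_subset = fit_ids, design = design)
      x <- residualize(harm, edge_table, covariates)
    }
  }
  zs <- .train_zscore(x[tr, , drop = FALSE], x[te, , drop = FALSE])
  list(train_idx = tr, test_idx = te, x_train = zs$train, x_test = zs$test,
       harmonization = harm)
}

#' Binary disease classification with L1 logistic regression
#'
#' Full pipeline: stratified 70/30 split; edgewise confound models fitted on
#' healthy controls of the training set only and applied to all scans;
#' train-set z-scoring; L1-regularized logistic regression with the penalty
#' chosen by repeated stratified 10-fold cross-validation maximizing mean
#' average precision (fold count reduced so each fold holds a positive);
#' refit on the training set; test-set AP and ROC AUC with percentile
#' bootstrap confidence intervals.
#'
#' @param edge_table scans x edges matrix (rownames = scan ids, colnames =
#'   `"roi_i|roi_j"` edge labels)
#' @param labels diagnosis label per scan; the positive class is everything
#'   different from `config$hc_label` (exactly 2 distinct labels required)
#' @param covariates covariate data.frame (see [scan_covariates()]) or NULL
#'   to skip harmonization
#' @param config a [classification_config()]
#' @param seed integer run seed (drives split, CV and bootstrap)
#' @return a `classifier_report`: test AP + CI, chance level (test-set
#'   positive prevalence), ROC AUC + CI, chosen lambda, per-edge
#'   coefficients, per-ROI importance, test scores and indices
#' @export
classify_disease_binary <- function(edge_table, labels, covariates = NULL,
                                    config = classification_config(),
                                    seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("need exactly 2 classes, got ",
                                 length(classes))
  positive <- setdiff(classes, config$hc_label)
  if (length(positive) != 1) positive <- sort(classes)[2]
  y <- as.numeric(labels == positive)
  if (sum(y) < 2) stop("need at least 2 positive-class scans")
  seeds <- .child_seeds(seed, 4)

  prep <- .prepare_split(edge_table, labels, covariates, config, seeds[1])
  y_tr <- y[prep$train_idx]
  y_te <- y[prep$test_idx]
  if (sum(y_tr) < 2 || sum(y_tr == 0) < 2) {
    stop("fewer than 2 scans of a class in the training split; ",
         "the cohort is too small for a 70/30 split")
  }

  cv <- .with_seed(seeds[2],
                   .cv_lambda(prep$x_train, y_tr, config, "binomial"))
  lambda <- .pick_lambda(cv, config$lambda_grid)
  fit <- suppressWarnings(
    glmnet::glmnet(prep$x_train, y_tr, family = "binomial", alpha = 1,
                   lambda = config$lambda_grid, standardize = FALSE))
  beta <- as.numeric(stats::coef(fit, s = lambda))[-1]
  names(beta) <- colnames(edge_table)
  scores <- as.numeric(stats::predict(fit, prep$x_test, s = lambda,
                                      type = "response"))
  ap <- average_precision(scores, y_te)
  auc <- roc_auc(scores, y_te)
  structure(list(
    task = paste(positive, "vs", config$hc_label),
    positive_class = positive,
    ap = ap,
    ap_ci = .bootstrap_ci(average_precision, scores, y_te,
                          config$n_boot, config$conf, seeds[3]),
    ap_chance = mean(y_te),
    auc = auc,
    auc_ci = .bootstrap_ci(roc_auc, scores, y_te,
                           config$n_boot, config$conf, seeds[4]),
    lambda = lambda, cv_scores = cv,
    coefficients = beta,
    importance = regional_importance(beta),
    test_scores = scores, test_labels = y_te,
    train_ids = rownames(edge_table)[prep$train_idx],
    test_ids = rownames(edge_table)[prep$test_idx],
    harmonization = prep$harmonization
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>", x$task, "\n",
      sprintf("  test AP %.3f [%.3f, %.3f] (chance %.3f); ROC AUC %.3f [%.3f, %.3f]\n",
              x$ap, x$ap_ci[1], x$ap_ci[2], x$ap_chance,
              x$auc, x$auc_ci[1], x$auc_ci[2]),
      sprintf("  lambda %.4g; %d nonzero edges\n", x$lambda,
              sum(x$coefficients != 0)))
  invisible(x)
}

#' Multiclass disease classification
#'
#' Same leakage-safe pipeline as [classify_disease_binary()] but with a
#' multinomial L1 logistic regression; the penalty is chosen by repeated
#' stratified CV maximizing mean balanced accuracy, and test-set balanced
#' accuracy is reported with a bootstrap CI and the confusion matrix.
#'
#' @inheritParams classify_disease_binary
#' @param group_labels class label per scan (>= 2 classes)
#' @return list: balanced accuracy + CI, confusion matrix, per-group recall,
#'   chosen lambda, per-class coefficient matrix
#' @export
classify_multiclass <- function(edge_table, group_labels, covariates = NULL,
                                config = classification_config(),
                                seed = 1L) {
  labels <- as.character(group_labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  seeds <- .child_seeds(seed, 3)
  prep <- .prepare_split(edge_table, labels, covariates, config, seeds[1])
  y_tr <- labels[prep$train_idx]
  y_te <- labels[prep$test_idx]

  cv <- .with_seed(seeds[2],
                   .cv_lambda(prep$x_train, y_tr, config, "multinomial"))
  lambda <- .pick_lambda(cv, config$lambda_grid)
  fit <- suppressWarnings(
    glmnet::glmnet(prep$x_train, factor(y_tr), family = "multinomial",
                   alpha = 1, lambda = config$lambda_grid,
                   standardize = FALSE))
  pred <- as.character(stats::predict(fit, prep$x_test, s = lambda,
                                      type = "class"))
  rep_ <- confusion_report(y_te, pred)
  n_te <- length(y_te)
  alpha <- (1 - config$conf) / 2
  boots <- .with_seed(seeds[3], vapply(seq_len(config$n_boot), function(b) {
    idx <- sample.int(n_te, n_te, replace = TRUE)
    confusion_report(y_te[idx], pred[idx])$balanced_accuracy
  }, numeric(1)))
  coefs <- lapply(stats::coef(fit, s = lambda), function(m) {
    v <- as.numeric(m)[-1]
    names(v) <- colnames(edge_table)
    v
  })
  list(balanced_accuracy = rep_$balanced_accuracy,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       confusion = rep_$confusion, recall = rep_$recall,
       lambda = lambda, coefficients = coefs,
       test_ids = rownames(edge_table)[prep$test_idx])
}

#' Predict a technical/biological covariate from network edges
#'
#' Measures how strongly a covariate (batch, sex, genotype) is encoded in
#' the networks. The other covariates are regressed out first; then a
#' stratified 70/30 split, grid search by 10-fold CV on balanced accuracy
#' over elastic-net logistic regression and k-nearest-neighbour models, and
#' the best model's test balanced accuracy with a bootstrap CI. (SVMs are
#' not available in this environment.)
#'
#' @inheritParams classify_disease_binary
#' @param target one of `"batch"`, `"sex"`, `"genotype"`
#' @param covariates covariate data.frame (used for the target labels and
#'   the pre-residualization design)
#' @param enet_alpha elastic-net mixing grid
#' @param knn_k KNN neighbourhood grid
#' @return list: best model label, test balanced accuracy + CI, CV table
#' @export
predict_covariate <- function(edge_table, target, covariates,
                              config = classification_config(),
                              enet_alpha = c(0.1, 0.5, 0.9),
                              knn_k = c(3, 5, 7, 9, 11),
                              seed = 1L) {
  stopifnot(target %in% c("batch", "sex", "genotype"))
  covariates <- covariates[match(rownames(edge_table), covariates$scan_id), ,
                           drop = FALSE]
  labels <- as.character(covariates[[target]])
  if (length(unique(labels)) < 2) {
    stop("target '", target, "' has a single class")
  }
  # residualize for the other covariates (batch prediction: remove
  # sex/genotype/age/dw; sex or genotype prediction: remove batch first)
  others <- if (target == "batch") c("sex", "genotype", "age", "dw")
            else "batch"
  others <- others[vapply(others, function(v) {
    length(unique(stats::na.omit(as.character(covariates[[v]])))) >= 2
  }, logical(1))]
  x <- edge_table
  if (length(others) > 0) {
    m <- fit_edgewise_model(edge_table, covariates, design = others)
    x <- residualize(m, edge_table, covariates)
  }
  seeds <- .child_seeds(seed, 3)
  split <- .with_seed(seeds[1], .stratified_split(labels, config$train_frac))
  tr <- split$train; te <- split$test
  if (length(unique(labels[tr])) < 2 || length(unique(labels[te])) < 2) {
    stop("a class is absent from the train or test split; try another seed")
  }
  zs <- .train_zscore(x[tr, , drop = FALSE], x[te, , drop = FALSE])
  y_tr <- labels[tr]; y_te <- labels[te]
  binary <- length(unique(labels)) == 2
  fam <- if (binary) "binomial" else "multinomial"

  grid <- list()
  for (a in enet_alpha) grid[[paste0("enet_a", a)]] <- list(type = "enet", alpha = a)
  for (k in knn_k) grid[[paste0("knn_k", k)]] <- list(type = "knn", k = k)

  cv_tab <- .with_seed(seeds[2], {
    n_folds <- max(2, min(config$n_folds, min(table(y_tr))))
    fold <- .stratified_folds(y_tr, n_folds)
    vapply(grid, function(g) {
      accs <- vapply(seq_len(n_folds), function(f) {
        itr <- fold != f
        if (length(unique(y_tr[itr])) < 2) return(NA_real_)
        pred <- if (g$type == "enet") {
          fit <- glmnet::glmnet(zs$train[itr, , drop = FALSE],
                                factor(y_tr[itr]), family = fam,
                                alpha = g$alpha,
                                lambda = config$lambda_grid,
                                standardize = FALSE)
          # inner selection: median of the path by deviance is overkill
          # here; score each lambda and take the best fold-wise
          pr <- stats::predict(fit, zs$train[!itr, , drop = FALSE],
                               s = config$lambda_grid, type = "class")
          best <- which.max(apply(pr, 2, function(cl)
            confusion_report(y_tr[!itr], cl)$balanced_accuracy))
          pr[, best]
        } else {
          .knn_predict(zs$train[itr, , drop = FALSE], y_tr[itr],
                       zs$train[!itr, , drop = FALSE], g$k)
        }
        confusion_report(y_tr[!itr], pred)$balanced_accuracy
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
  })
  best_name <- names(grid)[which.max(cv_tab)]
  g <- grid[[best_name]]
  if (g$type == "enet") {
    # lambda by single-pass stratified CV scoring balanced accuracy
    cv_l <- .with_seed(seeds[2], {
      n_folds <- max(2, min(config$n_folds, min(table(y_tr))))
      fold <- .stratified_folds(y_tr, n_folds)
      sc <- matrix(NA_real_, n_folds, length(config$lambda_grid))
      for (f in seq_len(n_folds)) {
        itr <- fold != f
        if (length(unique(y_tr[itr])) < 2) next
        fit_f <- glmnet::glmnet(zs$train[itr, , drop = FALSE],
                                factor(y_tr[itr]), family = fam,
                                alpha = g$alpha, lambda = config$lambda_grid,
                                standardize = FALSE)
        pr <- stats::predict(fit_f, zs$train[!itr, , drop = FALSE],
                             s = config$lambda_grid, type = "class")
        sc[f, seq_len(ncol(pr))] <- apply(pr, 2, function(cl)
          confusion_report(y_tr[!itr], cl)$balanced_accuracy)
      }
      colMeans(sc, na.rm = TRUE)
    })
    lam <- .pick_lambda(cv_l, config$lambda_grid)
    fit <- glmnet::glmnet(zs$train, factor(y_tr), family = fam,
                          alpha = g$alpha, lambda = config$lambda_grid,
                          standardize = FALSE)
    pred <- as.character(stats::predict(fit, zs$test, s = lam,
                                        type = "class"))
  } else {
    pred <- .knn_predict(zs$train, y_tr, zs$test, g$k)
  }
  rep_ <- confusion_report(y_te, pred)
  n_te <- length(y_te)
  alpha_q <- (1 - config$conf) / 2
  boots <- .with_seed(seeds[3], vapply(seq_len(config$n_boot), function(b) {
    idx <- sample.int(n_te, n_te, replace = TRUE)
    confusion_report(y_te[idx], pred[idx])$balanced_accuracy
  }, numeric(1)))
  list(target = target, best_model = best_name,
       balanced_accuracy = rep_$balanced_accuracy,
       ci = unname(stats::quantile(boots, c(alpha_q, 1 - alpha_q))),
       cv_scores = cv_tab, confusion = rep_$confusion)
}

#' Regional importance scores from per-edge coefficients
#'
#' The importance of a region is the sum of |beta| over all edges touching
#' it, so the scores conserve 2 * sum(|beta|) overall.
#'
#' @param per_edge_coefficients named numeric vector, names `"roi_i|roi_j"`
#' @param registry optional `roi_registry` fixing the output order (regions
#'   absent from any edge get score 0)
#' @return named numeric vector of per-region scores
#' @export
regional_importance <- function(per_edge_coefficients, registry = NULL) {
  if (is.null(names(per_edge_coefficients))) {
    stop("coefficients must be named by edge ('roi_i|roi_j')")
  }
  parts <- strsplit(names(per_edge_coefficients), "|", fixed = TRUE)
  roi_i <- vapply(parts, `[`, "", 1)
  roi_j <- vapply(parts, `[`, "", 2)
  ab <- abs(per_edge_coefficients)
  agg <- tapply(c(ab, ab), c(roi_i, roi_j), sum)
  rois <- if (!is.null(registry)) registry$name else sort(unique(c(roi_i, roi_j)))
  out <- stats::setNames(rep(0, length(rois)), rois)
  out[names(agg)] <- as.numeric(agg)
  out
}

#' Overlap between two tasks' coefficient vectors
#'
#' Rank correlation (Kendall's tau by default) between the per-edge
#' coefficients of two classification tasks: low values indicate distinct,
#' disease-specific discriminative patterns.
#'
#' @param beta_task1,beta_task2 equal-length coefficient vectors
#' @param method `"kendall"` (default) or `"spearman"`
#' @return list: `estimate`, `p_value`, `method`
#' @export
coefficient_overlap <- function(beta_task1, beta_task2,
                                method = c("kendall", "spearman")) {
  method <- match.arg(method)
  if (length(beta_task1) != length(beta_task2)) {
    stop("coefficient vectors must have equal length")
  }
  ct <- suppressWarnings(stats::cor.test(beta_task1, beta_task2,
                                         method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method)
}

#' Individual-level diagnostic fingerprinting
#'
#' Each patient is assigned the diagnosis of the other patient with whom
#' they share the highest Spearman correlation between edge vectors (self
#' excluded). Optionally the edges are residualized with a harmonization
#' model first (the uncorrected variant is the sensitivity analysis).
#'
#' @param edge_table_patients scans x edges matrix of patient scans
#' @param diagnoses diagnosis label per scan
#' @param harmonization_model optional fitted `harmonization_model`
#' @param covariates required when a model is supplied
#' @return a `fingerprint_report`: Spearman matrix, assigned labels,
#'   confusion matrix, balanced accuracy, per-group recall
#' @export
patient_fingerprint <- function(edge_table_patients, diagnoses,
                                harmonization_model = NULL,
                                covariates = NULL) {
  diagnoses <- as.character(diagnoses)
  if (length(unique(diagnoses)) < 2) stop("need >= 2 diagnostic groups")
  x <- edge_table_patients
  if (!is.null(harmonization_model)) {
    if (is.null(covariates)) stop("covariates required with a model")
    x <- residualize(harmonization_model, x, covariates)
  }
  rho <- stats::cor(t(x), method = "spearman")
  diag(rho) <- -Inf
  nn <- apply(rho, 1, which.max)
  assigned <- diagnoses[nn]
  rep_ <- confusion_report(diagnoses, assigned)
  structure(list(rho = rho, assigned = assigned,
                 confusion = rep_$confusion,
                 balanced_accuracy = rep_$balanced_accuracy,
                 recall = rep_$recall),
            class = "fingerprint_report")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat("<fingerprint_report> balanced accuracy",
      sprintf("%.3f", x$balanced_accuracy), "\n")
  print(x$confusion)
  invisible(x)
}
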
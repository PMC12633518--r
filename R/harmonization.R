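# Edgewise linear confound models. One OLS fit per network edge against
# batch / sex / genotype / age / dose-per-weight, fitted on a designated
# subset (healthy controls of the training set in the disease pipeline) and
# applied to everyone — the linear analogue of site harmonization that
# preserves disease-related variance by construction.

# Build the design matrix for a covariate data.frame given a design spec.
# Factors are dummy-coded against an alphabetical reference level; continuous
# covariates are centered on the fit subset.
.build_design <- function(covariates, spec) {
  n <- nrow(covariates)
  cols <- list(`(Intercept)` = rep(1, n))
  for (f in names(spec$factors)) {
    lev <- spec$factors[[f]]
    x <- as.character(covariates[[f]])
    if (any(is.na(x))) stop("covariate '", f, "' has missing values")
    unknown <- setdiff(unique(x), lev)
    if (length(unknown) > 0) {
      stop("covariate '", f, "' has level(s) not seen at fit time: ",
           paste(unknown, collapse = ", "))
    }
    for (l in lev[-1]) cols[[paste0(f, "_", l)]] <- as.numeric(x == l)
  }
  for (v in names(spec$centers)) {
    x <- covariates[[v]]
    if (any(!is.finite(x))) stop("covariate '", v, "' has non-finite values")
    cols[[v]] <- x - spec$centers[[v]]
  }
  do.call(cbind, cols)
}

# Drop trailing covariates until the fit subset can support the design
# (n >= design columns + 2); warns for each dropped covariate. Used by the
# pipeline-level callers; fit_edgewise_model itself stays strict.
.shed_design <- function(design, cov_fit) {
  n_cols <- function(d) {
    1L + sum(vapply(d, function(v) {
      if (v %in% c("batch", "sex", "genotype", "tracer", "diagnosis")) {
        length(unique(as.character(cov_fit[[v]]))) - 1L
      } else 1L
    }, integer(1)))
  }
  while (length(design) > 0 && nrow(cov_fit) < n_cols(design) + 2) {
    warning("harmonization fit subset (", nrow(cov_fit),
            " scans) too small for covariate '", design[length(design)],
            "'; dropping it", call. = FALSE)
    design <- design[-length(design)]
  }
  design
}

# Drop factor covariates whose fit-subset levels do not cover the levels
# present in the full table (a level unseen at fit time cannot be corrected).
.coverable_design <- function(design, cov_fit, cov_all) {
  keep <- vapply(design, function(v) {
    if (!v %in% c("batch", "sex", "genotype", "tracer", "diagnosis")) {
      return(TRUE)
    }
    ok <- all(unique(as.character(cov_all[[v]])) %in%
                unique(as.character(cov_fit[[v]])))
    if (!ok) {
      warning("covariate '", v, "' has levels absent from the ",
              "harmonization fit subset; dropping it", call. = FALSE)
    }
    ok
  }, logical(1))
  design[keep]
}

#' Fit edgewise linear confound models
#'
#' Ordinary least squares of every edge on the requested covariates, fitted
#' only on `fit_subset` (typically healthy controls of a training split, so
#' patient rows never inform the correction). Factor covariates are one-hot
#' coded against the alphabetically first level; continuous covariates are
#' centered on the fit subset.
#'
#' @param edge_table scans x edges matrix, rownames = scan ids
#' @param covariates data.frame with column `scan_id` plus the covariate
#'   columns (see [scan_covariates()]); `dw` is dose/weight
#' @param fit_subset scan ids to fit on (default: all rows)
#' @param design character vector of covariate names; names present in
#'   `c("batch", "sex", "genotype", "tracer", "diagnosis")` are treated as
#'   factors, the rest as continuous
#' @param standardized if TRUE, edges and continuous predictors are z-scored
#'   on the fit subset before fitting, so coefficients are standardized
#'   betas (for [summarize_effect()]); residualization should use the
#'   default FALSE
#' @return a `harmonization_model`: design spec, scans used, and the
#'   (design columns) x (edges) coefficient matrix
#' @export
fit_edgewise_model <- function(edge_table, covariates,
                               fit_subset = rownames(edge_table),
                               design = c("batch", "sex", "genotype",
                                          "age", "dw"),
                               standardized = FALSE) {
  stopifnot(!is.null(rownames(edge_table)))
  covariates <- covariates[match(rownames(edge_table), covariates$scan_id), ,
                           drop = FALSE]
  if (any(is.na(covariates$scan_id))) {
    stop("covariates missing for some scans in the edge table")
  }
  fit_idx <- match(fit_subset, rownames(edge_table))
  if (any(is.na(fit_idx))) stop("fit_subset contains unknown scan ids")
  cov_fit <- covariates[fit_idx, , drop = FALSE]

  factor_like <- c("batch", "sex", "genotype", "tracer", "diagnosis")
  spec <- list(factors = list(), centers = list(), scales = list(),
               design = design, standardized = standardized)
  for (v in design) {
    if (!v %in% names(covariates)) stop("unknown covariate '", v, "'")
    if (v %in% factor_like) {
      lev <- sort(unique(as.character(cov_fit[[v]])))
      if (length(lev) < 2) {
        stop("rank-deficient design: covariate '", v,
             "' has a single level on the fit subset")
      }
      spec$factors[[v]] <- lev
    } else {
      spec$centers[[v]] <- mean(cov_fit[[v]])
      if (standardized) {
        s <- stats::sd(cov_fit[[v]])
        if (s == 0) stop("rank-deficient design: covariate '", v,
                         "' is constant on the fit subset")
        spec$scales[[v]] <- s
      }
    }
  }
  X <- .build_design(cov_fit, spec)
  if (standardized) {
    for (v in names(spec$scales)) X[, v] <- X[, v] / spec$scales[[v]]
  }
  if (nrow(X) < ncol(X) + 2) {
    stop("fit subset too small: ", nrow(X), " scans for ", ncol(X),
         " design columns")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- edge_table[fit_idx, , drop = FALSE]
  if (standardized) {
    mu <- colMeans(Y)
    sdv <- apply(Y, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Y <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
  }
  B <- qr.coef(qrX, Y)
  rownames(B) <- colnames(X)
  structure(list(spec = spec, coefficients = B, fit_scan_ids = fit_subset),
            class = "harmonization_model")
}

#' Remove fitted covariate effects from an edge table
#'
#' Corrected value = observed - (fitted covariate effects); the intercept is
#' retained so corrected edges remain on the similarity scale. Covariate
#' levels unseen at fit time are an error.
#'
#' @param model a `harmonization_model` (fitted with `standardized = FALSE`)
#' @param edge_table scans x edges matrix
#' @param covariates covariate data.frame covering all scans
#' @return corrected edge table of the same shape
#' @export
residualize <- function(model, edge_table, covariates) {
  if (isTRUE(model$spec$standardized)) {
    stop("residualize requires a model fitted with standardized = FALSE")
  }
  covariates <- covariates[match(rownames(edge_table), covariates$scan_id), ,
                           drop = FALSE]
  if (any(is.na(covariates$scan_id))) {
    stop("covariates missing for some scans in the edge table")
  }
  X <- .build_design(covariates, model$spec)
  B <- model$coefficients
  keep <- setdiff(rownames(B), "(Intercept)")
  corrected <- edge_table - X[, keep, drop = FALSE] %*% B[keep, , drop = FALSE]
  dimnames(corrected) <- dimnames(edge_table)
  corrected
}

#' Cohen's d summary of a covariate's edgewise effect
#'
#' Quantifies whether a covariate's effect on similarity values is
#' predominantly positive or negative: d = mean(beta) / SD(beta) over the
#' per-edge standardized betas, with a percentile bootstrap CI over edges.
#'
#' @param model a `harmonization_model` fitted with `standardized = TRUE`
#' @param covariate design column name (e.g. `"age"`, `"sex_M"`); a factor
#'   name with a single dummy column (e.g. `"sex"`) is also accepted
#' @param n_boot bootstrap resamples (default 10000)
#' @param conf confidence level (default 0.95)
#' @param seed RNG seed for the bootstrap
#' @return list: covariate, betas, d, ci (length 2), n_edges
#' @export
summarize_effect <- function(model, covariate, n_boot = 10000,
                             conf = 0.95, seed = 1L) {
  if (!isTRUE(model$spec$standardized)) {
    stop("summarize_effect requires a model fitted with standardized = TRUE")
  }
  rn <- rownames(model$coefficients)
  row <- covariate
  if (!row %in% rn) {
    cand <- rn[startsWith(rn, paste0(covariate, "_"))]
    if (length(cand) == 1) row <- cand
    else if (length(cand) > 1) {
      stop("covariate '", covariate, "' maps to several design columns (",
           paste(cand, collapse = ", "), "); name one explicitly")
    } else stop("no design column for covariate '", covariate, "'")
  }
  beta <- model$coefficients[row, ]
  s <- stats::sd(beta)
  if (s == 0) stop("degenerate beta distribution: SD of betas is zero")
  d <- mean(beta) / s
  E <- length(beta)
  boots <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    bb <- beta[sample.int(E, E, replace = TRUE)]
    mean(bb) / stats::sd(bb)
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(covariate = row, betas = beta, d = d,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_edges = E)
}

#' Serialize / restore a harmonization model as JSON + TSV
#'
#' The design spec goes to `<path>.json`, the coefficient table to
#' `<path>_coefficients.tsv`.
#'
#' @param model a `harmonization_model`
#' @param path output path stem
#' @export
write_harmonization_model <- function(model, path) {
  jsonlite::write_json(
    list(spec = model$spec, fit_scan_ids = model$fit_scan_ids,
         coefficients_file = paste0(basename(path), "_coefficients.tsv")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  B <- model$coefficients
  dt <- data.table::data.table(term = rownames(B))
  dt <- cbind(dt, data.table::as.data.table(B))
  data.table::fwrite(dt, paste0(path, "_coefficients.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_harmonization_model
#' @export
read_harmonization_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dirname(path), meta$coefficients_file),
                          sep = "\t")
  B <- as.matrix(dt[, -1])
  rownames(B) <- dt$term
  spec <- meta$spec
  spec$factors <- as.list(spec$factors)
  spec$centers <- as.list(spec$centers)
  spec$scales <- as.list(spec$scales)
  structure(list(spec = spec, coefficients = B,
                 fit_scan_ids = meta$fit_scan_ids),
            class = "harmonization_model")
}
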
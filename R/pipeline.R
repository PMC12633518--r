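# Workflow orchestration: YAML config -> simulate/load -> features ->
# networks -> harmonization -> analyses, with deterministic, provenance-
# stamped JSON reports.

# Tiny modular polynomial hash (hex) so reports can embed a config
# fingerprint without an external digest dependency.
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Load and validate a pipeline run configuration
#'
#' @param path YAML file, or a list already in config shape
#' @return validated config list
#' @export
load_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(config$seed)) stop("config validation: missing key 'seed'")
  if (is.null(config$out_dir)) stop("config validation: missing key 'out_dir'")
  if (is.null(config$simulate) && is.null(config$manifest)) {
    stop("config validation: need either 'simulate' or 'manifest'")
  }
  config$analyses <- config$analyses %||%
    c("network", "consistency", "reliability", "classify", "fingerprint")
  config$kinetics <- do.call(kinetics_config, config$kinetics %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' simulate (or load) -> kinetic features -> similarity networks ->
#' harmonization -> consistency / reliability / disease classification /
#' fingerprinting, writing per-scan similarity matrices, the cohort edge
#' table, and one JSON report per analysis under `out_dir`. Deterministic
#' given config + seed; every report embeds the package version and a
#' config hash.
#'
#' @param config path to a YAML config or an equivalent list (see
#'   [load_run_config()])
#' @return invisibly, the report bundle (named list)
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stamp <- list(
    package_version = as.character(utils::packageVersion("netfp")),
    # hash covers the analysis-relevant settings, not the output location
    config_hash = .config_hash(jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")],
      auto_unbox = TRUE, force = TRUE)),
    seed = seed)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    design <- if (identical(sim_cfg$design, "demo")) {
      demo_design(seed = seed, n_per_group = sim_cfg$n_per_group %||% 8)
    } else {
      stop("config validation: simulate$design must be 'demo' ",
           "(or supply 'manifest')")
    }
    cohort <- simulate_cohort(design, out_dir = file.path(out_dir, "cohort"))
    scans <- cohort$scans
    registry <- design$registry
  } else {
    registry <- build_default_registry()
    scans <- load_cohort(config$manifest, registry = registry)
  }
  covariates <- scan_covariates(scans)

  # --- networks -----------------------------------------------------------
  nets <- build_cohort_networks(scans, config$kinetics)
  mat_dir <- file.path(out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  for (id in names(nets$matrices)) {
    write_similarity_matrix(nets$matrices[[id]],
                            file.path(mat_dir, paste0(id, ".tsv")))
  }
  write_edge_table(nets$edges, file.path(out_dir, "edges.tsv"))

  reports <- list()
  baseline <- covariates$session == "baseline"
  hc <- covariates$diagnosis == "HC" & baseline

  if ("consistency" %in% config$analyses && sum(hc) >= 2) {
    cons <- cohort_consistency(nets$edges[hc, , drop = FALSE],
                               covariates$tracer[hc])
    reports$consistency <- c(stamp, list(
      global = as.list(cons$global),
      intra_tracer = lapply(cons$intra, as.list),
      inter_tracer = lapply(cons$inter, as.list)))
  }

  if ("reliability" %in% config$analyses) {
    retest <- covariates$session == "retest"
    subj_rt <- covariates$subject_id[retest]
    if (length(subj_rt) >= 3) {
      test_ids <- covariates$scan_id[baseline &
                                       covariates$subject_id %in% subj_rt]
      retest_ids <- covariates$scan_id[retest]
      ord <- match(covariates$subject_id[match(test_ids, covariates$scan_id)],
                   covariates$subject_id[match(retest_ids, covariates$scan_id)])
      te <- nets$edges[test_ids, , drop = FALSE]
      re <- nets$edges[retest_ids[ord], , drop = FALSE]
      rownames(te) <- rownames(re) <- subj_rt
      rho <- testretest_correlation(te, re)
      icc <- edgewise_icc(te, re)
      ident <- identify_subjects(te, re)
      reports$reliability <- c(stamp, list(
        testretest_rho_mean = attr(rho, "mean"),
        testretest_rho_sd = attr(rho, "sd"),
        icc_median = icc$median, icc_mad = icc$mad,
        identification_accuracy = ident$accuracy))
    }
  }

  diseases <- setdiff(unique(covariates$diagnosis[baseline]), "HC")
  if ("classify" %in% config$analyses && length(diseases) > 0) {
    cls_cfg <- do.call(classification_config,
                       config$classification %||% list())
    reports$classification <- c(stamp, list(tasks = lapply(diseases, function(d) {
      sel <- baseline & covariates$diagnosis %in% c("HC", d)
      ids <- covariates$scan_id[sel]
      tryCatch({
        rep_ <- classify_disease_binary(nets$edges[ids, , drop = FALSE],
                                        covariates$diagnosis[sel],
                                        covariates[sel, , drop = FALSE],
                                        cls_cfg, seed = seed)
        list(task = rep_$task, ap = rep_$ap, ap_ci = rep_$ap_ci,
             ap_chance = rep_$ap_chance, auc = rep_$auc,
             auc_ci = rep_$auc_ci, lambda = rep_$lambda,
             top_regions = names(sort(rep_$importance,
                                      decreasing = TRUE))[1:5])
      }, error = function(e) {
        warning("classification task '", d, "' failed: ",
                conditionMessage(e), call. = FALSE)
        list(task = paste(d, "vs HC"), error = conditionMessage(e))
      })
    })))
  }

  if ("fingerprint" %in% config$analyses && length(diseases) >= 2) {
    fp_design <- .shed_design(
      .coverable_design(
        intersect(c("batch", "sex", "genotype", "age", "dw"),
                  .usable_covariates(covariates[hc, ])),
        covariates[hc, , drop = FALSE],
        covariates[baseline, , drop = FALSE]),
      covariates[hc, , drop = FALSE])
    hm <- if (length(fp_design) > 0) {
      fit_edgewise_model(nets$edges[baseline, , drop = FALSE],
                         covariates[baseline, , drop = FALSE],
                         fit_subset = covariates$scan_id[hc],
                         design = fp_design)
    }
    pat <- baseline & covariates$diagnosis != "HC"
    fp <- patient_fingerprint(nets$edges[covariates$scan_id[pat], ,
                                         drop = FALSE],
                              covariates$diagnosis[pat],
                              harmonization_model = hm,
                              covariates = covariates[pat, , drop = FALSE])
    reports$fingerprint <- c(stamp, list(
      balanced_accuracy = fp$balanced_accuracy,
      recall = as.list(fp$recall)))
  }

  for (nm in names(reports)) {
    jsonlite::write_json(reports[[nm]],
                         file.path(out_dir, paste0(nm, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(reports)
}

# covariates with >= 2 levels / non-constant on the given rows
.usable_covariates <- function(cov) {
  cands <- c("batch", "sex", "genotype", "age", "dw")
  cands[vapply(cands, function(v) {
    x <- cov[[v]]
    if (is.numeric(x)) stats::sd(x) > 0 else
      length(unique(stats::na.omit(as.character(x)))) >= 2
  }, logical(1))]
}
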
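# Synthetic multi-site dynamic PET cohorts with known ground truth.
#
# Two levels of abstraction:
#  * simulate_scan / simulate_cohort generate full dynamic scans (regional
#    TACs driven by a tri-exponential plasma input through one-tissue
#    kinetics, frame-duration-dependent noise, multiplicative batch scaling,
#    covariate and localized disease effects on regional parameters) in the
#    exact file formats the IO module consumes;
#  * simulate_edge_cohort generates similarity-edge tables directly, for
#    harmonization / classification / fingerprinting studies where effects
#    are stated in edge units ("k noise-SDs on designated edges").

#' Tri-exponential bolus input function parameters
#'
#' The classic arterial bolus shape
#' Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t),
#' clipped at zero, with Cp(0) = 0.
#'
#' @param A1,A2,A3 amplitudes (kBq/mL/min, kBq/mL, kBq/mL)
#' @param l1,l2,l3 decay rates (1/min)
#' @return parameter list
#' @export
feng_params <- function(A1 = 851.1, A2 = 21.88, A3 = 20.81,
                        l1 = 4.134, l2 = 0.1191, l3 = 0.0104) {
  list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3)
}

#' Simulate a plasma input function on a time grid
#'
#' @param params a [feng_params()] list
#' @param grid sample times (minutes, strictly increasing, first >= 0)
#' @return an `input_function`
#' @export
simulate_input_function <- function(params = feng_params(),
                                    grid = seq(0, 90, by = 0.05)) {
  p <- params
  cp <- (p$A1 * grid - p$A2 - p$A3) * exp(-p$l1 * grid) +
    p$A2 * exp(-p$l2 * grid) + p$A3 * exp(-p$l3 * grid)
  cp <- pmax(0, cp)
  cp[grid == 0] <- 0
  input_function(grid, cp)
}

#' The default 26-frame, 90-minute acquisition schedule
#'
#' 8 x 15 s, 3 x 1 min, 5 x 2 min, 5 x 5 min, 5 x 10 min.
#' @return a `frame_schedule`
#' @export
default_schedule <- function() {
  dur <- c(rep(0.25, 8), rep(1, 3), rep(2, 5), rep(5, 5), rep(10, 5))
  ends <- cumsum(dur)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

# cumulative trapezoid
.cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (y[-1] + y[-length(y)]) / 2))
}

#' Simulate one dynamic PET scan
#'
#' Regional true curves are C_r(t) = s_r * (K1_r * int_0^t Cp + fv_r Cp(t)),
#' i.e. irreversible one-tissue trapping plus an optional fast
#' vascular/free component that decorrelates early SUVs from K1. Frame
#' values are either frame averages of the true curve (how PET frames
#' integrate counts; default) or midpoint samples (exact for recovery
#' tests). Gaussian noise with SD = kappa * sqrt(C / dt) per frame; the
#' batch effect multiplies all TAC values.
#'
#' @param scan_id,subject_id identifiers
#' @param k1 per-region K1 vector (named by registry region)
#' @param fv per-region vascular fraction (same length; default 0)
#' @param scale overall multiplicative TAC scale (batch x covariate effects)
#' @param schedule a `frame_schedule`
#' @param idif_params [feng_params()] for the input function
#' @param idif_dt IDIF sampling step, minutes
#' @param noise_kappa noise scale kappa (0 = noiseless); SD per frame is
#'   kappa * sqrt(max(C, 0) / frame duration)
#' @param frame_sampling `"average"` or `"midpoint"`
#' @param covariates named list: tracer, batch, dose, weight, age, sex,
#'   genotype, diagnosis, session
#' @param registry `roi_registry` naming the regions (length of `k1`)
#' @param seed RNG seed for the noise
#' @return list: `scan` (a `scan_record`) and `truth` (true per-region K1
#'   including the scale, fv, scale, noiseless frame matrix)
#' @export
simulate_scan <- function(scan_id, subject_id, k1, fv = NULL, scale = 1,
                          schedule = default_schedule(),
                          idif_params = feng_params(), idif_dt = 0.05,
                          noise_kappa = 0,
                          frame_sampling = c("average", "midpoint"),
                          covariates = list(), registry, seed = 1L) {
  frame_sampling <- match.arg(frame_sampling)
  R <- nrow(registry)
  stopifnot(length(k1) == R)
  if (is.null(fv)) fv <- rep(0, R)
  t_end <- max(schedule$frame_end)
  # the grid includes the frame midpoints so that midpoint sampling and the
  # estimator's union-grid trapezoid integral agree to machine precision
  tg <- sort(unique(c(seq(0, t_end, by = idif_dt),
                      frame_midpoints(schedule))))
  idif <- simulate_input_function(idif_params, tg)
  cp <- idif$concentrations
  cum <- .cumtrapz(tg, cp)

  mid <- frame_midpoints(schedule)
  nf <- n_frames(schedule)
  dur <- schedule$frame_end - schedule$frame_start
  frames <- matrix(0, R, nf, dimnames = list(registry$name, NULL))
  for (r in seq_len(R)) {
    curve <- scale * (k1[r] * cum + fv[r] * cp)
    if (frame_sampling == "midpoint") {
      frames[r, ] <- stats::approx(tg, curve, xout = mid)$y
    } else {
      for (f in seq_len(nf)) {
        sel <- tg >= schedule$frame_start[f] - 1e-9 &
          tg <= schedule$frame_end[f] + 1e-9
        tt <- tg[sel]; yy <- curve[sel]
        frames[r, f] <- sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) /
          (tt[length(tt)] - tt[1])
      }
    }
  }
  noiseless <- frames
  if (noise_kappa > 0) {
    sds <- noise_kappa * sqrt(pmax(frames, 0) /
                                matrix(dur, R, nf, byrow = TRUE))
    frames <- frames + .with_seed(seed, matrix(stats::rnorm(R * nf), R, nf)) * sds
    frames <- pmax(frames, 0)
  }
  cv <- utils::modifyList(list(tracer = "PBR28", batch = "B1", dose = 400,
                               weight = 75, age = 45, sex = "M",
                               genotype = "HAB", diagnosis = "HC",
                               session = "baseline"), covariates)
  scan <- scan_record(scan_id = scan_id, subject_id = subject_id,
                      tracer = cv$tracer, batch = cv$batch, dose = cv$dose,
                      weight = cv$weight, age = cv$age, sex = cv$sex,
                      genotype = cv$genotype, diagnosis = cv$diagnosis,
                      session = cv$session, tacs = frames,
                      schedule = schedule, idif = idif, registry = registry)
  list(scan = scan,
       truth = list(k1_true = scale * k1, fv = fv, scale = scale,
                    noiseless_frames = noiseless))
}

#' Design of a synthetic multi-site cohort
#'
#' The defaults describe a small two-batch, two-group study; `demo_design()`
#' ships a layout shaped like a multi-tracer clinical aggregate.
#'
#' @param groups list of lists: `name`, `n`, `affected_rois` (registry
#'   names), `effect` (fractional K1/uptake change in affected regions)
#' @param batches data.frame: name, tracer, scale (multiplicative TAC scale)
#' @param covariate_coefs named list of multiplicative TAC-scale
#'   coefficients: `sex_M`, `genotype_MAB`, `age` (per year, centered at
#'   45), `dw` (per MBq/kg, centered at the batch mean)
#' @param n_retest subjects (taken from the first group) with a retest
#'   session
#' @param n_block subjects (first group) with a blockade session
#' @param blockade_factor dispersion shrinkage of regional parameters
#'   toward the subject median in the blockade session (< 1 flattens the
#'   profile and raises similarity)
#' @param subject_sd log-scale between-subject SD of regional parameters
#' @param retest_sd log-scale within-subject session SD (0 = duplicate)
#' @param noise_kappa frame noise scale (see [simulate_scan()])
#' @param registry `roi_registry` (defaults to the full 87-region set)
#' @param schedule acquisition `frame_schedule`
#' @param seed mandatory design seed
#' @return a `cohort_design` list
#' @export
cohort_design <- function(groups = list(list(name = "HC", n = 10,
                                             affected_rois = character(0),
                                             effect = 0),
                                        list(name = "DIS", n = 10,
                                             affected_rois = character(0),
                                             effect = 0)),
                          batches = data.frame(name = c("B1", "B2"),
                                               tracer = c("PBR28", "PBR28"),
                                               scale = c(1.0, 1.1)),
                          covariate_coefs = list(sex_M = 0.05,
                                                 genotype_MAB = 0.08,
                                                 age = -0.002, dw = 0.01),
                          n_retest = 0, n_block = 0, blockade_factor = 0.5,
                          subject_sd = 0.10, retest_sd = 0,
                          noise_kappa = 0,
                          registry = build_default_registry(),
                          schedule = default_schedule(), seed) {
  if (missing(seed)) stop("cohort_design requires an explicit seed")
  stopifnot(all(vapply(groups, function(g) g$n >= 1, logical(1))),
            noise_kappa >= 0)
  structure(list(groups = groups, batches = batches,
                 covariate_coefs = covariate_coefs, n_retest = n_retest,
                 n_block = n_block, blockade_factor = blockade_factor,
                 subject_sd = subject_sd, retest_sd = retest_sd,
                 noise_kappa = noise_kappa, registry = registry,
                 schedule = schedule, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a cohort of dynamic PET scans
#'
#' Subjects are assigned to batches round-robin within group. Each subject
#' has a persistent regional parameter profile (identity for
#' fingerprinting); retest sessions redraw only the measurement noise (plus
#' optional parameter jitter `retest_sd`), blockade sessions shrink the
#' regional parameter dispersion by `blockade_factor`.
#'
#' @param design a [cohort_design()]
#' @param out_dir optional directory: when given, the cohort is also
#'   written with [write_cohort()]
#' @return list: `scans` (list of `scan_record`), `truth` (per-scan ground
#'   truth + design), `manifest` (path or NULL)
#' @export
simulate_cohort <- function(design, out_dir = NULL) {
  reg <- design$registry
  R <- nrow(reg)
  state <- .with_seed(design$seed, {
    list(k1_template = exp(stats::rnorm(R, log(0.12), 0.25)),
         fv_template = stats::runif(R, 0.02, 0.08))
  })
  seeds <- .child_seeds(design$seed, 100000)
  si <- 0
  next_seed <- function() {
    si <<- si + 1
    seeds[si]
  }
  scans <- list()
  truth <- list()
  cc <- design$covariate_coefs
  subj_i <- 0
  for (g in design$groups) {
    for (k in seq_len(g$n)) {
      subj_i <- subj_i + 1
      b <- design$batches[((subj_i - 1) %% nrow(design$batches)) + 1, ]
      subject_id <- sprintf("sub%03d", subj_i)
      sd_seed <- next_seed()
      prof <- .with_seed(sd_seed, {
        list(k1 = state$k1_template * exp(stats::rnorm(R, 0, design$subject_sd)),
             fv = pmax(0.001, state$fv_template *
                         exp(stats::rnorm(R, 0, design$subject_sd))),
             age = min(85, max(18, stats::rnorm(1, 45, 12))),
             sex = sample(c("M", "F"), 1),
             genotype = sample(c("HAB", "MAB"), 1),
             dose = max(50, stats::rnorm(1, 400, 50)),
             weight = max(40, stats::rnorm(1, 75, 12)))
      })
      affected <- match(g$affected_rois, reg$name)
      k1 <- prof$k1
      fv <- prof$fv
      if (length(affected) > 0 && g$effect != 0) {
        k1[affected] <- k1[affected] * (1 + g$effect)
        fv[affected] <- fv[affected] * (1 + g$effect)
      }
      dw <- prof$dose / prof$weight
      scale <- b$scale *
        (1 + cc$sex_M * (prof$sex == "M") +
           cc$genotype_MAB * (prof$genotype == "MAB") +
           cc$age * (prof$age - 45) + cc$dw * (dw - 400 / 75))
      cv <- list(tracer = b$tracer, batch = b$name, dose = prof$dose,
                 weight = prof$weight, age = prof$age, sex = prof$sex,
                 genotype = prof$genotype, diagnosis = g$name)
      sessions <- list(baseline = list(k1 = k1, fv = fv))
      if (g$name == design$groups[[1]]$name && k <= design$n_retest) {
        jit <- if (design$retest_sd > 0) {
          .with_seed(next_seed(), exp(stats::rnorm(R, 0, design$retest_sd)))
        } else rep(1, R)
        sessions$retest <- list(k1 = k1 * jit, fv = fv)
      }
      if (g$name == design$groups[[1]]$name && k <= design$n_block) {
        shrink <- function(x) {
          stats::median(x) + design$blockade_factor * (x - stats::median(x))
        }
        sessions$block <- list(k1 = shrink(k1), fv = shrink(fv))
      }
      for (sess in names(sessions)) {
        scan_id <- paste0(subject_id, "_", sess)
        sim <- simulate_scan(
          scan_id = scan_id, subject_id = subject_id,
          k1 = sessions[[sess]]$k1, fv = sessions[[sess]]$fv, scale = scale,
          schedule = design$schedule, noise_kappa = design$noise_kappa,
          covariates = utils::modifyList(cv, list(session = sess)),
          registry = reg, seed = next_seed())
        scans[[scan_id]] <- sim$scan
        truth[[scan_id]] <- sim$truth
      }
    }
  }
  manifest <- if (!is.null(out_dir)) write_cohort(scans, out_dir) else NULL
  list(scans = unname(scans), truth = truth, design = design,
       manifest = manifest)
}

#' A multi-tracer, multi-batch demo design
#'
#' Shaped like a multi-centre clinical aggregate: three tracers, seven
#' batches, healthy controls plus five disease groups with localized
#' regional effects. Sized down for desk-scale runs.
#'
#' @param seed design seed
#' @param n_per_group subjects per group (default 8)
#' @return a [cohort_design()]
#' @export
demo_design <- function(seed, n_per_group = 8) {
  reg <- build_default_registry()
  pick <- function(bases) reg$name[reg$base %in% bases]
  cohort_design(
    groups = list(
      # controls outnumber each disease group, as in multi-centre
      # aggregates, and must cover the 11-column harmonization design
      list(name = "HC", n = 5 * n_per_group,
           affected_rois = character(0), effect = 0),
      list(name = "TBI", n = n_per_group,
           affected_rois = pick(c("lateralorbitofrontal",
                                  "medialorbitofrontal",
                                  "rostralanteriorcingulate")),
           effect = 0.15),
      list(name = "MS", n = n_per_group,
           affected_rois = pick(c("putamen", "thalamus")), effect = 0.15),
      list(name = "cLBP", n = n_per_group,
           affected_rois = pick(c("accumbens", "caudalanteriorcingulate",
                                  "bankssts")), effect = 0.12),
      list(name = "SCZ", n = n_per_group,
           affected_rois = pick(c("putamen", "pallidum", "frontalpole")),
           effect = 0.12),
      list(name = "DEP", n = n_per_group,
           affected_rois = pick(c("caudalmiddlefrontal",
                                  "rostralanteriorcingulate",
                                  "parsopercularis")),
           effect = 0.10)
    ),
    batches = data.frame(
      name = c("KCL_PBR28", "MGH_Bay6", "MGH_Bay7", "UBC",
               "KCL_DPA714", "ICM_PETMR", "ICM_HRRT"),
      tracer = c("PBR28", "PBR28", "PBR28", "PBR28",
                 "DPA714", "DPA714", "DPA714"),
      scale = c(1.00, 1.08, 1.12, 0.95, 1.00, 1.05, 0.92)),
    n_retest = min(5, n_per_group), noise_kappa = 0.3, seed = seed)
}

#' Simulate a cohort directly in edge space
#'
#' Generates scans x edges tables with a fixed base network pattern,
#' optional per-tracer pattern perturbations, multiplicative batch scaling,
#' additive covariate effects, additive group signatures on designated
#' edges (stated in noise-SD units), and iid Gaussian edge noise. This is
#' the generator behind the harmonization, classification and
#' fingerprinting property suites, where effects are specified in edge
#' units.
#'
#' @param n_regions registry head size (edges = R(R-1)/2)
#' @param groups named integer vector: scans per diagnosis label; the first
#'   label is the control group
#' @param affected_edges named list: per group, indices of edges carrying
#'   the group signature
#' @param effect_size signature size in units of `noise_sd`
#' @param noise_sd SD of the iid edge noise
#' @param batches character vector of batch labels (assigned round-robin)
#' @param batch_scale named multiplicative edge scale per batch (default 1)
#' @param tracer_by_batch named tracer label per batch (default one tracer)
#' @param tracer_shift_sd SD of a per-tracer perturbation of the base
#'   pattern (creates intra- > inter-tracer consistency)
#' @param covariate_coefs named list of additive edge effects: `sex_M`,
#'   `genotype_MAB`, `age` (per year, centered 45), `dw` (per MBq/kg,
#'   centered 5.33)
#' @param seed mandatory seed
#' @return list: `edges`, `covariates`, `truth` (base pattern, affected
#'   edge indices, coefficients)
#' @export
simulate_edge_cohort <- function(n_regions = 30,
                                 groups = c(HC = 30, DIS = 30),
                                 affected_edges = list(),
                                 effect_size = 0, noise_sd = 0.02,
                                 batches = "B1", batch_scale = NULL,
                                 tracer_by_batch = NULL,
                                 tracer_shift_sd = 0,
                                 covariate_coefs = list(sex_M = 0,
                                                        genotype_MAB = 0,
                                                        age = 0, dw = 0),
                                 seed) {
  if (missing(seed)) stop("simulate_edge_cohort requires an explicit seed")
  reg <- subset_registry(n_regions)
  labels <- edge_labels(reg)
  E <- length(labels)
  n <- sum(groups)
  if (is.null(batch_scale)) {
    batch_scale <- stats::setNames(rep(1, length(batches)), batches)
  }
  if (is.null(tracer_by_batch)) {
    tracer_by_batch <- stats::setNames(rep("PBR28", length(batches)), batches)
  }
  cc <- utils::modifyList(list(sex_M = 0, genotype_MAB = 0, age = 0, dw = 0),
                          covariate_coefs)
  .with_seed(seed, {
    base <- stats::runif(E, 0.3, 0.8)
    tracers <- unique(tracer_by_batch)
    tracer_shift <- lapply(tracers, function(t)
      stats::rnorm(E, 0, tracer_shift_sd))
    names(tracer_shift) <- tracers

    diagnosis <- rep(names(groups), groups)
    batch <- rep_len(batches, n)
    # keep batch assignment balanced within group
    for (g in names(groups)) {
      idx <- which(diagnosis == g)
      batch[idx] <- rep_len(batches, length(idx))
    }
    tracer <- unname(tracer_by_batch[batch])
    sex <- sample(c("M", "F"), n, replace = TRUE)
    genotype <- sample(c("HAB", "MAB"), n, replace = TRUE)
    age <- pmin(85, pmax(18, stats::rnorm(n, 45, 12)))
    dose <- pmax(50, stats::rnorm(n, 400, 50))
    weight <- pmax(40, stats::rnorm(n, 75, 12))
    dw <- dose / weight

    edges <- matrix(NA_real_, n, E)
    for (i in seq_len(n)) {
      mu <- (base + tracer_shift[[tracer[i]]] +
               cc$sex_M * (sex[i] == "M") +
               cc$genotype_MAB * (genotype[i] == "MAB") +
               cc$age * (age[i] - 45) +
               cc$dw * (dw[i] - 400 / 75)) * batch_scale[batch[i]]
      g <- diagnosis[i]
      if (!is.null(affected_edges[[g]]) && effect_size != 0) {
        mu[affected_edges[[g]]] <- mu[affected_edges[[g]]] +
          effect_size * noise_sd
      }
      edges[i, ] <- mu + stats::rnorm(E, 0, noise_sd)
    }
    scan_id <- sprintf("scan%03d", seq_len(n))
    dimnames(edges) <- list(scan_id, labels)
    covariates <- data.frame(scan_id = scan_id,
                             subject_id = scan_id, tracer = tracer,
                             batch = batch, dose = dose, weight = weight,
                             dw = dw, age = age, sex = sex,
                             genotype = genotype, diagnosis = diagnosis,
                             session = "baseline", stringsAsFactors = FALSE)
    list(edges = edges, covariates = covariates,
         truth = list(base = base, affected_edges = affected_edges,
                      effect = effect_size * noise_sd, noise_sd = noise_sd,
                      covariate_coefs = cc, tracer_shift = tracer_shift))
  })
}
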
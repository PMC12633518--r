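# Domain types: frame schedules, TACs, input functions, scan records.
# All activities are in kBq/mL, times in minutes, doses in MBq, weights in kg.

#' Frame schedule of a dynamic PET acquisition
#'
#' @param frame_start,frame_end numeric vectors of frame start/end times in
#'   minutes. Frames must be sorted, non-overlapping, with
#'   `frame_start[i] < frame_end[i]` and `frame_start[1] >= 0`.
#' @return a `frame_schedule` object
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) != length(frame_end) || length(frame_start) < 1) {
    stop("frame_start and frame_end must have equal length >= 1")
  }
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end))) {
    stop("frame times must be finite")
  }
  if (frame_start[1] < 0) stop("frame_start[1] must be >= 0")
  if (any(frame_start >= frame_end)) {
    stop("each frame_start must be < its frame_end")
  }
  if (length(frame_start) > 1 &&
      any(frame_start[-1] < frame_end[-length(frame_end)] - 1e-9)) {
    stop("frames must be sorted and non-overlapping")
  }
  structure(list(frame_start = as.numeric(frame_start),
                 frame_end = as.numeric(frame_end)),
            class = "frame_schedule")
}

#' Frame midpoints of a schedule, in minutes
#' @param schedule a `frame_schedule`
#' @return numeric vector of midpoints
#' @export
frame_midpoints <- function(schedule) {
  (schedule$frame_start + schedule$frame_end) / 2
}

#' Number of frames
#' @param schedule a `frame_schedule`
#' @export
n_frames <- function(schedule) length(schedule$frame_start)

#' Image-derived input function
#'
#' @param times strictly increasing sample times (minutes), first >= 0
#' @param concentrations plasma activity concentrations (kBq/mL)
#' @return an `input_function` object
#' @export
input_function <- function(times, concentrations) {
  if (length(times) != length(concentrations) || length(times) < 2) {
    stop("times and concentrations must have equal length >= 2")
  }
  if (any(!is.finite(times)) || any(!is.finite(concentrations))) {
    stop("input function values must be finite")
  }
  if (times[1] < 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and start at >= 0")
  }
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations)),
            class = "input_function")
}

# TACs are stored as a regions x frames numeric matrix with rownames equal to
# registry names; a scan_record bundles it with its schedule and covariates.

#' A single PET scan record
#'
#' @param scan_id,subject_id identifiers
#' @param tracer tracer label (standardization / classification stratum)
#' @param batch batch label (site + scanner + protocol)
#' @param dose injected dose, MBq (> 0)
#' @param weight body weight, kg (> 0)
#' @param age years
#' @param sex "M" or "F"
#' @param genotype "HAB", "MAB", or NA for tracers without genotype dependence
#' @param diagnosis diagnosis label; "HC" for controls
#' @param session "baseline", "retest" or "block"
#' @param tacs regions x frames matrix (kBq/mL), rownames = registry names
#' @param schedule a `frame_schedule` with as many frames as `ncol(tacs)`
#' @param idif an `input_function`
#' @param registry the `roi_registry` the TAC rows must cover
#' @return a `scan_record`
#' @export
scan_record <- function(scan_id, subject_id, tracer, batch, dose, weight,
                        age, sex, genotype = NA_character_,
                        diagnosis = "HC", session = "baseline",
                        tacs, schedule, idif,
                        registry = build_default_registry()) {
  if (!is.finite(dose) || dose <= 0) {
    stop("non-positive dose for scan ", scan_id)
  }
  if (!is.finite(weight) || weight <= 0) {
    stop("non-positive weight for scan ", scan_id)
  }
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (!is.na(genotype) && !genotype %in% c("HAB", "MAB")) {
    stop("genotype must be 'HAB', 'MAB' or NA")
  }
  if (!session %in% c("baseline", "retest", "block")) {
    stop("session must be one of baseline/retest/block")
  }
  if (!inherits(schedule, "frame_schedule")) stop("schedule must be a frame_schedule")
  if (!inherits(idif, "input_function")) stop("idif must be an input_function")
  tacs <- as.matrix(tacs)
  if (ncol(tacs) != n_frames(schedule)) {
    stop("TAC frame count does not match schedule for scan ", scan_id)
  }
  missing_roi <- setdiff(registry$name, rownames(tacs))
  if (length(missing_roi) > 0) {
    stop("scan ", scan_id, " is missing TACs for ROI(s): ",
         paste(utils::head(missing_roi, 5), collapse = ", "))
  }
  tacs <- tacs[registry$name, , drop = FALSE]   # canonical order
  if (any(!is.finite(tacs))) stop("non-finite TAC values in scan ", scan_id)
  if (any(tacs < 0)) {
    warning("scan ", scan_id, " has negative TAC values (reconstruction noise?)")
  }
  structure(list(
    scan_id = scan_id, subject_id = subject_id, tracer = tracer,
    batch = batch, dose = as.numeric(dose), weight = as.numeric(weight),
    age = as.numeric(age), sex = sex, genotype = genotype,
    diagnosis = diagnosis, session = session,
    tacs = tacs, schedule = schedule, idif = idif
  ), class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat("<scan_record>", x$scan_id, "subject", x$subject_id,
      sprintf("[%s, %s, %s, %s]", x$tracer, x$batch, x$diagnosis, x$session),
      "\n  ", nrow(x$tacs), "regions x", ncol(x$tacs), "frames;",
      "dose", x$dose, "MBq; weight", x$weight, "kg\n")
  invisible(x)
}

#' Extract the covariate table of a list of scan records
#'
#' @param scans list of `scan_record`
#' @return data.frame with one row per scan: scan_id, subject_id, tracer,
#'   batch, dose, weight, dw (dose/weight), age, sex, genotype, diagnosis,
#'   session.
#' @export
scan_covariates <- function(scans) {
  out <- do.call(rbind, lapply(scans, function(s) {
    data.frame(scan_id = s$scan_id, subject_id = s$subject_id,
               tracer = s$tracer, batch = s$batch, dose = s$dose,
               weight = s$weight, dw = s$dose / s$weight, age = s$age,
               sex = s$sex, genotype = s$genotype, diagnosis = s$diagnosis,
               session = s$session, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
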
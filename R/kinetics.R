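# Kinetic feature extraction: frame-midpoint interpolation, SUV at fixed
# times, and K1 from an irreversible one-tissue compartment model fitted
# against an image-derived input function (IDIF).
#
# Input contract: TACs are assumed decay-corrected upstream; no decay
# correction is applied here.

#' Default kinetics configuration
#'
#' @return list with `suv_times_minutes` (defaults 1.25, 13.5, 50),
#'   `k1_fit_window_minutes` (default `c(0, 50)`) and
#'   `idif_integration` (`"trapezoid"`, the only supported rule).
#' @export
kinetics_config <- function(suv_times_minutes = c(1.25, 13.5, 50),
                            k1_fit_window_minutes = c(0, 50),
                            idif_integration = "trapezoid") {
  stopifnot(identical(idif_integration, "trapezoid"),
            length(k1_fit_window_minutes) == 2,
            k1_fit_window_minutes[1] < k1_fit_window_minutes[2])
  list(suv_times_minutes = sort(as.numeric(suv_times_minutes)),
       k1_fit_window_minutes = as.numeric(k1_fit_window_minutes),
       idif_integration = idif_integration)
}

#' Interpolate a TAC onto an arbitrary time grid
#'
#' Frame values are attached to frame midpoints (the standard frame-time
#' convention) and interpolated linearly; the interpolation is exact at
#' midpoints. Grid points outside the midpoint support are an error.
#'
#' @param tac numeric vector, one value per frame (kBq/mL)
#' @param schedule the scan's `frame_schedule`
#' @param grid_minutes query times (minutes)
#' @return numeric vector of interpolated activities
#' @export
interpolate_to_grid <- function(tac, schedule, grid_minutes) {
  mid <- frame_midpoints(schedule)
  if (length(tac) != length(mid)) {
    stop("TAC length does not match the schedule frame count")
  }
  bad <- grid_minutes < mid[1] - 1e-9 | grid_minutes > mid[length(mid)] + 1e-9
  if (any(bad)) {
    stop("grid point t=", grid_minutes[which(bad)[1]],
         " min is outside the TAC support [", mid[1], ", ",
         mid[length(mid)], "]")
  }
  stats::approx(mid, tac, xout = grid_minutes, rule = 2)$y
}

#' Standardized uptake value at a time point
#'
#' SUV = C(t) / (injected dose / body weight), with activity in kBq/mL,
#' dose converted to kBq and weight to grams (tissue density 1 g/mL), i.e.
#' SUV = C(t) * weight_kg / dose_MBq.
#'
#' @inheritParams interpolate_to_grid
#' @param dose_MBq injected dose (> 0)
#' @param weight_kg body weight (> 0)
#' @param t_minutes time post-injection, within the TAC support
#' @return unitless SUV
#' @export
compute_suv <- function(tac, schedule, dose_MBq, weight_kg, t_minutes) {
  if (dose_MBq <= 0 || weight_kg <= 0) stop("dose and weight must be > 0")
  ct <- interpolate_to_grid(tac, schedule, t_minutes)
  ct * weight_kg / dose_MBq
}

# Cumulative plasma integral int_0^t Cp at the query times, by trapezoid on
# the union of the IDIF samples and the query times. A bolus start Cp(0)=0
# is assumed when the IDIF does not sample t=0.
.plasma_integral <- function(idif, t_query) {
  times <- idif$times
  conc <- idif$concentrations
  if (max(t_query) > max(times) + 1e-9) {
    stop("IDIF does not cover the fit window (ends at ", max(times), " min)")
  }
  if (times[1] > 0) {
    times <- c(0, times)
    conc <- c(0, conc)
  }
  grid <- sort(unique(c(times, t_query)))
  cg <- stats::approx(times, conc, xout = grid)$y
  cum <- c(0, cumsum(diff(grid) * (cg[-1] + cg[-length(cg)]) / 2))
  cum[match(t_query, grid)]
}

#' Estimate K1 with an irreversible one-tissue compartment model
#'
#' With no efflux (k2 = 0) the tissue curve is CT(t) = K1 * int_0^t Cp, so
#' K1 is a single-parameter least-squares regression through the origin of
#' the frame-midpoint TAC samples on the cumulated plasma input. The
#' estimate is clipped at zero.
#'
#' @inheritParams interpolate_to_grid
#' @param idif an `input_function` covering the fit window
#' @param fit_window_minutes `c(lo, hi)`: frames whose midpoints fall in the
#'   window enter the fit (at least 3 required)
#' @return K1 in mL cm^-3 min^-1
#' @export
estimate_k1 <- function(tac, schedule, idif,
                        fit_window_minutes = c(0, 50)) {
  mid <- frame_midpoints(schedule)
  keep <- mid >= fit_window_minutes[1] & mid <= fit_window_minutes[2]
  if (sum(keep) < 3) {
    stop("fewer than 3 frames in the K1 fit window [",
         fit_window_minutes[1], ", ", fit_window_minutes[2], "] min")
  }
  x <- .plasma_integral(idif, mid[keep])
  y <- tac[keep]
  sxx <- sum(x^2)
  if (sxx <= 0) stop("degenerate input function: all-zero plasma integral")
  max(0, sum(x * y) / sxx)
}

#' Extract the regional pharmacokinetic feature vectors of a scan
#'
#' For each registry region: SUV at the configured times (defaults 1.25,
#' 13.5 and 50 minutes post-injection) and K1 from the irreversible
#' one-tissue model. These four features summarize regional tracer delivery
#' and uptake and are the raw (pre-standardization) inputs to the
#' similarity network.
#'
#' @param scan a `scan_record`
#' @param config a [kinetics_config()]
#' @return numeric matrix, regions x features, rownames in registry order,
#'   colnames `suv_<t>` then `k1`
#' @export
extract_features <- function(scan, config = kinetics_config()) {
  mid <- frame_midpoints(scan$schedule)
  t_max <- max(config$suv_times_minutes)
  if (t_max > mid[length(mid)] + 1e-9) {
    stop("scan ", scan$scan_id, " ends before the t=", t_max,
         " min SUV time point")
  }
  suv_names <- paste0("suv_", sub("\\.", "p", format(config$suv_times_minutes,
                                                     trim = TRUE)))
  fw <- c(config$k1_fit_window_minutes[1],
          min(config$k1_fit_window_minutes[2], mid[length(mid)]))
  feats <- t(vapply(seq_len(nrow(scan$tacs)), function(i) {
    tac <- scan$tacs[i, ]
    suv <- compute_suv(tac, scan$schedule, scan$dose, scan$weight,
                       config$suv_times_minutes)
    k1 <- estimate_k1(tac, scan$schedule, scan$idif, fw)
    c(suv, k1)
  }, numeric(length(config$suv_times_minutes) + 1)))
  dimnames(feats) <- list(rownames(scan$tacs), c(suv_names, "k1"))
  feats
}

#' Feature table for a whole cohort
#'
#' Stacks [extract_features()] over scans into a long table suitable for
#' [robust_standardize()].
#'
#' @param scans list of `scan_record`
#' @param config a [kinetics_config()]
#' @return data.frame: scan_id, roi, tracer, then one column per feature
#' @export
cohort_features <- function(scans, config = kinetics_config()) {
  out <- lapply(scans, function(s) {
    f <- extract_features(s, config)
    cbind(data.frame(scan_id = s$scan_id, roi = rownames(f),
                     tracer = s$tracer, stringsAsFactors = FALSE),
          as.data.frame(f))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
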
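# Readers and writers for cohort artifacts. All files are plain text:
# long-format TSV for TACs and IDIFs, JSON for the manifest, TSV with
# ROI-name header row/column for similarity matrices.

#' Write a simulated or assembled cohort to disk
#'
#' Emits, under `out_dir`: `manifest.json` (covariates, schedules, file
#' paths), one TAC table `tacs_<scan_id>.tsv` (columns scan_id, roi,
#' frame_index, activity_kBq_per_mL) and one IDIF table `idif_<scan_id>.tsv`
#' (columns time_minutes, activity_kBq_per_mL) per scan.
#'
#' @param scans list of `scan_record`
#' @param out_dir output directory (created if missing)
#' @return invisibly, the manifest path
#' @export
write_cohort <- function(scans, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(scans, function(s) {
    tac_file <- paste0("tacs_", s$scan_id, ".tsv")
    idif_file <- paste0("idif_", s$scan_id, ".tsv")
    tac_dt <- data.table::data.table(
      scan_id = s$scan_id,
      roi = rep(rownames(s$tacs), each = ncol(s$tacs)),
      frame_index = rep(seq_len(ncol(s$tacs)), times = nrow(s$tacs)),
      activity_kBq_per_mL = as.vector(t(s$tacs))
    )
    data.table::fwrite(tac_dt, file.path(out_dir, tac_file), sep = "\t")
    data.table::fwrite(
      data.table::data.table(time_minutes = s$idif$times,
                             activity_kBq_per_mL = s$idif$concentrations),
      file.path(out_dir, idif_file), sep = "\t")
    list(scan_id = s$scan_id, subject_id = s$subject_id, tracer = s$tracer,
         batch = s$batch, dose_MBq = s$dose, weight_kg = s$weight,
         age_years = s$age, sex = s$sex, genotype = s$genotype,
         diagnosis = s$diagnosis, session = s$session,
         frame_start_minutes = s$schedule$frame_start,
         frame_end_minutes = s$schedule$frame_end,
         tac_file = tac_file, idif_file = idif_file)
  })
  manifest <- list(format = "netfp-cohort-manifest",
                   units = list(activity = "kBq/mL", time = "minutes",
                                dose = "MBq", weight = "kg"),
                   scans = entries)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path path to `manifest.json` written by [write_cohort()]
#'   (or hand-assembled in the same schema)
#' @param tac_dir directory holding the TAC/IDIF tables; defaults to the
#'   manifest's directory
#' @param registry the `roi_registry` the scans must cover
#' @return list of validated `scan_record`
#' @export
load_cohort <- function(manifest_path, tac_dir = dirname(manifest_path),
                        registry = build_default_registry()) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  lapply(manifest$scans, function(e) {
    tac_path <- file.path(tac_dir, e$tac_file)
    if (!file.exists(tac_path)) {
      stop("missing TAC file for scan ", e$scan_id, ": ", tac_path)
    }
    idif_path <- file.path(tac_dir, e$idif_file)
    if (!file.exists(idif_path)) {
      stop("missing IDIF file for scan ", e$scan_id, ": ", idif_path)
    }
    sched <- frame_schedule(unlist(e$frame_start_minutes),
                            unlist(e$frame_end_minutes))
    tab <- data.table::fread(tac_path, sep = "\t")
    need <- c("roi", "frame_index", "activity_kBq_per_mL")
    if (!all(need %in% names(tab))) {
      stop("TAC table for scan ", e$scan_id, " lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
    rois <- unique(tab$roi)
    tacs <- matrix(NA_real_, nrow = length(rois), ncol = n_frames(sched),
                   dimnames = list(rois, NULL))
    idx <- cbind(match(tab$roi, rois), tab$frame_index)
    tacs[idx] <- tab$activity_kBq_per_mL
    if (any(is.na(tacs))) {
      stop("incomplete TAC table for scan ", e$scan_id)
    }
    idif_tab <- data.table::fread(idif_path, sep = "\t")
    genotype <- if (is.null(e$genotype)) NA_character_ else e$genotype
    scan_record(
      scan_id = e$scan_id, subject_id = e$subject_id, tracer = e$tracer,
      batch = e$batch, dose = e$dose_MBq, weight = e$weight_kg,
      age = e$age_years, sex = e$sex, genotype = genotype,
      diagnosis = e$diagnosis, session = e$session,
      tacs = tacs, schedule = sched,
      idif = input_function(idif_tab$time_minutes,
                            idif_tab$activity_kBq_per_mL),
      registry = registry
    )
  })
}

#' Write / read a similarity matrix as TSV with ROI header row and column
#'
#' @param S similarity matrix with ROI dimnames (see
#'   [build_similarity_matrix()])
#' @param path output path
#' @return `write_similarity_matrix` returns the path invisibly;
#'   `read_similarity_matrix` the matrix, checked against `registry`.
#' @export
write_similarity_matrix <- function(S, path) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S),
            !is.null(rownames(S)), identical(rownames(S), colnames(S)))
  dt <- data.table::data.table(roi = rownames(S))
  for (j in seq_len(ncol(S))) dt[[colnames(S)[j]]] <- S[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @param registry `roi_registry` the matrix must match, or NULL to skip
#' @export
read_similarity_matrix <- function(path, registry = build_default_registry()) {
  dt <- data.table::fread(path, sep = "\t")
  rois <- dt$roi
  S <- as.matrix(dt[, -1])
  rownames(S) <- rois
  if (!identical(rownames(S), colnames(S))) {
    stop("similarity matrix row/column names differ in ", path)
  }
  if (!is.null(registry) && !identical(rois, registry$name)) {
    stop("similarity matrix in ", path, " does not match the registry (",
         nrow(S), " rows vs ", nrow(registry), " registry regions)")
  }
  S
}

#' Write / read a cohort edge table (rows = scans, columns = edges)
#'
#' @param edges numeric matrix, rownames = scan ids, colnames = edge labels
#'   `"roi_i|roi_j"` in canonical order
#' @param path output path
#' @export
write_edge_table <- function(edges, path) {
  dt <- data.table::data.table(scan_id = rownames(edges))
  dt <- cbind(dt, data.table::as.data.table(edges))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$scan_id
  m
}
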
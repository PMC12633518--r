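# Similarity-network construction: robust z-scoring of regional features
# within tracer groups, inverse-Euclidean similarity, and the canonical
# upper-triangle edge flattening all statistics operate on.

.FEATURE_META_COLS <- c("scan_id", "roi", "tracer")

.feature_cols <- function(feature_table) {
  setdiff(names(feature_table), .FEATURE_META_COLS)
}

#' Robust z-score standardization within tracer groups
#'
#' Each feature is standardized as (x - median) / MAD, where the median and
#' the raw median absolute deviation (no 1.4826 consistency constant) are
#' computed per feature over all region x scan values within a tracer group.
#' Pooling regions preserves the between-region contrast the similarity
#' measure depends on.
#'
#' @param feature_table data.frame from [cohort_features()]: meta columns
#'   `scan_id`, `roi`, `tracer` plus numeric feature columns
#' @param tracer_grouping optional grouping vector overriding the `tracer`
#'   column (one value per row)
#' @return list with `table` (standardized copy of `feature_table`) and
#'   `params` (data.frame: group, feature, median, mad)
#' @export
robust_standardize <- function(feature_table, tracer_grouping = NULL) {
  grp <- if (is.null(tracer_grouping)) feature_table$tracer else tracer_grouping
  if (is.null(grp)) stop("no tracer grouping available")
  feats <- .feature_cols(feature_table)
  if (length(feats) == 0) stop("feature_table has no feature columns")
  out <- feature_table
  params <- list()
  for (g in unique(grp)) {
    rows <- grp == g
    for (f in feats) {
      x <- feature_table[[f]][rows]
      if (length(unique(x)) < 2) {
        stop("degenerate feature dispersion: feature '", f,
             "' is constant in group '", g, "'")
      }
      m <- stats::median(x)
      s <- stats::median(abs(x - m))
      if (s == 0) {
        stop("degenerate feature dispersion: MAD of feature '", f,
             "' is zero in group '", g, "'")
      }
      out[[f]][rows] <- (x - m) / s
      params[[length(params) + 1]] <-
        data.frame(group = g, feature = f, median = m, mad = s,
                   stringsAsFactors = FALSE)
    }
  }
  list(table = out, params = do.call(rbind, params))
}

#' Euclidean distance between two regional feature vectors
#'
#' @param x_i,x_j equal-length finite numeric vectors
#' @return d = sqrt(sum_k (x_ik - x_jk)^2)
#' @export
pairwise_distance <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) {
    stop("feature vectors have different lengths (", length(x_i), " vs ",
         length(x_j), ")")
  }
  if (any(!is.finite(x_i)) || any(!is.finite(x_j))) {
    stop("feature vectors must be finite")
  }
  sqrt(sum((x_i - x_j)^2))
}

#' Inverse-Euclidean similarity S = 1 / (1 + d)
#'
#' Strictly decreasing in d, with range (0, 1] and S = 1 iff d = 0.
#'
#' @param d non-negative distance(s)
#' @return similarity in (0, 1]
#' @export
similarity_from_distance <- function(d) {
  if (any(d < 0)) stop("distances must be non-negative")
  1 / (1 + d)
}

#' Build the similarity matrix of one scan
#'
#' For every pair of regions, the similarity between their standardized
#' feature vectors: S_ij = 1 / (1 + ||x_i - x_j||_2).
#'
#' @param features regions x features numeric matrix, rownames = registry
#'   names (standardized values)
#' @return symmetric matrix with unit diagonal and dimnames = region names
#' @export
build_similarity_matrix <- function(features) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) stop("features must have region rownames")
  if (any(!is.finite(features))) stop("features must be finite")
  d <- as.matrix(stats::dist(features, method = "euclidean"))
  S <- 1 / (1 + d)
  diag(S) <- 1
  dimnames(S) <- list(rownames(features), rownames(features))
  S
}

# Row-major upper-triangle index pairs (i < j), the canonical edge order.
.edge_index <- function(R) {
  i <- rep.int(seq_len(R - 1), times = (R - 1):1)
  j <- unlist(lapply(seq_len(R - 1), function(k) (k + 1):R))
  cbind(i = i, j = j)
}

#' Canonical edge labels of a registry
#'
#' @param registry a `roi_registry` (or character vector of region names)
#' @return character vector `"roi_i|roi_j"`, length R(R-1)/2, in row-major
#'   upper-triangle order
#' @export
edge_labels <- function(registry) {
  nm <- if (is.data.frame(registry)) registry$name else registry
  idx <- .edge_index(length(nm))
  paste(nm[idx[, 1]], nm[idx[, 2]], sep = "|")
}

#' Flatten a similarity matrix to its canonical edge vector (and back)
#'
#' The edge vector holds S_ij for all i < j in row-major registry order;
#' `matrix_from_edges` is its exact inverse (unit diagonal restored).
#'
#' @param S symmetric similarity matrix with region dimnames
#' @return named numeric vector of length R(R-1)/2
#' @export
edge_vector <- function(S) {
  R <- nrow(S)
  idx <- .edge_index(R)
  v <- S[idx]
  names(v) <- paste(rownames(S)[idx[, 1]], colnames(S)[idx[, 2]], sep = "|")
  v
}

#' @rdname edge_vector
#' @param edges edge vector as produced by [edge_vector()]
#' @param region_names region names defining the matrix order; recovered
#'   from the edge names when omitted
#' @export
matrix_from_edges <- function(edges, region_names = NULL) {
  E <- length(edges)
  R <- (1 + sqrt(1 + 8 * E)) / 2
  if (R != round(R)) stop("edge vector length ", E, " is not R(R-1)/2")
  R <- as.integer(R)
  if (is.null(region_names)) {
    if (is.null(names(edges))) stop("region_names required for unnamed edges")
    parts <- strsplit(names(edges), "|", fixed = TRUE)
    first <- vapply(parts, `[`, "", 1)
    region_names <- c(unique(first), parts[[E]][2])
  }
  if (length(region_names) != R) stop("region_names length must be ", R)
  S <- matrix(0, R, R, dimnames = list(region_names, region_names))
  idx <- .edge_index(R)
  S[idx] <- edges
  S <- S + t(S)
  diag(S) <- 1
  S
}

#' Similarity matrices and the cohort edge table for a list of scans
#'
#' Full front half of the pipeline: kinetic features, robust per-tracer
#' standardization, one similarity matrix per scan, and the stacked edge
#' table (rows = scans, columns = canonical edges) that all downstream
#' statistics consume.
#'
#' @param scans list of `scan_record`
#' @param config a [kinetics_config()]
#' @return list with `matrices` (named list of similarity matrices),
#'   `edges` (scans x edges matrix), `standardization` (fit params) and
#'   `features` (the standardized long table)
#' @export
build_cohort_networks <- function(scans, config = kinetics_config()) {
  ft <- cohort_features(scans, config)
  std <- robust_standardize(ft)
  feats <- .feature_cols(std$table)
  mats <- lapply(split(std$table, factor(std$table$scan_id,
                                         levels = unique(std$table$scan_id))),
                 function(tab) {
    m <- as.matrix(tab[, feats, drop = FALSE])
    rownames(m) <- tab$roi
    build_similarity_matrix(m)
  })
  edges <- do.call(rbind, lapply(mats, edge_vector))
  rownames(edges) <- names(mats)
  list(matrices = mats, edges = edges,
       standardization = std$params, features = std$table)
}

#' Inter-subject consistency of network patterns
#'
#' Pairwise Spearman correlations between the edge vectors of (typically
#' healthy-control) scans, summarized as median +/- raw MAD globally and by
#' tracer stratum (intra- and inter-tracer).
#'
#' @param edges scans x edges matrix
#' @param tracer optional tracer label per scan for stratified summaries
#' @return list with `correlation` (scans x scans Spearman matrix),
#'   `global`, `intra`, `inter` (each median + mad over the off-diagonal
#'   pairs of the stratum)
#' @export
cohort_consistency <- function(edges, tracer = NULL) {
  if (nrow(edges) < 2) stop("need at least 2 scans")
  rho <- stats::cor(t(edges), method = "spearman")
  diag(rho) <- 1
  ut <- upper.tri(rho)
  summ <- function(v) {
    m <- stats::median(v)
    c(median = m, mad = stats::median(abs(v - m)))
  }
  out <- list(correlation = rho, global = summ(rho[ut]))
  if (!is.null(tracer)) {
    tr <- as.character(tracer)
    same <- outer(tr, tr, "==")
    intra <- lapply(unique(tr), function(g) {
      sel <- ut & outer(tr == g, tr == g, "&")
      if (any(sel)) summ(rho[sel]) else NULL
    })
    names(intra) <- unique(tr)
    out$intra <- Filter(Negate(is.null), intra)
    if (length(unique(tr)) >= 2) {
      pairs <- utils::combn(unique(tr), 2, simplify = FALSE)
      inter <- lapply(pairs, function(p) {
        sel <- ut & (outer(tr == p[1], tr == p[2], "&") |
                       outer(tr == p[2], tr == p[1], "&"))
        if (any(sel)) summ(rho[sel]) else NULL
      })
      names(inter) <- vapply(pairs, paste, "", collapse = " vs ")
      out$inter <- Filter(Negate(is.null), inter)
    }
  }
  out
}
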
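# Reliability analyses: pharmacological-blocking comparison, test-retest
# correlation, edgewise ICC(3,1), and retest identification (fingerprinting).

#' Median upper-triangle similarity of a matrix
#'
#' The per-scan blocking statistic: the median over the strict upper
#' triangle (diagonal excluded).
#'
#' @param S similarity matrix
#' @return scalar median
#' @export
median_similarity <- function(S) {
  stats::median(S[upper.tri(S)])
}

#' Compare network similarity before and after target blockade
#'
#' Tests whether pharmacological blockade flattens the inter-regional
#' signal distribution — i.e. raises the per-scan median similarity — with
#' a one-tailed Wilcoxon signed-rank test (alternative: post > pre). Zero
#' differences are dropped (signed-rank convention); the null is exact for
#' n <= 25 untied pairs, normal with continuity correction otherwise.
#'
#' @param pre_matrices,post_matrices paired lists of similarity matrices
#'   (same subjects, same order)
#' @return list: per-subject `pre`/`post` medians, `pct_increase` (mean
#'   percentage increase), `p_value`, `n_effective` (nonzero differences)
#' @export
blocking_comparison <- function(pre_matrices, post_matrices) {
  if (length(pre_matrices) != length(post_matrices)) {
    stop("pre and post lists must be paired (equal length)")
  }
  if (length(pre_matrices) < 1) stop("need at least one pair")
  pre <- vapply(pre_matrices, median_similarity, numeric(1))
  post <- vapply(post_matrices, median_similarity, numeric(1))
  d <- post - pre
  dnz <- d[d != 0]
  if (length(dnz) == 0) stop("no signed ranks: all paired differences are zero")
  exact <- length(dnz) <= 25 && !any(duplicated(abs(dnz)))
  p <- suppressWarnings(
    stats::wilcox.test(dnz, alternative = "greater", mu = 0,
                       exact = exact, correct = TRUE)$p.value)
  list(pre = pre, post = post,
       pct_increase = mean((post - pre) / pre) * 100,
       p_value = p, n_effective = length(dnz))
}

#' Per-subject test-retest Spearman correlation of edge vectors
#'
#' @param test_edges,retest_edges subjects x edges matrices with matching
#'   rownames (subject ids) or matched row order
#' @return named numeric vector of per-subject rho, with attributes `mean`
#'   and `sd`
#' @export
testretest_correlation <- function(test_edges, retest_edges) {
  if (!identical(dim(test_edges), dim(retest_edges))) {
    stop("test and retest edge tables must have identical dimensions")
  }
  rho <- vapply(seq_len(nrow(test_edges)), function(i) {
    stats::cor(test_edges[i, ], retest_edges[i, ], method = "spearman")
  }, numeric(1))
  names(rho) <- rownames(test_edges)
  attr(rho, "mean") <- mean(rho)
  attr(rho, "sd") <- stats::sd(rho)
  rho
}

#' Edgewise test-retest ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measurement intraclass
#' correlation per edge: ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E) with
#' k = 2 sessions, where MS_R is the between-subject and MS_E the residual
#' mean square of the subject x session ANOVA.
#'
#' @param test_set,retest_set subjects x edges matrices (>= 3 complete
#'   subject pairs, matched rows)
#' @return list: `icc` per-edge vector, `median`, `mad` (raw MAD)
#' @export
edgewise_icc <- function(test_set, retest_set) {
  if (!identical(dim(test_set), dim(retest_set))) {
    stop("test and retest sets must have identical dimensions")
  }
  n <- nrow(test_set)
  if (n < 3) stop("need at least 3 complete subject pairs, got ", n)
  k <- 2
  subj_mean <- (test_set + retest_set) / 2
  sess_mean_1 <- colMeans(test_set)
  sess_mean_2 <- colMeans(retest_set)
  grand <- (sess_mean_1 + sess_mean_2) / 2
  ss_subj <- k * colSums(sweep(subj_mean, 2, grand)^2)
  ss_sess <- n * ((sess_mean_1 - grand)^2 + (sess_mean_2 - grand)^2)
  ss_tot <- colSums(sweep(test_set, 2, grand)^2) +
    colSums(sweep(retest_set, 2, grand)^2)
  ms_r <- ss_subj / (n - 1)
  ms_e <- pmax(0, ss_tot - ss_subj - ss_sess) / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  med <- stats::median(icc)
  list(icc = icc, median = med, mad = stats::median(abs(icc - med)))
}

#' Retest identification (connectome-style fingerprinting)
#'
#' For each test scan, retest scans are ranked by Spearman correlation of
#' edge vectors; the identification is correct when the top-ranked retest
#' belongs to the same subject. Exact correlation ties go to the first
#' index, with a warning.
#'
#' @param test_edge_vectors,retest_edge_vectors subjects x edges matrices,
#'   rows matched by subject (same order)
#' @return list: `accuracy`, `match` data.frame (subject, top_match,
#'   rank_of_true, rho_true), `rho` the test x retest Spearman matrix
#' @export
identify_subjects <- function(test_edge_vectors, retest_edge_vectors) {
  if (nrow(test_edge_vectors) != nrow(retest_edge_vectors)) {
    stop("test and retest sets must contain the same subjects")
  }
  n <- nrow(test_edge_vectors)
  rho <- stats::cor(t(test_edge_vectors), t(retest_edge_vectors),
                    method = "spearman")
  subj <- rownames(test_edge_vectors)
  if (is.null(subj)) subj <- as.character(seq_len(n))
  top <- integer(n)
  rank_true <- integer(n)
  for (i in seq_len(n)) {
    r <- rho[i, ]
    if (anyDuplicated(r[r == max(r)]) > 0 && sum(r == max(r)) > 1) {
      warning("identification tie for test scan ", subj[i],
              "; first index wins")
    }
    top[i] <- which.max(r)
    rank_true[i] <- rank(-r, ties.method = "first")[i]
  }
  list(
    accuracy = mean(top == seq_len(n)),
    match = data.frame(subject = subj, top_match = subj[top],
                       rank_of_true = rank_true,
                       rho_true = rho[cbind(seq_len(n), seq_len(n))],
                       stringsAsFactors = FALSE),
    rho = rho
  )
}
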
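# Differential abundance: eligibility prefilter, Wilcoxon rank-sum,
# Storey q-values and the dual significance criterion
# (q < 0.05 AND |median difference| > 5 normalized counts).

#' Eligibility prefilter for differential testing
#'
#' Keeps features with more than `min_count` spectral counts in at least
#' `min_runs` of the runs belonging to the two groups under comparison
#' (pooled across both groups; both bounds follow the printed rule "more than
#' five spectral counts in four or more of the runs").
#'
#' @param counts matrix features x runs (normalized counts).
#' @param groups list of two character vectors of run ids.
#' @param min_count strict count threshold (default 5).
#' @param min_runs minimum number of qualifying runs (default 4).
#' @return character vector of eligible feature ids.
#' @export
prefilter_features <- function(counts, groups, min_count = 5, min_runs = 4) {
  stopifnot(length(groups) == 2L)
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 runs", call. = FALSE)
  runs <- unlist(groups)
  if (!all(runs %in% colnames(counts)))
    stop("group run ids missing from count matrix", call. = FALSE)
  m <- counts[, runs, drop = FALSE]
  rownames(m)[rowSums(m > min_count) >= min_runs]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution by enumeration of all group labelings when the
#' combined sample size is at most `exact_max_n` and there are no ties;
#' otherwise mid-ranks with the tie-corrected normal approximation. The
#' two-sided exact p-value is the proportion of labelings whose rank-sum
#' deviates from its mean at least as much as observed. Symmetric under
#' swapping the groups; identical values across both groups give p = 1.
#'
#' @param x,y numeric vectors of per-run counts (each length >= 2).
#' @param exact_max_n largest combined size for exact enumeration (default 12).
#' @return two-sided p-value.
#' @examples
#' wilcoxon_p(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
wilcoxon_p <- function(x, y, exact_max_n = 12L) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  v <- c(x, y)
  if (length(unique(v)) == 1L) return(1.0)
  m <- length(x); nn <- length(y); N <- m + nn
  r <- rank(v)
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  if (N <= exact_max_n && !anyDuplicated(v)) {
    splits <- combn(N, m)
    stats <- colSums(matrix(r[splits], nrow = m))
    mean(abs(stats - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(v)
    sigma2 <- m * nn / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1.0)
    z <- (W - mu) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Storey q-values
#'
#' `pi0` is estimated as `#\{p > lambda\} / ((1 - lambda) m)` at a fixed
#' `lambda` (default 0.5), clamped to `[1/m, 1]`; q-values are the step-down
#' minima `q_(i) = min_(j >= i) pi0 m p_(j) / j` on the sorted p-values,
#' capped at 1. With `pi0` forced to 1 this reduces exactly to
#' Benjamini-Hochberg.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param lambda tuning parameter for the pi0 estimate (default 0.5).
#' @param pi0 optional fixed pi0 overriding the estimate.
#' @return q-values in the input order (empty input gives empty output).
#' @examples
#' storey_q(c(0.125, 0.375, 0.625, 0.875))  # pi0 = 1; 0.5 0.75 0.8333 0.875
#' @export
storey_q <- function(p, lambda = 0.5, pi0 = NULL) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(pi0)) {
    pi0 <- sum(p > lambda) / ((1 - lambda) * m)
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

#' Call differentially abundant features between two groups
#'
#' The full decision procedure: eligibility prefilter, per-feature Wilcoxon
#' rank-sum p-value, Storey q-values across the prefiltered set, and the dual
#' criterion — a feature is significant iff `q < alpha_q` and the absolute
#' difference of its group medians exceeds `min_median_diff` normalized
#' counts. Works identically for clusters, COGs, genera, human proteins or
#' modules.
#'
#' @param counts normalized count matrix, features x runs.
#' @param group_a,group_b character vectors of run ids (>= 2 each).
#' @param alpha_q q-value threshold (default 0.05).
#' @param min_median_diff strict threshold on |median_a - median_b|
#'   (default 5).
#' @param min_count,min_runs prefilter parameters (see
#'   [prefilter_features()]).
#' @param lambda Storey lambda.
#' @param pi0 optional fixed pi0 (1 recovers Benjamini-Hochberg).
#' @return data.frame with one row per eligible feature: feature_id,
#'   median_a, median_b, median_diff, p, q, significant, direction. Features
#'   excluded by the prefilter are absent. If fewer than 2 features are
#'   eligible the result carries a `low_power = TRUE` attribute.
#' @export
call_differential <- function(counts, group_a, group_b, alpha_q = 0.05,
                              min_median_diff = 5, min_count = 5,
                              min_runs = 4, lambda = 0.5, pi0 = NULL) {
  eligible <- prefilter_features(counts, list(group_a, group_b),
                                 min_count, min_runs)
  k <- length(eligible)
  out <- data.frame(feature_id = eligible,
                    median_a = rep(NA_real_, k), median_b = rep(NA_real_, k),
                    median_diff = rep(NA_real_, k), p = rep(NA_real_, k),
                    q = rep(NA_real_, k), significant = rep(FALSE, k),
                    direction = rep(NA_character_, k),
                    stringsAsFactors = FALSE)
  if (length(eligible)) {
    for (i in seq_along(eligible)) {
      xa <- counts[eligible[i], group_a]
      xb <- counts[eligible[i], group_b]
      out$median_a[i] <- median(xa)
      out$median_b[i] <- median(xb)
      out$p[i] <- wilcoxon_p(xa, xb)
    }
    out$median_diff <- out$median_a - out$median_b
    out$q <- storey_q(out$p, lambda = lambda, pi0 = pi0)
    out$significant <- out$q < alpha_q & abs(out$median_diff) > min_median_diff
    out$direction <- ifelse(out$median_diff > 0, "higher_in_a",
                            ifelse(out$median_diff < 0, "higher_in_b", "none"))
  }
  if (length(eligible) < 2L) attr(out, "low_power") <- TRUE
  out
}
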
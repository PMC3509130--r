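# KEGG-module level analysis: coverage gating, module abundance, differential
# testing with Benjamini-Hochberg FDR, and deviation of a (taxon, module)
# abundance shift from the taxon's own abundance shift.

#' Module coverage gate
#'
#' Coverage is the fraction of a module's member KOs that were detected;
#' modules pass when coverage exceeds `min_coverage` strictly (more than 30%
#' by default).
#'
#' @param detected_kos character vector of detected KO ids.
#' @param module_defs data.frame with `module_id`, `ko_id`.
#' @param min_coverage strict lower bound (default 0.3).
#' @return data.frame with `module_id`, `n_members`, `n_detected`,
#'   `coverage`, `pass`.
#' @export
module_coverage <- function(detected_kos, module_defs, min_coverage = 0.3) {
  stopifnot(all(c("module_id", "ko_id") %in% names(module_defs)))
  mods <- split(module_defs$ko_id, module_defs$module_id)
  mods <- lapply(mods, function(k) unique(k[!is.na(k) & nzchar(k)]))
  if (any(lengths(mods) == 0L))
    stop("module definition error: module with empty member set", call. = FALSE)
  out <- data.frame(
    module_id = names(mods),
    n_members = lengths(mods),
    n_detected = vapply(mods, function(k) sum(unique(k) %in% detected_kos),
                        integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$coverage <- out$n_detected / out$n_members
  out$pass <- out$coverage > min_coverage
  out
}

#' Module abundance matrix
#'
#' Module abundance is the sum of member-KO normalized spectral counts per
#' run; with `annotations` carrying a genus, abundances are computed per
#' (taxon, module) pair (row names `genus|module`). Aggregation commutes with
#' run normalization.
#'
#' @param counts matrix of feature counts (clusters or KOs) x runs.
#' @param annotations data.frame mapping `feature_id` to `ko` (and optional
#'   `genus`).
#' @param module_defs data.frame with `module_id`, `ko_id`.
#' @param by_taxon aggregate per (genus, module) instead of per module.
#' @return matrix modules (or genus|module) x runs.
#' @export
module_abundance <- function(counts, annotations, module_defs,
                             by_taxon = FALSE) {
  ann <- annotations[annotations$feature_id %in% rownames(counts), ,
                     drop = FALSE]
  merged <- merge(ann, module_defs, by.x = "ko", by.y = "ko_id")
  if (nrow(merged) == 0L)
    return(matrix(numeric(0), 0, ncol(counts),
                  dimnames = list(NULL, colnames(counts))))
  key <- if (by_taxon) paste(merged$genus, merged$module_id, sep = "|")
  else merged$module_id
  m <- counts[merged$feature_id, , drop = FALSE]
  rowsum(m, group = key)
}

#' Differential modules between two groups
#'
#' Wilcoxon rank-sum per module with Benjamini-Hochberg adjustment; a module
#' is significant iff its adjusted p-value is below `fdr` and the absolute
#' difference of group medians exceeds `min_median_diff` (two-sided).
#'
#' @param counts module abundance matrix (normalized), modules x runs.
#' @param group_a,group_b run id vectors.
#' @param fdr BH threshold (default 0.10).
#' @param min_median_diff strict median-difference threshold (default 5).
#' @return data.frame: module_id, median_a, median_b, median_diff, p, p_adj,
#'   significant, direction.
#' @export
differential_modules <- function(counts, group_a, group_b, fdr = 0.10,
                                 min_median_diff = 5) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  mods <- rownames(counts)
  out <- data.frame(module_id = mods, median_a = NA_real_,
                    median_b = NA_real_, median_diff = NA_real_,
                    p = NA_real_, p_adj = NA_real_, significant = FALSE,
                    direction = NA_character_, stringsAsFactors = FALSE)
  if (length(mods) == 0L) return(out)
  for (i in seq_along(mods)) {
    xa <- counts[mods[i], group_a]
    xb <- counts[mods[i], group_b]
    out$median_a[i] <- median(xa)
    out$median_b[i] <- median(xb)
    out$p[i] <- wilcoxon_p(xa, xb)
  }
  out$median_diff <- out$median_a - out$median_b
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr & abs(out$median_diff) > min_median_diff
  out$direction <- ifelse(out$median_diff > 0, "higher_in_a",
                          ifelse(out$median_diff < 0, "higher_in_b", "none"))
  out
}

#' Log2 fold change of group medians with a pseudo-count
#'
#' `log2((median_b + pseudo) / (median_a + pseudo))`; the pseudo-count of one
#' stabilizes modules/taxa with zero counts in a group.
#'
#' @param counts matrix features x runs.
#' @param group_a,group_b run id vectors.
#' @param pseudo pseudo-count (default 1).
#' @return named numeric vector of log2 fold changes (B vs A).
#' @export
group_lfc <- function(counts, group_a, group_b, pseudo = 1) {
  ma <- apply(counts[, group_a, drop = FALSE], 1, median)
  mb <- apply(counts[, group_b, drop = FALSE], 1, median)
  log2((mb + pseudo) / (ma + pseudo))
}

#' Deviation of module abundance shifts from their host taxon's shift
#'
#' Fits ordinary least squares of the observed (taxon, module) log2 fold
#' change against the expected value — the taxon's own abundance log2 fold
#' change — over all points, and flags points falling outside the per-point
#' prediction interval at `level`. Module-level significance (from
#' [differential_modules()]) is carried through so flags report both axes.
#'
#' @param points data.frame with `taxon`, `module_id`, `observed_lfc`,
#'   `expected_lfc` and optionally `significant`.
#' @param level prediction-interval level (default 0.95).
#' @return the input with `fitted_value`, `interval_low`, `interval_high`,
#'   `deviating` columns appended; the fitted `lm` is attached as the
#'   `model` attribute.
#' @export
taxon_module_deviation <- function(points, level = 0.95) {
  stopifnot(all(c("observed_lfc", "expected_lfc") %in% names(points)))
  if (nrow(points) < 3L)
    stop("need at least 3 (taxon, module) points to fit a line", call. = FALSE)
  if (var(points$expected_lfc) == 0)
    stop("degenerate fit: all expected_lfc values are equal", call. = FALSE)
  fit <- lm(observed_lfc ~ expected_lfc, data = points)
  # predict()s in-sample prediction-interval warning is the intended use here
  pr <- suppressWarnings(predict(fit, interval = "prediction", level = level))
  points$fitted_value <- pr[, "fit"]
  points$interval_low <- pr[, "lwr"]
  points$interval_high <- pr[, "upr"]
  points$deviating <- points$observed_lfc < points$interval_low |
    points$observed_lfc > points$interval_high
  if (!"significant" %in% names(points)) points$significant <- NA
  attr(points, "model") <- fit
  points
}
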
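# Spectrum-level acceptance rules and target-decoy FDR estimation.

#' Filter policy for peptide-spectrum matches
#'
#' The acceptance thresholds applied to every PSM: charge-dependent XCorr
#' floors (boundary inclusive), a deltCN floor of 0 (no gate beyond
#' non-negativity), up to 4 internal missed cleavages, fully tryptic termini,
#' a closed ppm window (applied only for matched-metagenome searches), and a
#' protein-level minimum of 2 distinct peptides.
#'
#' @param xcorr_min_by_charge named numeric vector of XCorr floors for charges
#'   1..3; charges above 3 use the charge-3 threshold.
#' @param deltcn_min minimum deltCN (default 0).
#' @param max_miscleavages maximum internal missed cleavages (default 4).
#' @param require_fully_tryptic require tryptic N- and C-termini.
#' @param ppm_window closed interval for the precursor mass error (ppm),
#'   applied in MM searches.
#' @param min_peptides_per_protein distinct peptides required to retain a
#'   protein (default 2).
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(xcorr_min_by_charge = c(`1` = 1.8, `2` = 2.5,
                                                  `3` = 3.5),
                          deltcn_min = 0.0,
                          max_miscleavages = 4L,
                          require_fully_tryptic = TRUE,
                          ppm_window = c(-10, 10),
                          min_peptides_per_protein = 2L) {
  stopifnot(all(is.finite(xcorr_min_by_charge)), is.finite(deltcn_min),
            length(ppm_window) == 2L, ppm_window[1] <= ppm_window[2])
  structure(list(xcorr_min_by_charge = xcorr_min_by_charge,
                 deltcn_min = deltcn_min,
                 max_miscleavages = as.integer(max_miscleavages),
                 require_fully_tryptic = isTRUE(require_fully_tryptic),
                 ppm_window = ppm_window,
                 min_peptides_per_protein = as.integer(min_peptides_per_protein)),
            class = "filter_policy")
}

# Fully tryptic status from flanking residues ("-" marks a protein terminus).
# N-side: preceded by K/R (and the peptide must not start with P, since
# trypsin does not cleave before proline) or protein N-terminus.
# C-side: ends in K/R with the next residue not P, or protein C-terminus.
is_fully_tryptic <- function(peptide, prev_aa, next_aa) {
  first <- substr(peptide, 1L, 1L)
  last <- substr(peptide, nchar(peptide), nchar(peptide))
  n_ok <- prev_aa == "-" | (prev_aa %in% c("K", "R") & first != "P")
  c_ok <- next_aa == "-" | (last %in% c("K", "R") & next_aa != "P")
  n_ok & c_ok
}

#' Filter PSMs by spectrum-level acceptance rules
#'
#' Retains exactly the PSMs that are fully tryptic, have at most
#' `max_miscleavages` internal missed cleavages, reach the charge-dependent
#' XCorr floor (inclusive), have deltCN at or above the floor, and — for MM
#' searches — a ppm error inside the closed window. PSMs with missing
#' flanking information are rejected (tallied in the `n_missing_flanks`
#' attribute). Charges above 3 use the charge-3 XCorr threshold.
#'
#' @param psms data.frame in the PSM schema (see [simulate_psm_tables()]).
#' @param policy a [filter_policy()].
#' @param search_kind `"MM"` (matched metagenome; ppm window applies) or
#'   `"HMRG"` (reference genomes; no ppm gate).
#' @param keep_all if TRUE return all rows with `accepted` and `reason`
#'   columns instead of the accepted subset.
#' @return accepted PSM rows (or annotated full table when `keep_all`).
#' @export
filter_psms <- function(psms, policy = filter_policy(),
                        search_kind = c("MM", "HMRG"), keep_all = FALSE) {
  search_kind <- match.arg(search_kind)
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(psms)
  reason <- character(n)
  flank_missing <- is.na(psms$prev_aa) | is.na(psms$next_aa) |
    psms$prev_aa == "" | psms$next_aa == ""
  if (any(flank_missing)) {
    warning(sprintf("%d PSMs rejected for missing flanking residues",
                    sum(flank_missing)), call. = FALSE)
    reason[flank_missing] <- "missing_flanks"
  }
  ok <- !flank_missing
  if (policy$require_fully_tryptic) {
    tryp <- is_fully_tryptic(psms$peptide, psms$prev_aa, psms$next_aa)
    reason[ok & !tryp] <- "not_fully_tryptic"
    ok <- ok & tryp
  }
  mc <- count_missed_cleavages(psms$peptide)
  reason[ok & mc > policy$max_miscleavages] <- "miscleavages"
  ok <- ok & mc <= policy$max_miscleavages
  ch <- pmin(pmax(as.integer(psms$charge), 1L),
             max(as.integer(names(policy$xcorr_min_by_charge))))
  thr <- policy$xcorr_min_by_charge[as.character(ch)]
  reason[ok & psms$xcorr < thr] <- "xcorr"
  ok <- ok & psms$xcorr >= thr
  reason[ok & psms$deltcn < policy$deltcn_min] <- "deltcn"
  ok <- ok & psms$deltcn >= policy$deltcn_min
  if (search_kind == "MM") {
    in_win <- psms$ppm_error >= policy$ppm_window[1] &
      psms$ppm_error <= policy$ppm_window[2]
    reason[ok & !in_win] <- "ppm"
    ok <- ok & in_win
  }
  if (keep_all) {
    psms$accepted <- ok
    psms$reason <- ifelse(ok, "", reason)
    out <- psms
  } else {
    out <- psms[ok, , drop = FALSE]
  }
  attr(out, "n_missing_flanks") <- sum(flank_missing)
  out
}

#' Protein-level peptide-count filter
#'
#' HMRG searches keep proteins identified by at least
#' `min_peptides_per_protein` distinct peptide sequences. MM searches accept
#' read-level identifications at one peptide, then require the distinct
#' peptide minimum per ortholog cluster (supply `cluster_map`). PSMs whose
#' matched proteins are all dropped are discarded. Decoy PSMs pass through
#' unchanged: decoy counting happens at the peptide level ([estimate_fdr()]).
#'
#' @param psms spectrum-level accepted PSMs.
#' @param search_kind `"MM"` or `"HMRG"`.
#' @param policy a [filter_policy()].
#' @param cluster_map named character vector protein id -> cluster id
#'   (required for MM).
#' @return list with `psms` (retained PSMs) and `retained` (character vector
#'   of retained protein or cluster ids).
#' @export
protein_level_filter <- function(psms, search_kind = c("MM", "HMRG"),
                                 policy = filter_policy(),
                                 cluster_map = NULL) {
  search_kind <- match.arg(search_kind)
  is_dec <- as.logical(psms$is_decoy)
  targets <- psms[!is_dec, , drop = FALSE]
  decoys <- psms[is_dec, , drop = FALSE]
  if (nrow(targets) == 0L)
    return(list(psms = psms, retained = character(0)))
  ids <- strsplit(targets$protein_ids, ";", fixed = TRUE)
  if (search_kind == "MM") {
    if (is.null(cluster_map))
      stop("MM protein-level filtering requires a cluster_map", call. = FALSE)
    feat <- lapply(ids, function(p) {
      cl <- cluster_map[p]
      # unmapped reads are their own singleton feature
      cl[is.na(cl)] <- paste0("SGL_", p[is.na(cl)])
      unique(cl)
    })
  } else {
    feat <- lapply(ids, unique)
  }
  pep_per_feat <- tapply(
    rep(targets$peptide, lengths(feat)), unlist(feat),
    function(x) length(unique(x)))
  retained <- names(pep_per_feat)[pep_per_feat >= policy$min_peptides_per_protein]
  keep <- vapply(feat, function(f) any(f %in% retained), logical(1))
  out <- rbind(targets[keep, , drop = FALSE], decoys)
  rownames(out) <- NULL
  list(psms = out, retained = retained)
}

#' Empirical FDR from a concatenated target-decoy search
#'
#' Returns `2 * D / (T + D)` where `D` and `T` are the decoy and target PSMs
#' passing all filters: in a concatenated search an incorrect match falls on
#' the target and decoy halves with equal probability, so `2D` estimates the
#' total number of incorrect matches among the `T + D` accepted PSMs. The
#' simple decoy/target ratio `D / T` is available as an alternative. The
#' estimate is capped at 1; an empty input yields `NA`.
#'
#' @param psms filtered PSMs carrying `is_decoy`.
#' @param method `"concatenated"` (default) or `"ratio"`.
#' @return FDR as a fraction in `[0, 1]`, or `NA` when no PSMs.
#' @examples
#' psms <- data.frame(is_decoy = rep(c(FALSE, TRUE), c(98, 2)))
#' estimate_fdr(psms)  # 0.04
#' @export
estimate_fdr <- function(psms, method = c("concatenated", "ratio")) {
  method <- match.arg(method)
  d <- sum(as.logical(psms$is_decoy))
  t <- sum(!as.logical(psms$is_decoy))
  if (t + d == 0L) return(NA_real_)
  est <- if (method == "concatenated") 2 * d / (t + d)
  else if (t == 0L) Inf else d / t
  min(est, 1)
}

#' Per-run and pooled FDR report
#'
#' @inheritParams estimate_fdr
#' @return data.frame with one row per run plus a `pooled` row: run_id,
#'   n_target, n_decoy, fdr.
#' @export
fdr_report <- function(psms, method = c("concatenated", "ratio")) {
  method <- match.arg(method)
  runs <- c(sort(unique(psms$run_id)), "pooled")
  do.call(rbind, lapply(runs, function(r) {
    sub <- if (r == "pooled") psms else psms[psms$run_id == r, , drop = FALSE]
    data.frame(run_id = r,
               n_target = sum(!as.logical(sub$is_decoy)),
               n_decoy = sum(as.logical(sub$is_decoy)),
               fdr = estimate_fdr(sub, method),
               stringsAsFactors = FALSE)
  }))
}
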
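# Spectral-count attribution and cross-run normalization.

split_ids <- function(x) strsplit(x, ";", fixed = TRUE)

#' Attribute spectra to features by unique cluster membership
#'
#' A peptide contributes its spectra to a feature (ortholog cluster, genus,
#' COG, ...) only when every protein it matches maps to that single feature;
#' peptides spanning two or more features contribute nothing. Decoy PSMs are
#' ignored.
#'
#' @param psms accepted PSMs.
#' @param feature_map named character vector protein id -> feature id. Every
#'   non-decoy protein id in `psms` must be present.
#' @param runs optional character vector fixing the column order.
#' @param shared_label if non-NULL, spectra discarded for spanning multiple
#'   features are tallied in a row with this name (used for conservation
#'   accounting).
#' @return integer matrix features x runs of raw spectral counts.
#' @export
attribute_spectra <- function(psms, feature_map, runs = NULL,
                              shared_label = NULL) {
  psms <- psms[!as.logical(psms$is_decoy), , drop = FALSE]
  if (is.null(runs)) runs <- sort(unique(psms$run_id))
  ids <- split_ids(psms$protein_ids)
  unknown <- setdiff(unique(unlist(ids)), names(feature_map))
  if (length(unknown))
    stop("PSMs reference unknown protein ids: ",
         paste(head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) sprintf(" (and %d more)", length(unknown) - 5),
         call. = FALSE)
  feat <- vapply(ids, function(p) {
    f <- unique(feature_map[p])
    if (length(f) == 1L) f else NA_character_
  }, character(1))
  features <- sort(unique(feature_map))
  if (!is.null(shared_label)) features <- c(features, shared_label)
  counts <- matrix(0L, length(features), length(runs),
                   dimnames = list(features, runs))
  tab_feat <- ifelse(is.na(feat),
                     if (is.null(shared_label)) NA_character_ else shared_label,
                     feat)
  keep <- !is.na(tab_feat) & psms$run_id %in% runs
  if (any(keep)) {
    tb <- table(factor(tab_feat[keep], levels = features),
                factor(psms$run_id[keep], levels = runs))
    counts[] <- as.integer(tb)
  }
  counts
}

#' Spectral counts for human proteins
#'
#' Human proteins are counted from both unique and non-unique peptide
#' identifications: a shared peptide contributes its spectra to every human
#' protein it matches.
#'
#' @param psms accepted PSMs.
#' @param human_ids character vector of human protein ids.
#' @param runs optional run order.
#' @return integer matrix human proteins x runs (empty when no human PSMs).
#' @export
human_protein_counts <- function(psms, human_ids, runs = NULL) {
  psms <- psms[!as.logical(psms$is_decoy), , drop = FALSE]
  if (is.null(runs)) runs <- sort(unique(psms$run_id))
  ids <- split_ids(psms$protein_ids)
  hits <- lapply(ids, function(p) intersect(unique(p), human_ids))
  nh <- lengths(hits)
  if (sum(nh) == 0L)
    return(matrix(0L, 0, length(runs), dimnames = list(NULL, runs)))
  long <- data.frame(protein = unlist(hits),
                     run_id = rep(psms$run_id, nh))
  tb <- table(factor(long$protein, levels = sort(unique(long$protein))),
              factor(long$run_id, levels = runs))
  counts <- matrix(as.integer(tb), nrow = nrow(tb),
                   dimnames = dimnames(tb))
  counts
}

#' Run profiles with scaling factors
#'
#' `alpha_i = N / n_i`, where `n_i` is run i's total acquired MS/MS count and
#' `N` the cohort mean of the `n_i`.
#'
#' @param metadata data.frame with `run_id`, `sample_id`, `group`, `n_i`.
#' @return the input with an `alpha_i` column appended.
#' @export
make_run_profiles <- function(metadata) {
  if (!all(c("run_id", "n_i") %in% names(metadata)))
    stop("metadata must contain run_id and n_i", call. = FALSE)
  if (anyNA(metadata$n_i) || any(metadata$n_i <= 0))
    stop("every run needs a positive total MS/MS count n_i", call. = FALSE)
  metadata$alpha_i <- mean(metadata$n_i) / metadata$n_i
  metadata
}

#' Normalize raw spectral counts across runs
#'
#' Multiplies every run's raw counts by its scaling factor
#' `alpha_i = N / n_i`. When the matrix accounts for all `n_i` spectra of a
#' run, its post-normalization column total equals `N` exactly; the
#' transformation is invariant to rescaling all `n_i` by a common factor.
#'
#' @param counts raw count matrix, features x runs (columns named by run id).
#' @param run_profiles output of [make_run_profiles()] (an `alpha_i` column
#'   is computed if absent).
#' @return numeric matrix of normalized counts with `alpha` and `N`
#'   attributes.
#' @examples
#' m <- matrix(4, 1, 3, dimnames = list("f", c("a", "b", "c")))
#' rp <- make_run_profiles(data.frame(run_id = c("a", "b", "c"),
#'                                    n_i = c(8000, 10000, 12000)))
#' normalize_counts(m, rp)  # alpha = 1.25, 1, 0.8333...
#' @export
normalize_counts <- function(counts, run_profiles) {
  if (!"alpha_i" %in% names(run_profiles))
    run_profiles <- make_run_profiles(run_profiles)
  miss <- setdiff(colnames(counts), run_profiles$run_id)
  if (length(miss))
    stop("runs missing n_i: ", paste(miss, collapse = ", "), call. = FALSE)
  alpha <- setNames(run_profiles$alpha_i, run_profiles$run_id)[colnames(counts)]
  out <- sweep(counts, 2, alpha, "*")
  attr(out, "alpha") <- alpha
  attr(out, "N") <- mean(run_profiles$n_i)
  out
}

#' Aggregate a feature-level matrix to a coarser level
#'
#' Sums member-feature counts (e.g. cluster -> COG, cluster -> genus or
#' KO -> module). Aggregation commutes with run normalization.
#'
#' @param counts matrix features x runs.
#' @param feature_map named vector feature id -> aggregate id; features
#'   absent from the map are dropped.
#' @return matrix aggregates x runs.
#' @export
aggregate_features <- function(counts, feature_map) {
  keep <- rownames(counts) %in% names(feature_map)
  m <- counts[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(matrix(numeric(0), 0, ncol(counts),
                  dimnames = list(NULL, colnames(counts))))
  g <- feature_map[rownames(m)]
  rowsum(m, group = g)
}
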
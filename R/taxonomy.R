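# Nearest-neighbor taxonomic assignment and rarefied annotation abundance.

HGM_FALLBACK <- "human gut microbiome"

#' Classify reads/ORFs against genus-labelled references
#'
#' Nearest-neighbor assignment: each query takes the genus of the
#' best-identity reference whose alignment reaches both the identity and
#' query-coverage thresholds. When the best identity is shared by references
#' from different genera the query stays unassigned at genus rank and
#' receives the fallback label, as does any query with no qualifying match.
#'
#' @param reads data.frame with `id`, `sequence`.
#' @param refs data.frame with `id`, `sequence`, `genus`.
#' @param min_id minimum percent identity (default 80).
#' @param min_cov minimum fraction of the query covered by the alignment
#'   (default 0.8).
#' @param fallback label for unassigned queries.
#' @return data.frame with `query_id`, `taxon`, `percent_identity`,
#'   `coverage`.
#' @export
classify_reads <- function(reads, refs, min_id = 80, min_cov = 0.8,
                           fallback = HGM_FALLBACK) {
  out <- data.frame(query_id = reads$id, taxon = fallback,
                    percent_identity = NA_real_, coverage = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(refs) == 0L) return(out)
  n <- nrow(reads)
  qlen <- nchar(reads$sequence)
  best_pi <- rep(-Inf, n)
  best_cov <- rep(NA_real_, n)
  best_genera <- vector("list", n)
  for (j in seq_len(nrow(refs))) {
    e <- aln_identity_set(reads$sequence, refs$sequence[j])
    cov_q <- e$span_q / qlen  # fraction of the query covered
    ok <- e$percent_identity >= min_id & cov_q >= min_cov
    better <- ok & e$percent_identity > best_pi + 1e-9
    tied <- ok & !better & abs(e$percent_identity - best_pi) <= 1e-9
    if (any(better)) {
      best_pi[better] <- e$percent_identity[better]
      best_cov[better] <- cov_q[better]
      best_genera[better] <- list(refs$genus[j])
    }
    for (i in which(tied))
      best_genera[[i]] <- union(best_genera[[i]], refs$genus[j])
  }
  hit <- lengths(best_genera) == 1L
  out$taxon[hit] <- unlist(best_genera[hit])
  out$percent_identity[hit] <- best_pi[hit]
  out$coverage[hit] <- best_cov[hit]
  out
}

#' Taxon of a contig from its constituent read assignments
#'
#' Majority genus among the assigned reads; a tie, or no assigned reads,
#' yields the fallback label. A spectrum inherits its protein's contig taxon.
#'
#' @param taxa character vector of per-read taxon labels (fallback labels
#'   count as unassigned).
#' @param fallback the unassigned label.
#' @return single taxon label.
#' @export
contig_taxon <- function(taxa, fallback = HGM_FALLBACK) {
  stopifnot(length(taxa) >= 1L)
  assigned <- taxa[taxa != fallback & !is.na(taxa)]
  if (length(assigned) == 0L) return(fallback)
  tb <- sort(table(assigned), decreasing = TRUE)
  if (length(tb) > 1L && tb[1] == tb[2]) return(fallback)
  names(tb)[1]
}

#' Genus relative-abundance profile from read assignments
#'
#' @param assignments output of [classify_reads()] with a `sample_id` column
#'   (or supply `sample_id` separately).
#' @param sample_id optional vector aligned with `assignments`.
#' @param drop_fallback exclude unassigned reads from the denominator.
#' @return matrix genus x sample of relative abundances.
#' @export
genus_profile <- function(assignments, sample_id = NULL,
                          drop_fallback = TRUE) {
  if (is.null(sample_id)) sample_id <- assignments$sample_id
  taxa <- assignments$taxon
  if (drop_fallback) {
    keep <- taxa != HGM_FALLBACK
    taxa <- taxa[keep]; sample_id <- sample_id[keep]
  }
  tb <- table(taxa, sample_id)
  m <- matrix(as.numeric(tb), nrow = nrow(tb), dimnames = dimnames(tb))
  sweep(m, 2, pmax(colSums(m), 1), "/")
}

#' Rarefied relative abundance of annotations
#'
#' For each sample, draws (without replacement) the smallest per-sample depth
#' from its annotated units, tallies annotation frequencies, repeats
#' `iterations` times and returns the mean relative abundance. Seeded and
#' reproducible; per-sample abundances sum to 1.
#'
#' @param counts matrix annotations x samples of non-negative integer counts.
#' @param iterations number of random subsamples (default 100).
#' @param seed integer seed.
#' @return matrix annotations x samples of mean rarefied proportions.
#' @export
rarefied_annotation_abundance <- function(counts, iterations = 100L,
                                          seed = 1L) {
  if (iterations < 1L)
    stop("invalid configuration: iterations must be >= 1", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (ncol(counts) < 1L) stop("at least one sample required", call. = FALSE)
  depth <- min(colSums(counts))
  with_seed(seed, {
    out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    for (s in seq_len(ncol(counts))) {
      pool <- rep.int(seq_len(nrow(counts)), counts[, s])
      acc <- numeric(nrow(counts))
      for (it in seq_len(iterations)) {
        draw <- if (length(pool) <= depth) pool else sample(pool, depth)
        acc <- acc + tabulate(draw, nbins = nrow(counts)) / depth
      }
      out[, s] <- acc / iterations
    }
    out
  })
}
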
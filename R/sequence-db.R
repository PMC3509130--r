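# Per-sample non-redundant protein databases and orthologous clustering of
# microbial ORFs by identity-graph Markov clustering (MCL).
#
# Local alignment scheme (fixed, documented): BLOSUM62, affine gaps with
# opening 10 and extension 0.5. Percent identity is recomputed from the
# alignment path (matches / alignment columns), so results depend only on
# the optimal path.

ALN_GAP_OPENING <- 10
ALN_GAP_EXTENSION <- 0.5

#' Remove redundant protein sequences
#'
#' Drops every protein whose full length is contained at 100% identity in a
#' longer protein (100% identity over 100% of the shorter sequence). When two
#' sequences are identical the lexicographically smaller id is kept. The
#' operation is idempotent.
#'
#' @param proteins data.frame with columns `id` and `sequence` (additional
#'   columns are carried through).
#' @return the non-redundant subset, in the input row order.
#' @examples
#' remove_redundant(data.frame(id = c("A", "B"),
#'                             sequence = c("MKLVQRST", "MKLV")))
#' @export
remove_redundant <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  check_sequences(proteins$sequence)
  if (anyDuplicated(proteins$id)) stop("protein ids must be unique", call. = FALSE)
  # equal sequences first: keep the lexicographically smallest id
  ord <- order(-nchar(proteins$sequence), proteins$id)
  keep_seq <- character(0)
  keep_idx <- integer(0)
  for (i in ord) {
    s <- proteins$sequence[i]
    contained <- any(vapply(keep_seq, function(k) {
      nchar(s) <= nchar(k) && grepl(s, k, fixed = TRUE)
    }, logical(1)))
    if (!contained) {
      keep_seq <- c(keep_seq, s)
      keep_idx <- c(keep_idx, i)
    }
  }
  proteins[sort(keep_idx), , drop = FALSE]
}

#' Percent identity of the optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps; identity is
#' the fraction of matching columns over the alignment length, and
#' `coverage_shorter` the aligned span of the shorter sequence divided by its
#' length. Symmetric in its arguments; identical sequences give identity 100
#' and coverage 1.
#'
#' @param a,b amino-acid strings.
#' @return list with `percent_identity`, `aln_length`, `coverage_shorter`.
#' @export
pairwise_identity <- function(a, b) {
  check_sequences(c(a, b))
  if (grepl("^X+$", a) || grepl("^X+$", b))
    stop("sequence consists only of ambiguous residues", call. = FALSE)
  e <- aln_identity_set(a, b)
  short_len <- min(nchar(a), nchar(b))
  span_short <- if (nchar(a) <= nchar(b)) e$span_q else e$span_s
  list(percent_identity = e$percent_identity,
       aln_length = e$aln_length,
       coverage_shorter = span_short / short_len,
       span_a = e$span_q, span_b = e$span_s)
}

# Vectorized core: local-align many queries against one subject, returning
# per-query identity/length/spans recomputed from the alignment paths.
aln_identity_set <- function(queries, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = ALN_GAP_OPENING, gapExtension = ALN_GAP_EXTENSION)
  len <- Biostrings::nchar(aln)             # alignment columns incl. gaps
  matches <- Biostrings::nmatch(aln)
  span_q <- BiocGenerics::width(Biostrings::pattern(aln)@range)
  span_s <- BiocGenerics::width(Biostrings::subject(aln)@range)
  data.frame(percent_identity = ifelse(len > 0, 100 * matches / pmax(len, 1), 0),
             aln_length = len, span_q = span_q, span_s = span_s)
}

#' All-vs-all identity edges above threshold
#'
#' Computes the identity graph used for ortholog clustering: one edge per
#' unordered pair whose local alignment reaches `min_aln_len` columns and
#' exceeds `min_identity` percent identity. The minimum alignment length
#' replaces a database-size-dependent e-value gate.
#'
#' @param proteins data.frame with `id`, `sequence`.
#' @param min_identity percent identity strict lower bound (default 80).
#' @param min_aln_len minimum local-alignment length in columns (default 30).
#' @return data.frame with `a`, `b`, `percent_identity`, `aln_length`,
#'   `coverage_shorter`.
#' @export
identity_edges <- function(proteins, min_identity = 80, min_aln_len = 30) {
  n <- nrow(proteins)
  res <- list()
  if (n >= 2L) {
    for (j in seq(2L, n)) {
      qi <- seq_len(j - 1L)
      e <- aln_identity_set(proteins$sequence[qi], proteins$sequence[j])
      keep <- e$aln_length >= min_aln_len & e$percent_identity > min_identity
      if (any(keep)) {
        short_len <- pmin(nchar(proteins$sequence[qi]),
                          nchar(proteins$sequence[j]))
        span_short <- ifelse(nchar(proteins$sequence[qi]) <=
                               nchar(proteins$sequence[j]),
                             e$span_q, e$span_s)
        res[[length(res) + 1L]] <- data.frame(
          a = proteins$id[qi][keep], b = proteins$id[j],
          percent_identity = e$percent_identity[keep],
          aln_length = e$aln_length[keep],
          coverage_shorter = (span_short / short_len)[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(a = character(0), b = character(0),
                  percent_identity = numeric(0), aln_length = integer(0),
                  coverage_shorter = numeric(0))
}

# One MCL inflation step: elementwise power then column renormalization.
.mcl_inflate <- function(M, inflation) {
  M <- M^inflation
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

#' Markov clustering of an identity graph
#'
#' Implements MCL on the thresholded similarity graph: column-stochastic
#' normalization, then alternating expansion (matrix power 2) and inflation
#' (elementwise power `inflation`, then renormalization) until the flow matrix
#' stabilizes. Self-loops (weight = maximum incident edge weight, or 1 for
#' isolated nodes) are added before normalization, standard MCL practice that
#' prevents period-2 oscillation. Read-out is attractor-based: attractors with
#' mutual flow form one cluster; every other node joins the attractor that
#' receives its largest flow, ties broken toward the smallest cluster id, so
#' output is deterministic and a partition.
#'
#' @param edges data.frame with `a`, `b` and `percent_identity` (edge weight).
#' @param nodes optional character vector of node ids; nodes without edges
#'   become singleton clusters.
#' @param min_identity edges at or below this identity are dropped (default 80).
#' @param inflation inflation exponent (default 1.5).
#' @param prune flow entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute change.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   iteration count and residual.
#' @return list of character vectors (cluster members), ordered by smallest
#'   member id.
#' @export
mcl_cluster <- function(edges, nodes = NULL, min_identity = 80,
                        inflation = 1.5, prune = 1e-8, tol = 1e-8,
                        max_iter = 200L) {
  if (nrow(edges)) edges <- edges[edges$percent_identity > min_identity, ,
                                  drop = FALSE]
  ids <- sort(unique(c(edges$a, edges$b, nodes)))
  n <- length(ids)
  if (n == 0L) return(list())
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    ai <- match(edges$a, ids); bi <- match(edges$b, ids)
    for (k in seq_along(ai)) {
      w <- edges$percent_identity[k]
      A[ai[k], bi[k]] <- max(A[ai[k], bi[k]], w)
      A[bi[k], ai[k]] <- max(A[bi[k], ai[k]], w)
    }
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  res <- NA_real_
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- .mcl_inflate(M2, inflation)
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    res <- max(abs(M2 - M))
    M <- M2
    if (res < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("MCL did not converge after %d iterations (residual %.3g)",
                 max_iter, res), call. = FALSE)
  attractors <- which(diag(M) > sqrt(.Machine$double.eps))
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # attractor systems: mutual-flow components among attractors
  comp <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
      if (comp[i] != comp[j] &&
          (M[attractors[i], attractors[j]] > 0 ||
           M[attractors[j], attractors[i]] > 0)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cluster_of_attr <- match(comp, sort(unique(comp)))
  assignment <- integer(n)
  for (j in seq_len(n)) {
    flows <- M[attractors, j]
    if (all(flows == 0)) {
      # no attractor reaches it (degenerate); make it its own cluster
      assignment[j] <- NA_integer_
    } else {
      best <- which(flows == max(flows))
      assignment[j] <- min(cluster_of_attr[best])
    }
  }
  orphan <- which(is.na(assignment))
  if (length(orphan))
    assignment[orphan] <- max(cluster_of_attr, 0L) + seq_along(orphan)
  groups <- split(ids, assignment)
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, character(1)))]
}

#' Cluster proteins into ortholog clusters
#'
#' End-to-end wrapper: identity graph above `min_identity`, MCL clustering,
#' and representative selection (longest member, ties broken by
#' lexicographically smaller id). Proteins without qualifying edges become
#' singleton clusters, so the output partitions the input.
#'
#' @inheritParams identity_edges
#' @param inflation MCL inflation (default 1.5).
#' @return object of class `ortholog_clusters`: data.frame with `cluster_id`,
#'   `member_id`, `representative_flag` plus a `representatives` attribute
#'   (named vector cluster_id -> representative id).
#' @export
cluster_proteins <- function(proteins, min_identity = 80, inflation = 1.5,
                             min_aln_len = 30) {
  edges <- identity_edges(proteins, min_identity, min_aln_len)
  groups <- mcl_cluster(edges, nodes = proteins$id,
                        min_identity = min_identity, inflation = inflation)
  cluster_table(groups, proteins)
}

# Build the cluster table + representatives from member groups.
cluster_table <- function(groups, proteins) {
  lens <- setNames(nchar(proteins$sequence), proteins$id)
  out <- do.call(rbind, lapply(seq_along(groups), function(k) {
    members <- groups[[k]]
    ml <- lens[members]
    rep_id <- members[order(-ml, members)][1]
    data.frame(cluster_id = sprintf("OC%05d", k), member_id = members,
               representative_flag = members == rep_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(cluster_id = character(0), member_id = character(0),
                      representative_flag = logical(0))
  reps <- setNames(out$member_id[out$representative_flag],
                   out$cluster_id[out$representative_flag])
  structure(out, representatives = reps, class = c("ortholog_clusters",
                                                   "data.frame"))
}

#' Map new ORFs onto existing ortholog clusters
#'
#' Each ORF is aligned against every cluster representative and assigned to
#' the cluster with the highest identity above `min_identity`; ORFs below the
#' threshold everywhere are flagged as singletons (`cluster_id = NA`).
#'
#' @param orfs data.frame with `id`, `sequence`.
#' @param clusters an `ortholog_clusters` object (see [cluster_proteins()]).
#' @param proteins data.frame with `id`, `sequence` providing representative
#'   sequences.
#' @param min_identity percent identity strict lower bound (default 80).
#' @param min_aln_len minimum alignment length (default 30).
#' @return data.frame with `orf_id`, `cluster_id` (NA for singletons),
#'   `percent_identity`.
#' @export
map_orfs_to_clusters <- function(orfs, clusters, proteins, min_identity = 80,
                                 min_aln_len = 30) {
  reps <- attr(clusters, "representatives")
  stopifnot(!is.null(reps))
  rep_seq <- setNames(proteins$sequence[match(reps, proteins$id)], names(reps))
  if (anyNA(rep_seq)) stop("representative sequences missing from proteins",
                           call. = FALSE)
  # align each distinct sequence once, then expand back to ORF ids
  uniq <- unique(orfs$sequence)
  ui <- match(orfs$sequence, uniq)
  ucl <- rep(NA_character_, length(uniq))
  upi <- rep(NA_real_, length(uniq))
  best_pi <- rep(-Inf, length(uniq))
  for (cl in names(rep_seq)) {
    e <- aln_identity_set(uniq, rep_seq[[cl]])
    better <- e$aln_length >= min_aln_len &
      e$percent_identity > min_identity & e$percent_identity > best_pi
    if (any(better)) {
      best_pi[better] <- e$percent_identity[better]
      ucl[better] <- cl
      upi[better] <- e$percent_identity[better]
    }
  }
  data.frame(orf_id = orfs$id, cluster_id = ucl[ui],
             percent_identity = upi[ui], stringsAsFactors = FALSE)
}
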
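test_that("redundancy removal keeps the longer of fully contained pairs", {
  expect_equal(remove_redundant(data.frame(
    id = c("A", "B"), sequence = c("MKLV", "MKLV")))$id, "A")
  expect_equal(remove_redundant(data.frame(
    id = c("A", "B"), sequence = c("MKLVQRST", "MKLV")))$id, "A")
  both <- remove_redundant(data.frame(
    id = c("A", "B"), sequence = c("MKLV", "MKIV")))
  expect_setequal(both$id, c("A", "B"))
  expect_equal(nrow(remove_redundant(
    data.frame(id = character(0), sequence = character(0)))), 0L)
})

test_that("redundancy removal is idempotent", {
  set.seed(42)
  seqs <- vapply(sample(20:60, 30, replace = TRUE), function(n)
    paste(sample(c("M", "K", "L", "V", "A", "G"), n, TRUE), collapse = ""),
    character(1))
  seqs <- c(seqs, substring(seqs[1:5], 2, 12))  # plant contained fragments
  prot <- data.frame(id = sprintf("p%02d", seq_along(seqs)), sequence = seqs)
  once <- remove_redundant(prot)
  expect_identical(remove_redundant(once), once)
  expect_lte(nrow(once), nrow(prot) - 5L)
})

test_that("pairwise identity is exact on identity and single substitutions", {
  e <- pairwise_identity("MKLVMKLVMK", "MKLVMKLVMK")
  expect_equal(e$percent_identity, 100)
  expect_equal(e$coverage_shorter, 1.0)
  e2 <- pairwise_identity("MKLVMKLVMK", "MKLVMKIVMK")
  expect_equal(e2$percent_identity, 90)
  expect_equal(e2$aln_length, 10L)
  # symmetric
  e3 <- pairwise_identity("MKLVMKIVMK", "MKLVMKLVMK")
  expect_equal(e3$percent_identity, e2$percent_identity)
  expect_error(pairwise_identity("XXXX", "MKLV"), "ambiguous")
})

test_that("tryptic digestion obeys the K/R-not-before-P rule", {
  d <- digest_protein("MAAAGGGKEEEFFFRHHHIIIK", max_mc = 1)
  expect_setequal(
    d$peptide,
    c("MAAAGGGK", "EEEFFFR", "HHHIIIK", "MAAAGGGKEEEFFFR",
      "EEEFFFRHHHIIIK"))
  expect_equal(d$prev_aa[d$peptide == "MAAAGGGK"], "-")
  expect_equal(d$next_aa[d$peptide == "HHHIIIK"], "-")
  # no cleavage before proline
  dp <- digest_protein("AAAKPGGGRTTTTTT", max_mc = 0)
  expect_false("AAAK" %in% dp$peptide)
  expect_equal(count_missed_cleavages("MAAAGGGKEEEFFFR"), 1L)
  expect_equal(count_missed_cleavages("AAAKPGGGR"), 0L)  # KP is not a site
})

test_that("MCL recovers disconnected components and singletons", {
  ed <- data.frame(a = c("a", "a", "b", "x", "x", "y"),
                   b = c("b", "c", "c", "y", "z", "z"),
                   percent_identity = 90)
  cl <- mcl_cluster(ed, nodes = c("a", "b", "c", "x", "y", "z", "solo"))
  expect_equal(canonical_partition(cl),
               list(c("a", "b", "c"), "solo", c("x", "y", "z")))
})

test_that("MCL equals connected components on random clique graphs", {
  for (s in 1:30) {
    g <- random_clique_graph(s)
    got <- canonical_partition(mcl_cluster(g$edges, nodes = g$nodes))
    want <- canonical_partition(oracle_components(g$edges, g$nodes))
    expect_identical(got, want, label = sprintf("seed %d", s))
  }
})

test_that("inflation preserves column stochasticity", {
  set.seed(8)
  M <- matrix(runif(36), 6, 6)
  M <- sweep(M, 2, colSums(M), "/")
  for (r in c(1.2, 1.5, 2)) {
    M2 <- mpdiff:::.mcl_inflate(M %*% M, r)
    expect_true(all(abs(colSums(M2) - 1) < 1e-9))
  }
})

test_that("raising the identity threshold never merges clusters", {
  ed <- data.frame(a = c("a", "b", "c", "d", "a"),
                   b = c("b", "c", "d", "e", "e"),
                   percent_identity = c(95, 85, 82, 95, 81))
  lo <- mcl_cluster(ed, nodes = letters[1:5], min_identity = 80)
  hi <- mcl_cluster(ed, nodes = letters[1:5], min_identity = 90)
  # every high-threshold cluster sits inside one low-threshold cluster
  for (h in hi) {
    containing <- vapply(lo, function(l) all(h %in% l), logical(1))
    expect_equal(sum(containing), 1L)
  }
})

test_that("ORFs map to the best representative above the identity threshold", {
  base <- paste(rep(c("M", "A", "D", "E", "F", "G", "H", "I", "K", "L"), 4),
                collapse = "")
  mutate_at <- function(s, pos, to) {
    for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- to[k]
    s
  }
  protos <- data.frame(
    id = c("r1", "r2"),
    sequence = c(base, mutate_at(base, c(3, 7, 11, 15, 19, 23, 27, 31, 35, 39,
                                         4, 8, 12, 16, 20, 24, 28, 32, 36, 2),
                                 rep(c("W", "Y"), each = 10))))
  clusters <- cluster_proteins(protos, min_aln_len = 20)
  expect_equal(length(unique(clusters$cluster_id)), 2L)

  orfs <- data.frame(
    id = c("exact", "close", "far"),
    sequence = c(base,
                 mutate_at(base, c(5, 13, 21, 29, 37, 9), rep("C", 6)),
                 mutate_at(base, seq(2, 40, by = 2), rep("W", 20))))
  m <- map_orfs_to_clusters(orfs, clusters, protos, min_identity = 80,
                            min_aln_len = 20)
  r1_cluster <- clusters$cluster_id[clusters$member_id == "r1"]
  expect_equal(m$cluster_id[m$orf_id == "exact"], r1_cluster)
  expect_equal(m$percent_identity[m$orf_id == "exact"], 100)
  expect_equal(m$cluster_id[m$orf_id == "close"], r1_cluster)
  expect_true(is.na(m$cluster_id[m$orf_id == "far"]))
})

test_that("clustering partitions the input set", {
  spec <- small_spec(seed = 21)
  refs <- generate_reference_proteomes(spec)
  nr <- remove_redundant(refs$proteins)
  cl <- cluster_proteins(nr, min_aln_len = 25)
  expect_setequal(cl$member_id, nr$id)
  expect_equal(anyDuplicated(cl$member_id), 0L)
  expect_equal(sum(cl$representative_flag),
               length(unique(cl$cluster_id)))
})
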
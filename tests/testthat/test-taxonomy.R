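base40 <- paste(rep(c("M", "A", "D", "E", "F", "G", "H", "I", "K", "L"), 4),
                collapse = "")
sub_at <- function(s, pos, to) {
  for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- to[k]
  s
}

test_that("reads are assigned by identity and coverage thresholds", {
  refs <- data.frame(id = c("g1", "g2"),
                     sequence = c(base40, sub_at(base40, seq(2, 40, 2),
                                                 rep("W", 20))),
                     genus = c("Faecalibacterium", "Bacteroides"))
  # exact copy: genus of the reference at identity 100
  reads <- data.frame(id = "exact", sequence = base40)
  a <- classify_reads(reads, refs)
  expect_equal(a$taxon, "Faecalibacterium")
  expect_equal(a$percent_identity, 100)

  # ~85% identity over full coverage is assigned
  close <- data.frame(id = "c", sequence = sub_at(base40, c(3, 7, 13, 23, 33,
                                                            37), rep("C", 6)))
  expect_equal(classify_reads(close, refs)$taxon, "Faecalibacterium")

  # high identity but low coverage: only a fragment aligns -> fallback
  frag <- data.frame(id = "f",
                     sequence = paste0(substr(base40, 1, 20),
                                       paste(rep("W", 20), collapse = "")))
  out <- classify_reads(frag, refs, min_id = 80, min_cov = 0.8)
  expect_equal(out$taxon, "human gut microbiome")
})

test_that("ties across genera stay unassigned at genus rank", {
  refs <- data.frame(id = c("g1", "g2"),
                     sequence = c(base40, base40),
                     genus = c("Faecalibacterium", "Bacteroides"))
  a <- classify_reads(data.frame(id = "q", sequence = base40), refs)
  expect_equal(a$taxon, "human gut microbiome")
  # empty reference set: everything falls back
  none <- classify_reads(data.frame(id = "q", sequence = base40),
                         refs[0, , drop = FALSE])
  expect_equal(none$taxon, "human gut microbiome")
})

test_that("contig taxon is the majority of assigned reads", {
  expect_equal(contig_taxon(c("A", "A", "B")), "A")
  expect_equal(contig_taxon(c("A", "B")), "human gut microbiome")
  expect_equal(contig_taxon(rep("human gut microbiome", 3)),
               "human gut microbiome")
  expect_equal(contig_taxon(c("A", "human gut microbiome")), "A")
})

test_that("recovered genus profiles track ground-truth abundances", {
  rho <- numeric(10); assigned_rate <- numeric(10); correct_rate <- numeric(10)
  for (s in 1:10) {
    spec <- cohort_spec(n_genera = 4, proteins_per_genus = 6,
                        seq_length_range = c(60, 100),
                        groups = list(H = 2), runs_per_subject = 1,
                        depletion = list(), strain_mutation_rate = 0.03,
                        paralog_fraction = 0, seed = 30 + s)
    refs <- generate_reference_proteomes(spec)
    cohort <- generate_cohort(spec, refs)
    smp <- cohort$samples$sample_id[1]
    orfs <- cohort$orfs[cohort$orfs$sample_id == smp, ]
    # abundance-weighted read set: replicate ORFs by detection weight
    w <- cohort$weights[orfs$ref_id, smp]
    reps <- pmax(1L, round(200 * w / sum(w)))
    reads <- data.frame(id = sprintf("read%04d", seq_len(sum(reps))),
                        sequence = rep(orfs$sequence, reps))
    truth_genus <- rep(orfs$genus, reps)
    a <- classify_reads(reads, refs$proteins[, c("id", "sequence", "genus")])
    assigned <- a$taxon != "human gut microbiome"
    assigned_rate[s] <- mean(assigned)
    correct_rate[s] <- mean(a$taxon[assigned] == truth_genus[assigned])
    prof <- table(a$taxon[assigned]) / sum(assigned)
    truth_prof <- cohort$abundances[names(prof), smp]
    rho[s] <- cor(as.numeric(prof), truth_prof, method = "spearman")
  }
  expect_gt(min(assigned_rate), 0.8)
  expect_gt(min(correct_rate), 0.95)
  expect_gte(median(rho), 0.9)
})

test_that("rarefied abundances are exact at equal depth and sum to one", {
  cm <- matrix(c(60, 40, 30, 70), 2, 2,
               dimnames = list(c("x", "y"), c("s1", "s2")))
  r <- rarefied_annotation_abundance(cm, iterations = 10, seed = 2)
  expect_equal(r[, "s1"], c(x = 0.6, y = 0.4))
  expect_equal(r[, "s2"], c(x = 0.3, y = 0.7))
  expect_true(all(abs(colSums(r) - 1) < 1e-9))
  # unequal depth: subsampled sample still sums to 1 and is reproducible
  cm2 <- matrix(c(500, 500, 30, 10), 2, 2,
                dimnames = list(c("x", "y"), c("s1", "s2")))
  r1 <- rarefied_annotation_abundance(cm2, iterations = 50, seed = 9)
  r2 <- rarefied_annotation_abundance(cm2, iterations = 50, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(abs(colSums(r1) - 1) < 1e-9))
  # 50/50 annotations stay near 0.5 under subsampling
  expect_lt(abs(r1["x", "s1"] - 0.5), 0.05)
  expect_error(rarefied_annotation_abundance(cm, iterations = 0), "iterations")
})
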
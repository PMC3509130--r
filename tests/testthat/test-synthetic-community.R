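test_that("reference proteome counts and labels follow the spec", {
  spec <- cohort_spec(n_genera = 3, proteins_per_genus = 10, seed = 7,
                      seq_length_range = c(60, 120))
  refs <- generate_reference_proteomes(spec)
  expect_equal(nrow(refs$proteins), 30L)
  expect_setequal(unique(refs$proteins$genus),
                  c("Faecalibacterium", "Roseburia", "Coprococcus"))
  expect_true(all(nzchar(refs$proteins$ko)))
  expect_true(all(nzchar(refs$proteins$cog)))
  # every genus covers at least one multi-KO module
  for (g in unique(refs$proteins$genus)) {
    kos <- refs$proteins$ko[refs$proteins$genus == g]
    mods <- refs$modules$module_id[refs$modules$ko_id %in% kos]
    expect_true(any(table(mods) >= 2))
  }
  expect_true(all(valid_sequence <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$",
                                          refs$proteins$sequence)))
})

test_that("seeded generation is reproducible down to FASTA bytes", {
  spec <- cohort_spec(n_genera = 3, proteins_per_genus = 10, seed = 7,
                      seq_length_range = c(60, 120))
  refs1 <- generate_reference_proteomes(spec)
  refs2 <- generate_reference_proteomes(spec)
  expect_identical(refs1, refs2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(refs1$proteins, f1); write_fasta(refs2$proteins, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("zero strain mutation with two strains duplicates sequences", {
  spec <- cohort_spec(n_genera = 2, proteins_per_genus = 5, seed = 3,
                      strains_per_genus = 2, strain_mutation_rate = 0,
                      seq_length_range = c(60, 100), paralog_fraction = 0)
  refs <- generate_reference_proteomes(spec)
  expect_equal(nrow(refs$proteins), 20L)
  dup <- refs$proteins[refs$proteins$cluster_tag == "Faecalibacterium_p001", ]
  expect_equal(length(unique(dup$sequence)), 1L)
  # the redundancy filter collapses the identical strain copies
  nr <- remove_redundant(refs$proteins)
  expect_equal(nrow(nr), 10L)
})

test_that("cohort abundances are proportions and depletion scales groups", {
  spec <- small_spec(seed = 5)
  refs <- generate_reference_proteomes(spec)
  cohort <- generate_cohort(spec, refs)
  expect_true(all(abs(colSums(cohort$abundances) - 1) < 1e-9))
  expect_identical(generate_cohort(spec, refs), cohort)

  # empirical 5-fold depletion across seeds (renormalization shifts the
  # realized ratio slightly away from the nominal fold-change)
  ratios <- vapply(1:20, function(s) {
    sp <- cohort_spec(n_genera = 6, proteins_per_genus = 4,
                      seq_length_range = c(60, 100),
                      groups = list(H = 4, ICD = 4), runs_per_subject = 1,
                      depletion = list(ICD = c(Faecalibacterium = 0.2)),
                      abundance_sdlog = 0.3, seed = s)
    rf <- generate_reference_proteomes(sp)
    co <- generate_cohort(sp, rf)
    h <- mean(co$abundances["Faecalibacterium", co$samples$group == "H"])
    i <- mean(co$abundances["Faecalibacterium", co$samples$group == "ICD"])
    i / h
  }, numeric(1))
  expect_gt(mean(ratios), 0.12)
  expect_lt(mean(ratios), 0.35)
})

test_that("null depletion leaves the two groups exchangeable", {
  sp <- cohort_spec(n_genera = 4, proteins_per_genus = 4,
                    seq_length_range = c(60, 100),
                    groups = list(H = 4, ICD = 4), runs_per_subject = 1,
                    depletion = list(ICD = c(Faecalibacterium = 1.0)),
                    seed = 11)
  rf <- generate_reference_proteomes(sp)
  diffs <- vapply(1:20, function(s) {
    sp$seed <- s
    co <- generate_cohort(sp, rf)
    mean(co$abundances["Faecalibacterium", co$samples$group == "H"]) -
      mean(co$abundances["Faecalibacterium", co$samples$group == "ICD"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("group with zero subjects is a configuration error", {
  expect_error(cohort_spec(groups = list(H = 4, ICD = 0)), "groups")
})

test_that("simulated PSM tables honor decoy rate, totals and zero abundance", {
  spec <- small_spec(seed = 9, decoy_hit_rate = 0)
  refs <- generate_reference_proteomes(spec)
  cohort <- generate_cohort(spec, refs)
  sim <- simulate_psm_tables(spec, cohort)
  expect_false(any(sim$psms$is_decoy))
  tab <- table(sim$psms$run_id)
  expect_equal(unname(tab[sim$run_profiles$run_id]),
               sim$run_profiles$n_i, ignore_attr = TRUE)

  # a protein with zero weight in one sample draws no spectra there
  # (no paralogs, so no other ORF can carry the victim's peptides)
  spec2 <- small_spec(seed = 9, paralog_fraction = 0)
  refs <- generate_reference_proteomes(spec2)
  cohort2 <- generate_cohort(spec2, refs)
  victim <- refs$proteins$id[1]
  smp <- cohort2$samples$sample_id[1]
  cohort2$weights[victim, smp] <- 0
  sim2 <- simulate_psm_tables(spec2, cohort2)
  runs_smp <- cohort2$runs$run_id[cohort2$runs$sample_id == smp]
  hit <- sim2$psms$run_id %in% runs_smp & !sim2$psms$is_decoy &
    grepl(paste0(smp, "\\|", victim, "($|;)"), sim2$psms$protein_ids)
  truth_hit <- sim2$truth$is_correct[hit]
  expect_equal(sum(truth_hit), 0L)
})

test_that("simulated flanking residues are consistent with tryptic digestion", {
  spec <- small_spec(seed = 13)
  refs <- generate_reference_proteomes(spec)
  cohort <- generate_cohort(spec, refs)
  sim <- simulate_psm_tables(spec, cohort)
  ok <- mpdiff:::is_fully_tryptic(sim$psms$peptide, sim$psms$prev_aa,
                                  sim$psms$next_aa)
  expect_true(all(ok))
  expect_true(all(count_missed_cleavages(sim$psms$peptide) <= 4))
  expect_true(all(nchar(sim$psms$peptide) >= 6))
})
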
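make_psm <- function(..., spectrum_id = "s1", run_id = "r1", sample_id = "a",
                     peptide = "EEEFFFR", prev_aa = "K", next_aa = "H",
                     charge = 2, xcorr = 3.0, deltcn = 0.1, ppm_error = 0,
                     protein_ids = "p1", is_decoy = FALSE) {
  data.frame(spectrum_id = spectrum_id, run_id = run_id,
             sample_id = sample_id, peptide = peptide, prev_aa = prev_aa,
             next_aa = next_aa, charge = charge, xcorr = xcorr,
             deltcn = deltcn, ppm_error = ppm_error,
             protein_ids = protein_ids, is_decoy = is_decoy, ...,
             stringsAsFactors = FALSE)
}

test_that("XCorr thresholds are charge-dependent and boundary-inclusive", {
  pol <- filter_policy()
  expect_equal(nrow(filter_psms(make_psm(charge = 2, xcorr = 2.49), pol, "MM")), 0L)
  expect_equal(nrow(filter_psms(make_psm(charge = 2, xcorr = 2.50), pol, "MM")), 1L)
  expect_equal(nrow(filter_psms(make_psm(charge = 1, xcorr = 1.80), pol, "MM")), 1L)
  expect_equal(nrow(filter_psms(make_psm(charge = 3, xcorr = 3.49), pol, "MM")), 0L)
  # charges above 3 inherit the charge-3 threshold
  expect_equal(nrow(filter_psms(make_psm(charge = 4, xcorr = 3.49), pol, "MM")), 0L)
  expect_equal(nrow(filter_psms(make_psm(charge = 4, xcorr = 3.50), pol, "MM")), 1L)
})

test_that("the ppm window is closed and applies to MM searches only", {
  pol <- filter_policy()
  expect_equal(nrow(filter_psms(make_psm(ppm_error = 10.0), pol, "MM")), 1L)
  expect_equal(nrow(filter_psms(make_psm(ppm_error = 10.1), pol, "MM")), 0L)
  expect_equal(nrow(filter_psms(make_psm(ppm_error = -10.0), pol, "MM")), 1L)
  expect_equal(nrow(filter_psms(make_psm(ppm_error = -10.1), pol, "MM")), 0L)
  expect_equal(nrow(filter_psms(make_psm(ppm_error = 45), pol, "HMRG")), 1L)
})

test_that("tryptic termini and missed cleavages follow trypsin rules", {
  pol <- filter_policy()
  # non-tryptic N-side
  expect_equal(nrow(filter_psms(make_psm(prev_aa = "E"), pol, "MM")), 0L)
  # cleavage cannot have produced a peptide starting with proline
  expect_equal(nrow(filter_psms(make_psm(peptide = "PEEFFFR", prev_aa = "K"),
                                pol, "MM")), 0L)
  # protein termini are valid boundaries
  expect_equal(nrow(filter_psms(make_psm(prev_aa = "-", peptide = "MEEFFFR"),
                                pol, "MM")), 1L)
  expect_equal(nrow(filter_psms(make_psm(peptide = "EEEFFFH", next_aa = "-"),
                                pol, "MM")), 1L)
  # C-side: K/R not before P
  expect_equal(nrow(filter_psms(make_psm(peptide = "EEEFFFR", next_aa = "P"),
                                pol, "MM")), 0L)
  # five missed cleavages exceeds the cap of four
  pep5 <- "AKEKAKEKAKEE"
  expect_equal(count_missed_cleavages(pep5), 5L)
  expect_equal(nrow(filter_psms(make_psm(peptide = pep5, prev_aa = "R",
                                         next_aa = "-"), pol, "MM")), 0L)
  pep4 <- "AKEKAKEKAEEE"
  expect_equal(count_missed_cleavages(pep4), 4L)
  expect_equal(nrow(filter_psms(make_psm(peptide = pep4, prev_aa = "R",
                                         next_aa = "-"), pol, "MM")), 1L)
})

test_that("missing flanking residues reject with a warning tally", {
  pol <- filter_policy()
  psms <- rbind(make_psm(), make_psm(spectrum_id = "s2", prev_aa = NA))
  expect_warning(out <- filter_psms(psms, pol, "MM"), "missing flanking")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_missing_flanks"), 1L)
})

test_that("filtering is monotone in every threshold", {
  set.seed(33)
  n <- 400
  psms <- make_psm(
    spectrum_id = sprintf("s%03d", 1:n),
    peptide = sample(c("EEEFFFR", "AAKEEFFFR", "PEEFFFR"), n, TRUE),
    prev_aa = sample(c("K", "R", "E", "-"), n, TRUE),
    next_aa = sample(c("H", "P", "-"), n, TRUE),
    charge = sample(1:4, n, TRUE),
    xcorr = runif(n, 0, 6), deltcn = runif(n, 0, 0.4),
    ppm_error = runif(n, -50, 50))
  base <- filter_psms(psms, filter_policy(), "MM")
  tighter <- list(
    filter_policy(xcorr_min_by_charge = c(`1` = 2.2, `2` = 3.0, `3` = 4.0)),
    filter_policy(deltcn_min = 0.1),
    filter_policy(max_miscleavages = 0),
    filter_policy(ppm_window = c(-5, 5)))
  for (pol in tighter) {
    out <- filter_psms(psms, pol, "MM")
    expect_true(all(out$spectrum_id %in% base$spectrum_id))
  }
})

test_that("protein-level filter needs two distinct peptides", {
  pol <- filter_policy()
  # HMRG: one distinct peptide over many spectra is dropped
  psms <- make_psm(spectrum_id = sprintf("s%d", 1:10))
  out <- protein_level_filter(psms, "HMRG", pol)
  expect_equal(nrow(out$psms), 0L)
  # two distinct peptides retained
  psms2 <- rbind(psms, make_psm(spectrum_id = "s11", peptide = "MAAAGGGK",
                                prev_aa = "-", next_aa = "E"))
  out2 <- protein_level_filter(psms2, "HMRG", pol)
  expect_equal(nrow(out2$psms), 11L)
  expect_equal(out2$retained, "p1")
  # MM: the cluster needs the second distinct peptide
  cmap <- c(p1 = "OC1", p2 = "OC1")
  one <- make_psm(protein_ids = "p1")
  expect_equal(nrow(protein_level_filter(one, "MM", pol, cmap)$psms), 0L)
  two <- rbind(one, make_psm(spectrum_id = "s2", protein_ids = "p2",
                             peptide = "MAAAGGGK", prev_aa = "-",
                             next_aa = "E"))
  expect_equal(nrow(protein_level_filter(two, "MM", pol, cmap)$psms), 2L)
})

test_that("target-decoy FDR follows the concatenated-search estimator", {
  expect_equal(estimate_fdr(data.frame(is_decoy = rep(c(FALSE, TRUE),
                                                      c(98, 2)))), 0.04)
  expect_equal(estimate_fdr(data.frame(is_decoy = rep(FALSE, 50))), 0)
  expect_equal(estimate_fdr(data.frame(is_decoy = rep(TRUE, 4))), 1)
  expect_true(is.na(estimate_fdr(data.frame(is_decoy = logical(0)))))
  expect_equal(estimate_fdr(data.frame(is_decoy = rep(c(FALSE, TRUE),
                                                      c(98, 2))),
                            method = "ratio"), 2 / 98)
  rep_df <- fdr_report(data.frame(run_id = c("r1", "r1", "r2"),
                                  is_decoy = c(FALSE, TRUE, FALSE)))
  expect_equal(rep_df$fdr[rep_df$run_id == "r1"], 1)
  expect_equal(rep_df$fdr[rep_df$run_id == "pooled"], 2 * 1 / 3)
})

test_that("accepted MM PSMs always satisfy the closed ppm window", {
  spec <- small_spec(seed = 17)
  refs <- generate_reference_proteomes(spec)
  cohort <- generate_cohort(spec, refs)
  sim <- simulate_psm_tables(spec, cohort)
  acc <- filter_psms(sim$psms, filter_policy(), "MM")
  expect_true(all(acc$ppm_error >= -10 & acc$ppm_error <= 10))
})
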
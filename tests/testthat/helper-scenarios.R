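# Shared simulation scenarios. Sizes are chosen as the smallest cohorts at
# which the planted signal structure is realistic (see the methods vignette);
# they are fixed here once and reused by the unit and acceptance tests.

# Small generic cohort for plumbing tests.
small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_genera = 3, proteins_per_genus = 8,
              seq_length_range = c(60, 120),
              groups = list(H = 2, ICD = 2), runs_per_subject = 2,
              spectra_per_run = c(mean = 400, dispersion = 50),
              strain_mutation_rate = 0.01,
              modules_per_genus = 2, kos_per_module = 3,
              seed = seed, ...)
}

# Recovery scenario: 4 healthy vs 6 disease runs, 50 ortholog clusters,
# 10 of them depleted 5-fold in the disease group, baseline cluster median
# around 20 counts per run. The planted clusters live in a low-abundance
# genus (~5% of the spectral pool, both groups) so that, under a fixed
# per-run spectrum total, their depletion does not inflate the null
# clusters past the median-difference gate (spectral counts are
# compositional; see the methods vignette).
recovery_spec <- function(seed) {
  tags <- sprintf("Bacteroides_p%03d", 1:10)
  cohort_spec(
    n_genera = 5, proteins_per_genus = 10, seq_length_range = c(80, 200),
    groups = list(H = 4, ICD = 6), runs_per_subject = 1,
    depletion = list(H = c(Bacteroides = 0.2), ICD = c(Bacteroides = 0.2)),
    planted_diff_clusters = data.frame(cluster_tag = tags, fold_change = 0.2,
                                       group = "ICD",
                                       stringsAsFactors = FALSE),
    spectra_per_run = c(mean = 5000, dispersion = 80),
    strain_mutation_rate = 0, paralog_fraction = 0,
    abundance_sdlog = 0.05, base_abundance_sdlog = 0,
    detectability_sdlog = 0.3, decoy_hit_rate = 0.05,
    seed = seed)
}

# Global-null scenario: no depletion, no planted effects.
null_spec <- function(seed) {
  cohort_spec(
    n_genera = 4, proteins_per_genus = 10, seq_length_range = c(80, 200),
    groups = list(H = 4, ICD = 6), runs_per_subject = 1,
    depletion = list(),
    spectra_per_run = c(mean = 1000, dispersion = 80),
    strain_mutation_rate = 0, paralog_fraction = 0,
    abundance_sdlog = 0.15, base_abundance_sdlog = 0,
    detectability_sdlog = 0.3, decoy_hit_rate = 0.05,
    seed = seed)
}

# Module-deviation scenario: 6 genera x 3 modules, two genera depleted in
# the disease group, one (genus, module) pair depleted 4-fold beyond its
# genus shift.
deviation_spec <- function(seed) {
  cohort_spec(
    n_genera = 6, proteins_per_genus = 12, seq_length_range = c(80, 200),
    groups = list(H = 4, ICD = 6), runs_per_subject = 1,
    depletion = list(ICD = c(Faecalibacterium = 0.5, Roseburia = 0.4)),
    planted_module_effects = data.frame(
      genus = "Faecalibacterium", module = "M002", fold_change = 0.25,
      group = "ICD", stringsAsFactors = FALSE),
    spectra_per_run = c(mean = 2000, dispersion = 80),
    strain_mutation_rate = 0, paralog_fraction = 0,
    abundance_sdlog = 0.25, base_abundance_sdlog = 0.8,
    detectability_sdlog = 0.3, decoy_hit_rate = 0.05,
    modules_per_genus = 3, kos_per_module = 4,
    seed = seed)
}

# Ancestry cluster map: every ORF belongs to the cluster of its source
# protein (cluster tag); exact at zero strain mutation.
truth_cluster_map <- function(cohort) {
  setNames(cohort$orfs$cluster_tag, cohort$orfs$orf_id)
}

# Downstream pipeline from simulated PSMs to normalized cluster counts.
quantify_cohort <- function(spec, cohort, sim, policy = filter_policy()) {
  acc <- filter_psms(sim$psms, policy, search_kind = "MM")
  cmap <- truth_cluster_map(cohort)
  pl <- protein_level_filter(acc, "MM", policy, cmap)
  targets <- pl$psms[!as.logical(pl$psms$is_decoy), , drop = FALSE]
  profiles <- make_run_profiles(sim$run_profiles)
  raw <- attribute_spectra(targets, cmap, runs = profiles$run_id)
  list(norm = normalize_counts(raw, profiles), profiles = profiles,
       accepted = acc, raw = raw)
}

group_runs <- function(profiles, group) profiles$run_id[profiles$group == group]
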
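# Cohort specification for the synthetic twin-cohort generator.

GUT_GENERA <- c("Faecalibacterium", "Roseburia", "Coprococcus", "Dialister",
                "Bacteroides", "Prevotella", "Alistipes", "Blautia",
                "Ruminococcus", "Eubacterium", "Akkermansia", "Bifidobacterium")

#' Specify a synthetic metaproteomic cohort
#'
#' Collects every parameter of the synthetic-community generator in one
#' validated object. The defaults emulate the study design the package is
#' built around: twelve subjects (4 healthy, 6 ileal Crohn's, 2 colonic
#' Crohn's) each measured in technical duplicate MS runs, with a
#' Firmicutes-like depletion of several genera in the ICD group.
#'
#' @param n_genera number of microbial genera.
#' @param proteins_per_genus proteins generated per genus (per strain).
#' @param seq_length_range two-element range of protein lengths (residues).
#' @param strain_mutation_rate per-residue substitution probability applied
#'   when deriving sample ORFs (and extra strains) from reference proteins.
#' @param strains_per_genus number of strain variants per genus in the
#'   reference set (variants beyond the first are mutated copies).
#' @param groups named list: phenotype label -> number of subjects.
#' @param runs_per_subject technical replicate MS runs per subject.
#' @param depletion named list: group label -> named numeric vector of
#'   genus fold-changes (< 1 depletes that genus in that group).
#' @param planted_diff_clusters `NULL` or data.frame with columns
#'   `cluster_tag` (reference protein id), `fold_change`, `group`.
#' @param planted_module_effects `NULL` or data.frame with columns `genus`,
#'   `module`, `fold_change`, `group` — an extra fold-change applied to
#'   proteins of that genus annotated to KOs of that module, beyond any
#'   genus-level abundance shift.
#' @param spectra_per_run c(mean, dispersion): negative-binomial model of the
#'   per-run total MS/MS count.
#' @param decoy_hit_rate fraction of PSMs drawn from the decoy model. An equal
#'   fraction of incorrect target matches is drawn (a concatenated
#'   target-decoy search splits incorrect matches evenly), so the total
#'   incorrect-PSM rate is `2 * decoy_hit_rate`.
#' @param abundance_sdlog sdlog of the per-sample log-normal noise on genus
#'   abundances.
#' @param base_abundance_sdlog sdlog of the cohort-level log-normal draw of
#'   genus base abundances (heavy-tailed gut-like profile).
#' @param detectability_sdlog sdlog of per-protein log-normal detectability.
#' @param xcorr_models list with `correct` and `incorrect` components, each
#'   c(shift, charge_slope, shape, scale): xcorr = shift + charge_slope *
#'   charge + Gamma(shape, scale).
#' @param ppm_error_model c(correct_sd, incorrect_halfwidth): Normal(0, sd)
#'   ppm error for correct matches, Uniform(-hw, hw) for incorrect.
#' @param modules_per_genus,kos_per_module KEGG-like module structure: each
#'   genus expresses `modules_per_genus` modules of `kos_per_module` KOs.
#' @param paralog_fraction fraction of proteins whose sequence is copied from
#'   another genus (creates peptides shared across genera).
#' @param charge_probs sampling probabilities for precursor charges 1..3.
#' @param max_missed_cleavages,min_peptide_length tryptic digestion bounds.
#' @param seed integer seed; all stochastic draws flow from it.
#' @return object of class `cohort_spec`.
#' @seealso [generate_reference_proteomes()], [generate_cohort()],
#'   [simulate_psm_tables()]
#' @examples
#' spec <- cohort_spec(n_genera = 3, proteins_per_genus = 10, seed = 7)
#' @export
cohort_spec <- function(n_genera = 8,
                        proteins_per_genus = 25,
                        seq_length_range = c(120L, 400L),
                        strain_mutation_rate = 0.02,
                        strains_per_genus = 1L,
                        groups = list(H = 4L, ICD = 6L, CCD = 2L),
                        runs_per_subject = 2L,
                        depletion = list(ICD = c(Faecalibacterium = 0.2,
                                                 Roseburia = 0.2,
                                                 Coprococcus = 0.25,
                                                 Dialister = 0.25)),
                        planted_diff_clusters = NULL,
                        planted_module_effects = NULL,
                        spectra_per_run = c(mean = 4000, dispersion = 50),
                        decoy_hit_rate = 0.05,
                        abundance_sdlog = 0.4,
                        base_abundance_sdlog = 1.0,
                        detectability_sdlog = 0.6,
                        xcorr_models = list(
                          correct = c(shift = 1.5, charge_slope = 0.4,
                                      shape = 3, scale = 0.8),
                          incorrect = c(shift = 0.3, charge_slope = 0.3,
                                        shape = 2, scale = 0.7)),
                        ppm_error_model = c(correct_sd = 3,
                                            incorrect_halfwidth = 50),
                        modules_per_genus = 3L,
                        kos_per_module = 5L,
                        paralog_fraction = 0.05,
                        charge_probs = c(0.15, 0.55, 0.30),
                        max_missed_cleavages = 4L,
                        min_peptide_length = 6L,
                        seed = 1L) {
  if (missing(depletion)) {
    # built-in default: keep only genera that exist at this n_genera
    genera <- genus_names(as.integer(n_genera))
    depletion <- lapply(depletion, function(d) d[names(d) %in% genera])
    depletion <- depletion[lengths(depletion) > 0]
  }
  spec <- list(
    n_genera = as.integer(n_genera),
    proteins_per_genus = as.integer(proteins_per_genus),
    seq_length_range = as.integer(seq_length_range),
    strain_mutation_rate = strain_mutation_rate,
    strains_per_genus = as.integer(strains_per_genus),
    groups = lapply(groups, as.integer),
    runs_per_subject = as.integer(runs_per_subject),
    depletion = depletion,
    planted_diff_clusters = planted_diff_clusters,
    planted_module_effects = planted_module_effects,
    spectra_per_run = spectra_per_run,
    decoy_hit_rate = decoy_hit_rate,
    abundance_sdlog = abundance_sdlog,
    base_abundance_sdlog = base_abundance_sdlog,
    detectability_sdlog = detectability_sdlog,
    xcorr_models = xcorr_models,
    ppm_error_model = ppm_error_model,
    modules_per_genus = as.integer(modules_per_genus),
    kos_per_module = as.integer(kos_per_module),
    paralog_fraction = paralog_fraction,
    charge_probs = charge_probs / sum(charge_probs),
    max_missed_cleavages = as.integer(max_missed_cleavages),
    min_peptide_length = as.integer(min_peptide_length),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

config_error <- function(field, msg) {
  stop(sprintf("invalid cohort_spec field '%s': %s", field, msg), call. = FALSE)
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_genera < 1L) config_error("n_genera", "must be >= 1")
  if (spec$proteins_per_genus < 1L) config_error("proteins_per_genus", "must be >= 1")
  if (length(spec$seq_length_range) != 2L ||
      any(spec$seq_length_range < 10L) || diff(spec$seq_length_range) < 0)
    config_error("seq_length_range", "must be an increasing pair >= 10")
  for (f in c("strain_mutation_rate", "decoy_hit_rate", "paralog_fraction")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) config_error(f, "must be a probability in [0,1]")
  }
  if (2 * spec$decoy_hit_rate > 1)
    config_error("decoy_hit_rate", "total incorrect rate 2*decoy_hit_rate exceeds 1")
  if (length(spec$groups) < 1L || is.null(names(spec$groups)))
    config_error("groups", "must be a named list of subject counts")
  if (any(unlist(spec$groups) < 1L))
    config_error("groups", "every group needs at least one subject")
  if (spec$runs_per_subject < 1L) config_error("runs_per_subject", "must be >= 1")
  genera <- genus_names(spec$n_genera)
  if (length(spec$depletion)) {
    if (is.null(names(spec$depletion)) ||
        !all(names(spec$depletion) %in% names(spec$groups)))
      config_error("depletion", "names must be group labels")
    for (g in names(spec$depletion)) {
      d <- spec$depletion[[g]]
      if (!all(names(d) %in% genera))
        config_error("depletion", sprintf(
          "genera %s not generated under n_genera = %d",
          paste(setdiff(names(d), genera), collapse = ", "), spec$n_genera))
      if (any(d <= 0)) config_error("depletion", "fold-changes must be > 0")
    }
  }
  for (f in c("planted_diff_clusters", "planted_module_effects")) {
    pl <- spec[[f]]
    if (!is.null(pl)) {
      if (!is.data.frame(pl) || !"fold_change" %in% names(pl) ||
          !"group" %in% names(pl))
        config_error(f, "must be a data.frame with fold_change and group columns")
      if (any(pl$fold_change <= 0)) config_error(f, "fold-changes must be > 0")
      if (!all(pl$group %in% names(spec$groups)))
        config_error(f, "group labels must be defined in groups")
    }
  }
  if (spec$spectra_per_run[[1]] <= 0 || spec$spectra_per_run[[2]] <= 0)
    config_error("spectra_per_run", "mean and dispersion must be > 0")
  if (abs(sum(spec$charge_probs) - 1) > 1e-9 || any(spec$charge_probs < 0))
    config_error("charge_probs", "must be non-negative and sum to 1")
  invisible(spec)
}

genus_names <- function(n) {
  if (n <= length(GUT_GENERA)) GUT_GENERA[seq_len(n)]
  else c(GUT_GENERA, sprintf("Genus%02d", seq_len(n - length(GUT_GENERA))))
}
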
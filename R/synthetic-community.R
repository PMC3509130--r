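# Synthetic twin-cohort generator: reference proteomes, per-sample ORF sets,
# PSM tables with decoys, and ground-truth effect tables. Everything flows
# from the single integer seed in the cohort_spec, with independent child
# seeds per stage so each stage is reproducible on its own.

random_protein <- function(len) {
  paste0("M", paste(sample(AA_STANDARD, len - 1L, replace = TRUE,
                           prob = AA_FREQS), collapse = ""))
}

mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  if (length(hit)) {
    aa[hit] <- vapply(aa[hit], function(x)
      sample(setdiff(AA_STANDARD, x), 1L), character(1))
  }
  paste(aa, collapse = "")
}

#' Generate synthetic reference proteomes with annotations
#'
#' Emulates a reference-isolate protein database: `n_genera` genera each with
#' `proteins_per_genus` proteins (per strain), every protein carrying a KO and
#' a COG label, a KO-to-module map with multi-KO modules, and a fraction of
#' paralogous sequences copied across genera so that some tryptic peptides are
#' shared between genera (exercising unique-attribution logic downstream).
#'
#' @param spec a [cohort_spec()].
#' @return object of class `reference_proteomes`: list with `proteins`
#'   (data.frame: id, cluster_tag, sequence, genus, strain, ko, cog,
#'   detectability) and `modules` (data.frame: module_id, ko_id).
#' @examples
#' refs <- generate_reference_proteomes(cohort_spec(n_genera = 3,
#'                                                  proteins_per_genus = 10,
#'                                                  seed = 7))
#' nrow(refs$proteins)  # 30
#' @export
generate_reference_proteomes <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(child_seed(spec$seed, 1L), {
    genera <- genus_names(spec$n_genera)
    n_ko <- spec$modules_per_genus * spec$kos_per_module
    kos <- sprintf("K%05d", seq_len(n_ko))
    modules <- data.frame(
      module_id = rep(sprintf("M%03d", seq_len(spec$modules_per_genus)),
                      each = spec$kos_per_module),
      ko_id = kos,
      stringsAsFactors = FALSE
    )
    rows <- list()
    for (g in genera) {
      for (s in seq_len(spec$strains_per_genus)) {
        j <- seq_len(spec$proteins_per_genus)
        tag <- sprintf("%s_p%03d", g, j)
        id <- if (s == 1L) tag else sprintf("%s_s%d", tag, s)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, cluster_tag = tag, genus = g, strain = s,
          ko = kos[(j - 1L) %% n_ko + 1L],
          cog = sprintf("COG%04d", (j - 1L) %% spec$proteins_per_genus + 1L),
          stringsAsFactors = FALSE
        )
      }
    }
    proteins <- do.call(rbind, rows)
    lens <- sample(seq(spec$seq_length_range[1], spec$seq_length_range[2]),
                   spec$n_genera * spec$proteins_per_genus, replace = TRUE)
    base_seq <- vapply(lens, random_protein, character(1))
    names(base_seq) <- proteins$cluster_tag[proteins$strain == 1L]
    # paralog families: copy a sequence from another genus
    n_par <- round(spec$paralog_fraction * length(base_seq))
    if (n_par > 0L && spec$n_genera > 1L) {
      tgt <- sample(names(base_seq), n_par)
      for (tag in tgt) {
        g <- proteins$genus[match(tag, proteins$cluster_tag)]
        donors <- proteins$cluster_tag[proteins$strain == 1L & proteins$genus != g]
        base_seq[tag] <- base_seq[sample(donors, 1L)]
      }
    }
    proteins$sequence <- vapply(seq_len(nrow(proteins)), function(i) {
      s0 <- base_seq[[proteins$cluster_tag[i]]]
      if (proteins$strain[i] == 1L) s0
      else mutate_sequence(s0, spec$strain_mutation_rate)
    }, character(1))
    proteins$detectability <- stats::rlnorm(nrow(proteins), 0,
                                            spec$detectability_sdlog)
    refs <- list(proteins = proteins[, c("id", "cluster_tag", "sequence",
                                         "genus", "strain", "ko", "cog",
                                         "detectability")],
                 modules = modules)
    class(refs) <- "reference_proteomes"
    refs
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-sample genus abundance profiles (log-normal, renormalized to
#' proportions), applies group-specific depletion fold-changes and planted
#' cluster/module effects, and derives per-sample ORF databases as mutated
#' copies of the reference proteins.
#'
#' @param spec a [cohort_spec()].
#' @param refs output of [generate_reference_proteomes()].
#' @return object of class `synthetic_cohort`: list with `samples` (sample_id,
#'   group, pair_id), `runs` (run_id, sample_id, group), `abundances`
#'   (genus x sample matrix of proportions), `orfs` (data.frame: orf_id,
#'   ref_id, cluster_tag, sample_id, genus, sequence), `weights` (protein x
#'   sample expected-detection weights) and `ground_truth`.
#' @export
generate_cohort <- function(spec, refs) {
  validate_cohort_spec(spec)
  stopifnot(inherits(refs, "reference_proteomes"))
  with_seed(child_seed(spec$seed, 2L), {
    genera <- genus_names(spec$n_genera)
    samples <- do.call(rbind, lapply(names(spec$groups), function(g) {
      n <- spec$groups[[g]]
      data.frame(sample_id = sprintf("%s%d", g, seq_len(n)), group = g,
                 pair_id = sprintf("%s_pair%d", g, ceiling(seq_len(n) / 2)),
                 stringsAsFactors = FALSE)
    }))
    runs <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      data.frame(run_id = sprintf("%s_r%d", samples$sample_id[i],
                                  seq_len(spec$runs_per_subject)),
                 sample_id = samples$sample_id[i],
                 group = samples$group[i], stringsAsFactors = FALSE)
    }))

    base_ab <- stats::rlnorm(length(genera), 0, spec$base_abundance_sdlog)
    names(base_ab) <- genera
    ab <- sapply(seq_len(nrow(samples)), function(i) {
      a <- base_ab * stats::rlnorm(length(genera), 0, spec$abundance_sdlog)
      dep <- spec$depletion[[samples$group[i]]]
      if (!is.null(dep)) a[names(dep)] <- a[names(dep)] * dep
      a / sum(a)
    })
    dimnames(ab) <- list(genera, samples$sample_id)

    prot <- refs$proteins
    # per-protein weight in each sample: genus abundance x detectability x
    # planted effects for the sample's group
    w <- matrix(prot$detectability, nrow = nrow(prot), ncol = nrow(samples),
                dimnames = list(prot$id, samples$sample_id))
    w <- w * ab[prot$genus, , drop = FALSE]
    pdc <- spec$planted_diff_clusters
    if (!is.null(pdc)) {
      for (i in seq_len(nrow(pdc))) {
        sel <- prot$cluster_tag == pdc$cluster_tag[i]
        if (!any(sel)) config_error("planted_diff_clusters",
                                    paste("unknown cluster_tag", pdc$cluster_tag[i]))
        smp <- samples$sample_id[samples$group == pdc$group[i]]
        w[sel, smp] <- w[sel, smp] * pdc$fold_change[i]
      }
    }
    pme <- spec$planted_module_effects
    if (!is.null(pme)) {
      for (i in seq_len(nrow(pme))) {
        mk <- refs$modules$ko_id[refs$modules$module_id == pme$module[i]]
        sel <- prot$genus == pme$genus[i] & prot$ko %in% mk
        if (!any(sel)) config_error("planted_module_effects",
                                    paste("no proteins for", pme$genus[i],
                                          pme$module[i]))
        smp <- samples$sample_id[samples$group == pme$group[i]]
        w[sel, smp] <- w[sel, smp] * pme$fold_change[i]
      }
    }

    orfs <- do.call(rbind, lapply(samples$sample_id, function(s) {
      data.frame(orf_id = paste0(s, "|", prot$id), ref_id = prot$id,
                 cluster_tag = prot$cluster_tag, sample_id = s,
                 genus = prot$genus,
                 sequence = if (spec$strain_mutation_rate > 0)
                   vapply(prot$sequence, mutate_sequence, character(1),
                          rate = spec$strain_mutation_rate, USE.NAMES = FALSE)
                 else prot$sequence,
                 stringsAsFactors = FALSE)
    }))

    truth_feats <- list()
    for (g in names(spec$depletion)) {
      d <- spec$depletion[[g]]
      if (length(d))
        truth_feats[[length(truth_feats) + 1L]] <- data.frame(
          feature_id = names(d), feature_kind = "genus", group = g,
          fold_change = unname(d), stringsAsFactors = FALSE)
    }
    if (!is.null(pdc))
      truth_feats[[length(truth_feats) + 1L]] <- data.frame(
        feature_id = pdc$cluster_tag, feature_kind = "cluster",
        group = pdc$group, fold_change = pdc$fold_change,
        stringsAsFactors = FALSE)
    ground_truth <- list(
      abundances = ab,
      true_differential_features = if (length(truth_feats))
        do.call(rbind, truth_feats) else NULL,
      true_deviating_modules = pme
    )

    cohort <- list(samples = samples, runs = runs, abundances = ab,
                   orfs = orfs, weights = w, ground_truth = ground_truth,
                   spec = spec)
    class(cohort) <- "synthetic_cohort"
    cohort
  })
}

# Digest every distinct sequence once; returns a data.table with a seq_idx
# column indexing into `uniq`.
digest_table <- function(uniq, max_mc, min_len) {
  dl <- lapply(uniq, function(s) digest_protein(s, max_mc, min_len))
  data.table::rbindlist(dl, idcol = "seq_idx")
}

#' Simulate PSM tables for every MS run of a cohort
#'
#' Spectra are allocated to proteins proportionally to sample abundance times
#' protein detectability; peptides come from in-silico tryptic digestion
#' (cleave after K/R, not before P, 0-4 missed cleavages). Correct matches
#' draw XCorr from the `correct` score model and small Normal ppm errors; a
#' `2 * decoy_hit_rate` fraction of PSMs are incorrect, split evenly between
#' reversed-sequence decoys and random target peptides, with the `incorrect`
#' score model and wide uniform ppm spread. Flanking residues are recorded so
#' tryptic status is checkable downstream.
#'
#' @param spec a [cohort_spec()].
#' @param cohort output of [generate_cohort()].
#' @return list with `psms` (one data.frame, spec PSM schema: spectrum_id,
#'   run_id, sample_id, peptide, prev_aa, next_aa, charge, xcorr, deltcn,
#'   ppm_error, protein_ids, is_decoy), `run_profiles` (run_id, sample_id,
#'   group, n_i) and `truth` (spectrum_id, is_correct).
#' @export
simulate_psm_tables <- function(spec, cohort) {
  validate_cohort_spec(spec)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (nrow(cohort$orfs) == 0L) stop("empty proteome: no ORFs in cohort", call. = FALSE)
  with_seed(child_seed(spec$seed, 3L), {
    orfs <- data.table::as.data.table(cohort$orfs)
    uniq <- unique(orfs$sequence)
    orfs[, "seq_idx" := match(orfs$sequence, uniq)]
    dig <- digest_table(uniq, spec$max_missed_cleavages,
                        spec$min_peptide_length)
    if (nrow(dig) == 0L)
      stop("empty proteome: digestion produced no peptides", call. = FALSE)
    dec_dig <- digest_table(
      vapply(strsplit(uniq, "", fixed = TRUE),
             function(a) paste(rev(a), collapse = ""), character(1)),
      spec$max_missed_cleavages, spec$min_peptide_length)

    xm <- spec$xcorr_models
    ppm <- spec$ppm_error_model

    draw_scores <- function(n, model) {
      charge <- sample(1:3, n, replace = TRUE, prob = spec$charge_probs)
      m <- xm[[model]]
      list(charge = charge,
           xcorr = round(m[["shift"]] + m[["charge_slope"]] * charge +
                           stats::rgamma(n, shape = m[["shape"]],
                                         scale = m[["scale"]]), 4),
           deltcn = round(if (model == "correct") stats::runif(n, 0.05, 0.45)
                          else stats::runif(n, 0, 0.12), 4),
           ppm_error = round(if (model == "correct")
             stats::rnorm(n, 0, ppm[["correct_sd"]])
             else stats::runif(n, -ppm[["incorrect_halfwidth"]],
                               ppm[["incorrect_halfwidth"]]), 3))
    }

    runs <- cohort$runs
    out <- vector("list", nrow(runs))
    prof <- runs
    prof$n_i <- NA_integer_
    for (r in seq_len(nrow(runs))) {
      smp <- runs$sample_id[r]
      so <- orfs[orfs$sample_id == smp, ]
      # sample-local digest / peptide index
      key <- data.table::data.table(seq_idx = so$seq_idx, orf_id = so$orf_id)
      sd_t <- dig[key, on = "seq_idx", allow.cartesian = TRUE, nomatch = NULL]
      pep_index <- sd_t[, list(pids = paste(sort(unique(orf_id)),
                                            collapse = ";")), by = "peptide"]
      data.table::setkeyv(pep_index, "peptide")
      dkey <- data.table::data.table(seq_idx = so$seq_idx,
                                     orf_id = paste0("rev_", so$orf_id))
      sdec <- dec_dig[dkey, on = "seq_idx", allow.cartesian = TRUE,
                      nomatch = NULL]
      dec_index <- sdec[, list(pids = paste(sort(unique(orf_id)),
                                            collapse = ";")), by = "peptide"]
      data.table::setkeyv(dec_index, "peptide")

      n_i <- max(1L, stats::rnbinom(1L, mu = spec$spectra_per_run[[1]],
                                    size = spec$spectra_per_run[[2]]))
      n_inc <- stats::rbinom(1L, n_i, 2 * spec$decoy_hit_rate)
      n_dec <- stats::rbinom(1L, n_inc, 0.5)
      n_inc_t <- n_inc - n_dec
      n_cor <- n_i - n_inc

      wt <- cohort$weights[, smp]
      wt <- wt[so$ref_id]  # align to ORF order
      pieces <- list()
      if (n_cor > 0L) {
        pick <- sample.int(nrow(so), n_cor, replace = TRUE, prob = wt)
        cnt <- tabulate(pick, nbins = nrow(so))
        sel <- which(cnt > 0L)
        rows_by_orf <- split(seq_len(nrow(sd_t)), sd_t$orf_id)
        rows <- data.table::rbindlist(lapply(sel, function(i) {
          ri <- rows_by_orf[[so$orf_id[i]]]
          if (is.null(ri)) return(NULL)
          sd_t[ri[sample.int(length(ri), cnt[i], replace = TRUE)], ]
        }))
        if (!is.null(rows) && nrow(rows)) {
          sc <- draw_scores(nrow(rows), "correct")
          pieces$correct <- data.table::data.table(
            peptide = rows$peptide, prev_aa = rows$prev_aa,
            next_aa = rows$next_aa, charge = sc$charge, xcorr = sc$xcorr,
            deltcn = sc$deltcn, ppm_error = sc$ppm_error,
            protein_ids = pep_index[rows$peptide, on = "peptide"]$pids,
            is_decoy = FALSE, is_correct = TRUE)
        }
      }
      if (n_inc_t > 0L) {
        rows <- sd_t[sample.int(nrow(sd_t), n_inc_t, replace = TRUE), ]
        sc <- draw_scores(nrow(rows), "incorrect")
        pieces$incorrect <- data.table::data.table(
          peptide = rows$peptide, prev_aa = rows$prev_aa,
          next_aa = rows$next_aa, charge = sc$charge, xcorr = sc$xcorr,
          deltcn = sc$deltcn, ppm_error = sc$ppm_error,
          protein_ids = pep_index[rows$peptide, on = "peptide"]$pids,
          is_decoy = FALSE, is_correct = FALSE)
      }
      if (n_dec > 0L && nrow(sdec) > 0L) {
        rows <- sdec[sample.int(nrow(sdec), n_dec, replace = TRUE), ]
        sc <- draw_scores(nrow(rows), "incorrect")
        pieces$decoy <- data.table::data.table(
          peptide = rows$peptide, prev_aa = rows$prev_aa,
          next_aa = rows$next_aa, charge = sc$charge, xcorr = sc$xcorr,
          deltcn = sc$deltcn, ppm_error = sc$ppm_error,
          protein_ids = dec_index[rows$peptide, on = "peptide"]$pids,
          is_decoy = TRUE, is_correct = FALSE)
      }
      tab <- data.table::rbindlist(pieces)
      if (nrow(tab)) {
        tab <- tab[sample.int(nrow(tab)), ]  # shuffle acquisition order
        tab[, "spectrum_id" := sprintf("%s.scan%05d", runs$run_id[r],
                                       seq_len(nrow(tab)))]
        tab[, "run_id" := runs$run_id[r]]
        tab[, "sample_id" := smp]
      }
      prof$n_i[r] <- n_i
      out[[r]] <- tab
    }
    psms <- as.data.frame(data.table::rbindlist(out))
    truth <- psms[, c("spectrum_id", "run_id", "is_correct")]
    psms <- psms[, c("spectrum_id", "run_id", "sample_id", "peptide",
                     "prev_aa", "next_aa", "charge", "xcorr", "deltcn",
                     "ppm_error", "protein_ids", "is_decoy")]
    list(psms = psms, run_profiles = prof, truth = truth)
  })
}
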
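# End-to-end orchestration from a single validated configuration.

#' Pipeline configuration
#'
#' Bundles a [cohort_spec()] (simulated input) with the group comparisons and
#' every stage threshold. Comparisons must reference groups defined in the
#' spec; this is validated before any stage runs.
#'
#' @param spec a [cohort_spec()] describing the simulated cohort.
#' @param comparisons list of length-2 character vectors of group labels.
#' @param min_identity,inflation,min_aln_len clustering thresholds.
#' @param policy a [filter_policy()].
#' @param alpha_q,min_median_diff,min_count,min_runs differential-call
#'   thresholds.
#' @param module_fdr,module_min_coverage,pi_level module-analysis thresholds.
#' @param map_method `"alignment"` maps sample ORFs onto clusters by local
#'   alignment against representatives; `"ancestry"` uses the simulator's
#'   ORF-to-reference ancestry (fast, for calibration studies).
#' @param out_dir optional output directory for TSV artifacts and manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec,
                            comparisons = list(c("H", "ICD")),
                            min_identity = 80, inflation = 1.5,
                            min_aln_len = 30,
                            policy = filter_policy(),
                            alpha_q = 0.05, min_median_diff = 5,
                            min_count = 5, min_runs = 4,
                            module_fdr = 0.10, module_min_coverage = 0.3,
                            pi_level = 0.95,
                            map_method = c("alignment", "ancestry"),
                            out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  map_method <- match.arg(map_method)
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% names(spec$groups)))
      stop("comparison references undefined group(s): ",
           paste(cmp, collapse = " vs "), call. = FALSE)
  }
  structure(list(spec = spec, comparisons = comparisons,
                 min_identity = min_identity, inflation = inflation,
                 min_aln_len = min_aln_len, policy = policy,
                 alpha_q = alpha_q, min_median_diff = min_median_diff,
                 min_count = min_count, min_runs = min_runs,
                 module_fdr = module_fdr,
                 module_min_coverage = module_min_coverage,
                 pi_level = pi_level, map_method = map_method,
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir))
      writeLines(paste("failed at stage:", name),
                 file.path(out_dir, "PIPELINE_FAILED"))
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the integrated pipeline end to end
#'
#' Simulate -> non-redundant database + ortholog clustering -> PSM filtering
#' and target-decoy FDR -> unique-attribution spectral counting and
#' normalization -> genus profile -> differential calls (cluster, COG, genus
#' levels) per comparison -> module coverage, differential modules and
#' taxon-module deviation. Deterministic given the spec seed; when `out_dir`
#' is set all tables, an FDR report and a JSON manifest of thresholds are
#' written.
#'
#' @param config a [pipeline_config()].
#' @return list with the per-stage results (`refs`, `cohort`, `clusters`,
#'   `orf_map`, `fdr`, `counts`, `normalized`, `differential`, `modules`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  od <- config$out_dir
  if (!is.null(od) && !dir.exists(od)) dir.create(od, recursive = TRUE)

  refs <- run_stage("simulate", od, generate_reference_proteomes(spec))
  cohort <- run_stage("simulate", od, generate_cohort(spec, refs))
  sim <- run_stage("simulate", od, simulate_psm_tables(spec, cohort))

  res <- run_stage("sequence_db", od, {
    nr <- remove_redundant(refs$proteins)
    clusters <- cluster_proteins(nr, min_identity = config$min_identity,
                                 inflation = config$inflation,
                                 min_aln_len = config$min_aln_len)
    if (config$map_method == "alignment") {
      om <- map_orfs_to_clusters(
        data.frame(id = cohort$orfs$orf_id, sequence = cohort$orfs$sequence,
                   stringsAsFactors = FALSE),
        clusters, nr, min_identity = config$min_identity,
        min_aln_len = config$min_aln_len)
      cluster_map <- setNames(om$cluster_id, om$orf_id)
    } else {
      # ancestry: an ORF belongs to the cluster containing its source protein
      ref_cluster <- setNames(clusters$cluster_id, clusters$member_id)
      cluster_map <- setNames(unname(ref_cluster[cohort$orfs$ref_id]),
                              cohort$orfs$orf_id)
    }
    # unmapped ORFs become singleton features
    na_map <- is.na(cluster_map)
    cluster_map[na_map] <- paste0("SGL_", names(cluster_map)[na_map])
    list(nr = nr, clusters = clusters, cluster_map = cluster_map)
  })

  filt <- run_stage("psm_quality", od, {
    acc <- filter_psms(sim$psms, config$policy, search_kind = "MM")
    fdr <- fdr_report(acc)
    pl <- protein_level_filter(acc, "MM", config$policy, res$cluster_map)
    list(accepted = pl$psms, retained = pl$retained, fdr = fdr)
  })

  quant <- run_stage("quantification", od, {
    profiles <- make_run_profiles(sim$run_profiles)
    run_order <- profiles$run_id
    targets <- filt$accepted[!as.logical(filt$accepted$is_decoy), ,
                             drop = FALSE]
    raw <- attribute_spectra(targets, res$cluster_map, runs = run_order,
                             shared_label = "_shared")
    raw <- raw[rownames(raw) != "_shared", , drop = FALSE]
    norm <- normalize_counts(raw, profiles)
    # cluster -> annotation maps via the representative's source protein
    reps <- attr(res$clusters, "representatives")
    pr <- refs$proteins
    rep_idx <- match(reps, pr$id)
    genus_map <- setNames(pr$genus[rep_idx], names(reps))
    cog_map <- setNames(pr$cog[rep_idx], names(reps))
    ko_map <- setNames(pr$ko[rep_idx], names(reps))
    list(profiles = profiles, raw = raw, norm = norm,
         genus = aggregate_features(norm, genus_map),
         cog = aggregate_features(norm, cog_map),
         ko = aggregate_features(norm, ko_map),
         genus_map = genus_map, ko_map = ko_map)
  })

  diffs <- run_stage("differential_stats", od, {
    out <- list()
    for (cmp in config$comparisons) {
      ga <- quant$profiles$run_id[quant$profiles$group == cmp[1]]
      gb <- quant$profiles$run_id[quant$profiles$group == cmp[2]]
      key <- paste(cmp, collapse = "_vs_")
      for (lvl in c("cluster", "cog", "genus")) {
        mat <- switch(lvl, cluster = quant$norm, cog = quant$cog,
                      genus = quant$genus)
        out[[paste(key, lvl, sep = ".")]] <- call_differential(
          mat, ga, gb, alpha_q = config$alpha_q,
          min_median_diff = config$min_median_diff,
          min_count = config$min_count, min_runs = config$min_runs)
      }
    }
    out
  })

  mods <- run_stage("module_analysis", od, {
    detected <- rownames(quant$ko)[rowSums(quant$ko) > 0]
    cov <- module_coverage(detected, refs$modules,
                           config$module_min_coverage)
    gated <- cov$module_id[cov$pass]
    ann <- data.frame(feature_id = names(quant$ko_map), ko = quant$ko_map,
                      genus = quant$genus_map[names(quant$ko_map)],
                      stringsAsFactors = FALSE)
    defs <- refs$modules[refs$modules$module_id %in% gated, , drop = FALSE]
    mod_mat <- module_abundance(quant$norm, ann, defs)
    tm_mat <- module_abundance(quant$norm, ann, defs, by_taxon = TRUE)
    out <- list(coverage = cov)
    for (cmp in config$comparisons) {
      ga <- quant$profiles$run_id[quant$profiles$group == cmp[1]]
      gb <- quant$profiles$run_id[quant$profiles$group == cmp[2]]
      key <- paste(cmp, collapse = "_vs_")
      dm <- differential_modules(mod_mat, ga, gb, fdr = config$module_fdr,
                                 min_median_diff = config$min_median_diff)
      out[[paste0(key, ".modules")]] <- dm
      if (nrow(tm_mat) >= 3L) {
        tm_lfc <- group_lfc(tm_mat, ga, gb)
        genus_lfc <- group_lfc(quant$genus, ga, gb)
        parts <- strsplit(rownames(tm_mat), "|", fixed = TRUE)
        pts <- data.frame(
          taxon = vapply(parts, `[`, character(1), 1L),
          module_id = vapply(parts, `[`, character(1), 2L),
          observed_lfc = unname(tm_lfc), stringsAsFactors = FALSE)
        pts$expected_lfc <- genus_lfc[pts$taxon]
        pts <- pts[!is.na(pts$expected_lfc), , drop = FALSE]
        dm_t <- differential_modules(tm_mat, ga, gb,
                                     fdr = config$module_fdr,
                                     min_median_diff = config$min_median_diff)
        pts$significant <- dm_t$significant[match(
          paste(pts$taxon, pts$module_id, sep = "|"), dm_t$module_id)]
        if (nrow(pts) >= 3L && var(pts$expected_lfc) > 0) {
          out[[paste0(key, ".deviation")]] <-
            taxon_module_deviation(pts, level = config$pi_level)
        }
      }
    }
    out
  })

  result <- list(refs = refs, cohort = cohort, sim = sim,
                 clusters = res$clusters, cluster_map = res$cluster_map,
                 fdr = filt$fdr, accepted = filt$accepted,
                 counts = quant$raw, normalized = quant$norm,
                 genus_counts = quant$genus, profiles = quant$profiles,
                 differential = diffs, modules = mods)

  if (!is.null(od)) run_stage("write_outputs", od, {
    write_fasta(refs$proteins, file.path(od, "reference_proteins.fasta"))
    write_tsv(as.data.frame(res$clusters), file.path(od, "clusters.tsv"))
    write_psm_table(sim$psms, file.path(od, "psms.tsv"))
    write_tsv(quant$profiles, file.path(od, "run_profiles.tsv"))
    write_tsv(filt$fdr, file.path(od, "fdr_report.tsv"))
    write_count_matrix(round(quant$norm, 6), file.path(od, "normalized_counts.tsv"))
    for (nm in names(diffs))
      write_tsv(within(diffs[[nm]], {
        median_a <- round(median_a, 6); median_b <- round(median_b, 6)
        median_diff <- round(median_diff, 6)
        p <- signif(p, 8); q <- signif(q, 8)
      }), file.path(od, paste0("differential.", nm, ".tsv")))
    write_tsv(mods$coverage, file.path(od, "module_coverage.tsv"))
    manifest <- list(
      seed = spec$seed,
      thresholds = list(
        min_identity = config$min_identity, inflation = config$inflation,
        min_aln_len = config$min_aln_len,
        xcorr = as.list(config$policy$xcorr_min_by_charge),
        deltcn_min = config$policy$deltcn_min,
        max_miscleavages = config$policy$max_miscleavages,
        ppm_window = config$policy$ppm_window,
        min_peptides_per_protein = config$policy$min_peptides_per_protein,
        alpha_q = config$alpha_q, min_median_diff = config$min_median_diff,
        prefilter = c(config$min_count, config$min_runs),
        module_fdr = config$module_fdr,
        module_min_coverage = config$module_min_coverage,
        pi_level = config$pi_level),
      groups = spec$groups,
      comparisons = lapply(config$comparisons, paste, collapse = "_vs_"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  result
}
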
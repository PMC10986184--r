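# End-to-end orchestration: qc -> wscore -> tractwise/gmwm/microstructure
# -> topology -> exact inference -> clinical regressions, with
# deterministic plain-text outputs carrying a provenance header.

#' Run the full connectome analysis pipeline
#'
#' Executes the pipeline stages in fixed order on a cohort (in memory or
#' read from disk), optionally writing every result table to `out_dir`
#' with a provenance header (configuration hash, seed, package version).
#' Given the same cohort and options the run is fully deterministic, so
#' repeated runs produce byte-identical output files.
#'
#' @param cohort A `cohort` object ([generate_cohort()] / [read_cohort()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param stages Prefix of
#'   `c("qc", "wscore", "tracts", "gmwm", "micro", "topology", "inference",
#'   "clinical")`; later stages need earlier ones.
#' @param island_threshold,phenotype_set,min_fraction Quality-control
#'   parameters (see [run_qc()]).
#' @param grid_size,augment_mst Filtration grid options (see [build_grid()]).
#' @param weight_source `"wscore"` (min/max-normalized w-scores) and/or
#'   `"gfa"` (untransformed GFA, missing as zero) for topology.
#' @param contrasts Betti-curve group contrasts, as a list of 2-vectors.
#' @param n_perm Permutations for validation p-values (0 = exact only).
#' @param seed Seed for permutation tests.
#' @param verbose Log stage row counts with `message()`.
#' @return Named list of stage results (class `tractopo_results`).
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         stages = c("qc", "wscore", "tracts", "gmwm", "micro",
                                    "topology", "inference", "clinical"),
                         island_threshold = 0.25,
                         phenotype_set = c("CN", "lvPPA", "PCA", "bvAD", "CBS"),
                         min_fraction = 0.5,
                         grid_size = 100L, augment_mst = FALSE,
                         weight_source = c("wscore", "gfa"),
                         contrasts = list(c("CN", "non-amnestic"),
                                          c("CN", "amnestic"),
                                          c("amnestic", "non-amnestic")),
                         n_perm = 0L, seed = 1L, verbose = FALSE) {
  all_stages <- c("qc", "wscore", "tracts", "gmwm", "micro", "topology",
                  "inference", "clinical")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)])) {
    stop("stages must form a prefix of: ", paste(all_stages, collapse = ", "))
  }
  log_ <- function(...) if (verbose) message(...)
  for (id in names(cohort$matrices)) {
    validate_connectivity_matrix(cohort$matrices[[id]], id)
  }
  header <- provenance_header(cohort, seed)
  res <- list()

  records <- impute_missing_meta(cohort$records)
  res$records <- records

  ## qc -----------------------------------------------------------------
  qc <- run_qc(cohort$matrices, records, template = cohort$template,
               island_threshold = island_threshold,
               phenotype_set = phenotype_set, min_fraction = min_fraction)
  res$qc <- qc
  log_("qc: ", length(qc$report$excluded_regions), " regions excluded, ",
       length(qc$report$retained_tracts), " tracts retained")
  if (last_stage(stages) == "qc") return(finalize_results(res, out_dir, header))

  ## wscore ---------------------------------------------------------------
  gfa_models <- fit_normative(qc$tract_table, records, c("age_at_mri", "sex"))
  w_gfa <- wscore_transform(qc$tract_table, gfa_models, records, "gfa")
  w_gfa <- wscore_truncate(w_gfa)
  keep_reg <- rownames(qc$matrices[[1L]])
  vols <- cohort$volumes[cohort$volumes$region_label %in% keep_reg, , drop = FALSE]
  vol_models <- fit_normative(vols, records, c("icv", "age_at_mri", "sex"))
  w_vol <- wscore_transform(vols, vol_models, records, "volume")
  w_vol <- wscore_truncate(w_vol)
  res$wscore <- list(gfa_models = gfa_models, vol_models = vol_models,
                     w_gfa = w_gfa, w_vol = w_vol)
  log_("wscore: ", length(gfa_models), " tract models, ", length(vol_models),
       " volume models")
  if (last_stage(stages) == "wscore") return(finalize_results(res, out_dir, header))

  ## tractwise contrasts --------------------------------------------------
  res$tracts <- list(
    group = fit_tractwise(w_gfa, records, contrast_spec("group", "mmse")),
    phenotype = fit_tractwise(w_gfa, records, contrast_spec("phenotype", "mmse"))
  )
  log_("tracts: ", sum(res$tracts$group$tracts$significant), " group-significant, ",
       sum(res$tracts$phenotype$tracts$significant), " phenotype-significant")
  if (last_stage(stages) == "tracts") return(finalize_results(res, out_dir, header))

  ## gm-wm coupling --------------------------------------------------------
  region_wm <- summarize_region_wm(w_gfa)
  res$gmwm <- list(
    region_wm = region_wm,
    group = fit_gmwm(region_wm, w_vol, records, "group"),
    phenotype = fit_gmwm(region_wm, w_vol, records, "phenotype")
  )
  if (any(!is.na(records$apoe_e4_count))) {
    res$gmwm$apoe <- tryCatch(
      fit_gmwm(region_wm, w_vol, records, "apoe_e4_count"),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "gmwm_error"))
  }
  if (last_stage(stages) == "gmwm") return(finalize_results(res, out_dir, header))

  ## global microstructure --------------------------------------------------
  res$micro <- global_micro_contrast(cohort$micro, records)
  if (last_stage(stages) == "micro") return(finalize_results(res, out_dir, header))

  ## topology ----------------------------------------------------------------
  weight_source <- match.arg(weight_source, c("wscore", "gfa"), several.ok = TRUE)
  topo <- list()
  for (src in weight_source) {
    wt <- if (src == "wscore") wscore_minmax(w_gfa) else {
      structure(data.frame(participant_id = qc$tract_table$participant_id,
                           target_id = qc$tract_table$tract,
                           w = ifelse(is.na(qc$tract_table$gfa), 0,
                                      qc$tract_table$gfa),
                           stringsAsFactors = FALSE),
                class = c("wscore_table", "data.frame"))
    }
    graphs <- tract_graphs(wt, region_labels = keep_reg)
    grid <- build_grid(graphs, n_linear = grid_size, augment_mst = augment_mst)
    topo[[src]] <- list(graphs = graphs, grid = grid,
                        curves = betti_curves(graphs, grid))
  }
  res$topology <- topo
  if (last_stage(stages) == "topology") return(finalize_results(res, out_dir, header))

  ## exact inference -----------------------------------------------------------
  inf <- list()
  for (src in names(topo)) {
    for (ct in c("betti0", "betti1")) {
      for (gp in contrasts) {
        key <- paste(src, ct, paste(gp, collapse = "_vs_"), sep = ".")
        inf[[key]] <- compare_betti_curves(topo[[src]]$curves, records,
                                           groups = gp, curve = ct,
                                           n_perm = n_perm, seed = seed)
      }
    }
  }
  res$inference <- inf
  if (last_stage(stages) == "inference") return(finalize_results(res, out_dir, header))

  ## clinical associations -------------------------------------------------------
  clin <- list()
  for (src in names(topo)) {
    ref <- inf[[paste(src, "betti0", "CN_vs_non-amnestic", sep = ".")]]
    lam <- if (!is.null(ref)) ref$lambda_star else inf[[1L]]$lambda_star
    metrics <- subnetwork_betti_at(topo[[src]]$graphs, lam)
    clin[[src]] <- list(
      lambda_star = lam, metrics = metrics,
      mmse = regress_clinical(metrics, records, "mmse"),
      duration = regress_clinical(metrics, records, "duration"),
      micro = correlate_microstructure(metrics, cohort$micro)
    )
  }
  res$clinical <- clin
  finalize_results(res, out_dir, header)
}

last_stage <- function(stages) stages[length(stages)]

# Provenance lines written at the top of every output table.
provenance_header <- function(cohort, seed) {
  cfg <- cohort$config
  if (!is.null(cfg)) class(cfg) <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(js, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  c(paste0("config_md5=", hash),
    paste0("seed=", seed),
    paste0("tractopo_version=", as.character(utils::packageVersion("tractopo"))))
}

# Write the result bundle as TSV/JSON files (deterministic content).
finalize_results <- function(res, out_dir, header) {
  class(res) <- "tractopo_results"
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write_tsv(df, file.path(out_dir, name), header)
  if (!is.null(res$qc)) {
    wt(res$qc$tract_table, "tract_table.tsv")
    rep <- res$qc$report
    jsonlite::write_json(
      list(excluded_regions = rep$excluded_regions,
           island_frequency = as.list(rep$island_frequency),
           retained_tracts = rep$retained_tracts,
           template_excluded = rep$template_excluded,
           mean_presence = rep$mean_presence),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(res$wscore)) {
    wt(as.data.frame(res$wscore$w_gfa), "wscores_gfa.tsv")
    wt(as.data.frame(res$wscore$w_vol), "wscores_volume.tsv")
  }
  if (!is.null(res$tracts)) {
    for (f in names(res$tracts)) {
      wt(res$tracts[[f]]$tracts, paste0("tractwise_", f, ".tsv"))
      if (!is.null(res$tracts[[f]]$posthoc)) {
        wt(res$tracts[[f]]$posthoc, paste0("tractwise_", f, "_posthoc.tsv"))
      }
      # edge list for brain-network plotting
      sig <- res$tracts[[f]]$tracts
      reg <- tract_regions(sig$tract)
      wt(cbind(reg, F = sig$F, q = sig$q), paste0("edges_", f, ".tsv"))
    }
  }
  if (!is.null(res$gmwm)) {
    for (f in intersect(c("group", "phenotype", "apoe"), names(res$gmwm))) {
      g <- res$gmwm[[f]]
      if (inherits(g, "gmwm_error")) next
      wt(g$fixed, paste0("gmwm_", f, "_fixed.tsv"))
      wt(g$anova, paste0("gmwm_", f, "_anova.tsv"))
    }
  }
  if (!is.null(res$micro)) wt(res$micro$tracts, "microstructure_anova.tsv")
  if (!is.null(res$topology)) {
    for (src in names(res$topology)) {
      cv <- res$topology[[src]]$curves
      th <- cv$grid$thresholds
      long <- data.frame(
        participant_id = rep(cv$participants, times = length(th)),
        lambda = rep(th, each = length(cv$participants)),
        betti0 = as.vector(cv$betti0), betti1 = as.vector(cv$betti1)
      )
      wt(long, paste0("betti_curves_", src, ".tsv"))
    }
  }
  if (!is.null(res$inference)) {
    jsonlite::write_json(
      lapply(res$inference, function(x) {
        x[c("groups", "curve", "ks_distance", "lambda_star", "q", "band",
            "p_exact", "p_permutation")]
      }),
      file.path(out_dir, "inference.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(res$clinical)) {
    for (src in names(res$clinical)) {
      cl <- res$clinical[[src]]
      wt(cl$metrics, paste0("betti_metrics_", src, ".tsv"))
      wt(cl$mmse, paste0("clinical_mmse_", src, ".tsv"))
      wt(cl$duration, paste0("clinical_duration_", src, ".tsv"))
      wt(cl$micro, paste0("betti_micro_corr_", src, ".tsv"))
    }
  }
  res
}

#' Concordance between full-cohort and subset tractwise analyses
#'
#' Re-runs quality control, w-scoring and the tractwise group/phenotype
#' contrasts on a participant subset (by default omitting patients
#' without biomarker confirmation and participants with imputed MMSE or
#' disease duration), then compares against the full-cohort results:
#' correlation of F statistics over shared tracts and concordance of
#' FDR-significance calls.
#'
#' @param cohort A `cohort` object.
#' @param full_results Results of [run_pipeline()] on the full cohort
#'   (stages through `"tracts"` at least).
#' @param keep Optional logical vector / participant-id vector selecting
#'   the subset; default applies the biomarker + imputation rule.
#' @param fdr_alpha Significance threshold for concordance calls.
#' @param ... Passed to [run_pipeline()] (QC options).
#' @return List of class `concordance_report`, one element per factor
#'   (`group`, `phenotype`): `n_shared`, `f_correlation`, `concordant`,
#'   `discordant`, `concordance_rate`, plus `subset_ids`,
#'   `tracts_only_full`, `tracts_only_subset`.
#' @export
subset_concordance <- function(cohort, full_results, keep = NULL,
                               fdr_alpha = 0.05, ...) {
  records <- impute_missing_meta(cohort$records)
  if (is.null(keep)) {
    drop <- (!is.na(records$biomarker_confirmed) & !records$biomarker_confirmed) |
      records$mmse_imputed | records$duration_imputed
    keep_ids <- records$participant_id[!drop]
  } else if (is.logical(keep)) {
    keep_ids <- cohort$records$participant_id[keep]
  } else {
    keep_ids <- keep
  }
  sub <- cohort
  sub$records <- cohort$records[cohort$records$participant_id %in% keep_ids, , drop = FALSE]
  sub$matrices <- cohort$matrices[keep_ids]
  sub$volumes <- cohort$volumes[cohort$volumes$participant_id %in% keep_ids, , drop = FALSE]
  sub$micro <- cohort$micro[cohort$micro$participant_id %in% keep_ids, , drop = FALSE]
  sub_res <- run_pipeline(sub, out_dir = NULL, stages = c("qc", "wscore", "tracts"), ...)

  out <- list(subset_ids = keep_ids)
  for (f in c("group", "phenotype")) {
    full_t <- full_results$tracts[[f]]$tracts
    sub_t <- sub_res$tracts[[f]]$tracts
    shared <- intersect(full_t$tract, sub_t$tract)
    fi <- full_t[match(shared, full_t$tract), ]
    si <- sub_t[match(shared, sub_t$tract), ]
    ok <- is.finite(fi$F) & is.finite(si$F)
    conc <- (fi$q < fdr_alpha) == (si$q < fdr_alpha)
    conc <- conc[!is.na(conc)]
    out[[f]] <- list(
      n_shared = length(shared),
      f_correlation = if (sum(ok) >= 3) cor(fi$F[ok], si$F[ok]) else NA_real_,
      concordant = sum(conc), discordant = sum(!conc),
      concordance_rate = mean(conc)
    )
  }
  out$tracts_only_full <- setdiff(full_results$tracts$group$tracts$tract,
                                  sub_res$tracts$group$tracts$tract)
  out$tracts_only_subset <- setdiff(sub_res$tracts$group$tracts$tract,
                                    full_results$tracts$group$tracts$tract)
  out$subset_results <- sub_res
  class(out) <- "concordance_report"
  out
}
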
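# End-to-end driver: features -> R2SN -> motif census -> PMV -> statistics
# (-> spatial association when map tables are supplied).

#' Assemble a resolved pipeline configuration
#'
#' Defaults follow the method's reference choices: 25 retained features,
#' correlation cap 0.90, alpha 0.05, top 500 genes.  Every run writes its
#' resolved configuration next to its outputs.
#'
#' @param atlas,manifest,features_dir input paths (or in-memory objects for
#'   `atlas`/`manifest`).
#' @param gene_maps,receptor_maps optional region x map table paths (or
#'   matrices) enabling the spatial-association stage.
#' @param target_count,r_cap feature-selection parameters.
#' @param alpha family-wise level for all Bonferroni corrections.
#' @param n_perm,n_boot,top_k spatial-association parameters.
#' @param seed integer seed governing every stochastic step.
#' @param reference_group control group label; pairwise Z maps are
#'   case-versus-reference.
#' @param pmv_reference `"all"` fits the PMV loading on every subject;
#'   a group label restricts the fit to that group.
#' @param posthoc_universe `"significant"` restricts Mann-Whitney maps to
#'   the Kruskal-Wallis-significant regions, `"all"` tests whole-brain.
#' @param tie_correction use tie-corrected sigma_U in Z maps.
#' @param orientation PCA orientation, see [fit_pmv_model()].
#' @param clinical_scores optional character vector naming manifest score
#'   columns; `NULL` autodetects numeric columns.
#' @param clinical_subset group labels pooled for clinical correlations
#'   (`NULL`: all non-reference groups).
#' @return named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(atlas = NULL, manifest = NULL,
                            features_dir = NULL, gene_maps = NULL,
                            receptor_maps = NULL,
                            target_count = 25L, r_cap = 0.90, alpha = 0.05,
                            n_perm = 999L, n_boot = 1000L, top_k = 500L,
                            seed = 1L, reference_group = "NC",
                            pmv_reference = "all",
                            posthoc_universe = c("significant", "all"),
                            tie_correction = FALSE,
                            orientation = c("motifs", "regions"),
                            clinical_scores = NULL,
                            clinical_subset = NULL) {
  structure(
    list(atlas = atlas, manifest = manifest, features_dir = features_dir,
         gene_maps = gene_maps, receptor_maps = receptor_maps,
         target_count = target_count, r_cap = r_cap, alpha = alpha,
         n_perm = n_perm, n_boot = n_boot, top_k = top_k, seed = seed,
         reference_group = reference_group, pmv_reference = pmv_reference,
         posthoc_universe = match.arg(posthoc_universe),
         tie_correction = tie_correction,
         orientation = match.arg(orientation),
         clinical_scores = clinical_scores,
         clinical_subset = clinical_subset),
    class = "pipeline_config"
  )
}

resolve_maps <- function(spec) {
  if (is.null(spec)) return(NULL)
  if (is.matrix(spec)) spec else read_spatial_maps(spec)
}

#' Run the full PMV pipeline
#'
#' Loads (or accepts) a cohort, selects features on the cohort, builds each
#' subject's R2SN, labels edges at cohort-median thresholds, counts the 20
#' motif types per region, fits the PMV model on the reference cohort and
#' projects every subject, then runs the group statistics
#' (Kruskal-Wallis map, pairwise Mann-Whitney Z maps against the reference
#' group, clinical correlation maps, partition summaries) and, when map
#' tables are configured, the spatial-association stage.  All tables, the
#' resolved configuration and a run summary are written to `out_dir`; the
#' run is deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param bundle optional preloaded [load_cohort()] bundle (skips reading).
#' @param quiet suppress progress messages.
#' @return the run summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, bundle = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[pmvnet] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(bundle)) bundle <- load_cohort(config)
  atlas <- bundle$atlas
  records <- bundle$records
  features <- bundle$features
  say("loaded ", length(features), " subjects, ", nrow(atlas), " regions")

  selected <- select_features(features, target_count = config$target_count,
                              r_cap = config$r_cap)
  writeLines(as.character(selected),
             file.path(out_dir, "selected_features.txt"))

  r2sns <- lapply(features, function(fm) {
    build_r2sn(minmax_normalize(fm), selected)
  })
  distances <- compute_edge_lengths(atlas)
  thr <- compute_thresholds(r2sns, distances, provenance = "run")
  write_threshold_pair(thr, file.path(out_dir, "thresholds.yaml"))
  say(sprintf("thresholds: strength median %.4f, length median %.2f mm",
              thr$strength_median, thr$length_median))

  catalog <- motif_catalog()
  counts <- lapply(r2sns, function(net) {
    count_motifs(label_edges(net, distances, thr), catalog)
  })

  ref_ids <- if (identical(config$pmv_reference, "all")) {
    records$subject_id
  } else {
    records$subject_id[records$group %in% config$pmv_reference]
  }
  model <- fit_pmv_model(counts[ref_ids], orientation = config$orientation)
  write_pmv_model(model, file.path(out_dir, "pmv_model.yaml"))
  say(sprintf("PMV component 1 explains %.1f%% of motif variance",
              100 * model$variance_explained_1))

  pmv <- t(vapply(counts, project_pmv, numeric(nrow(atlas)), model = model))
  rownames(pmv) <- names(counts)
  colnames(pmv) <- as.character(atlas$region_id)
  pmv_df <- data.frame(subject_id = rownames(pmv), pmv,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(pmv_df, file.path(out_dir, "pmv_maps.tsv"))

  groups <- records$group[match(rownames(pmv), records$subject_id)]
  summary <- list(n_subjects = nrow(pmv), n_regions = ncol(pmv),
                  groups = sort(unique(groups)),
                  variance_explained_1 = model$variance_explained_1,
                  strength_median = thr$strength_median,
                  length_median = thr$length_median)

  kw <- NULL
  zmaps <- list()
  if (length(unique(groups)) >= 2L) {
    kw <- kruskal_wallis_map(pmv, groups, alpha = config$alpha)
    write_tsv(as.data.frame(kw), file.path(out_dir, "kruskal_wallis.tsv"))
    sig_regions <- kw$region[kw$significant]
    summary$n_significant_regions <- length(sig_regions)
    say(length(sig_regions), " region(s) significant after Bonferroni")
    universe <- if (config$posthoc_universe == "significant") {
      sig_regions
    } else {
      kw$region
    }
    others <- setdiff(unique(groups), config$reference_group)
    for (g in others) {
      if (length(universe) == 0L) break
      mw <- mannwhitney_zmap(pmv, groups, group_a = g,
                             group_b = config$reference_group,
                             restrict_to = universe, alpha = config$alpha,
                             tie_correction = config$tie_correction)
      zmaps[[g]] <- mw$z
      write_tsv(as.data.frame(mw$table),
                file.path(out_dir, sprintf("zmap_%s_vs_%s.tsv", g,
                                           config$reference_group)))
    }
    if (length(zmaps) > 0L) {
      top <- names(sort(abs(zmaps[[1L]]), decreasing = TRUE))
      summary$top_regions <- utils::head(top, 10L)
    }
  }

  score_cols <- config$clinical_scores
  if (is.null(score_cols)) {
    cand <- setdiff(names(records),
                    c("subject_id", "group", "site_id", "dose"))
    score_cols <- cand[vapply(records[cand], is.numeric, TRUE)]
  }
  if (length(score_cols) > 0L) {
    subset <- config$clinical_subset %||%
      setdiff(unique(groups), config$reference_group)
    if (length(subset) > 0L) {
      cors <- clinical_correlation_map(pmv, records, score_cols,
                                       subset = subset,
                                       alpha = config$alpha)
      for (sc in names(cors)) {
        write_tsv(as.data.frame(cors[[sc]]),
                  file.path(out_dir, sprintf("clinical_%s.tsv", sc)))
      }
    }
  }

  for (part in c("functional", "anatomical")) {
    ps <- summarize_by_partition(pmv, atlas, which = part,
                                 alpha = config$alpha)
    write_tsv(ps$summary,
              file.path(out_dir, sprintf("partition_%s_summary.tsv", part)))
    if (!is.null(ps$pairwise)) {
      write_tsv(ps$pairwise,
                file.path(out_dir, sprintf("partition_%s_pairwise.tsv",
                                           part)))
    }
  }

  if (length(zmaps) > 0L &&
      (!is.null(config$gene_maps) || !is.null(config$receptor_maps))) {
    target <- as.numeric(zmaps[[length(zmaps)]])
    gene_maps <- resolve_maps(config$gene_maps)
    if (!is.null(gene_maps)) {
      sub <- gene_maps[names(zmaps[[length(zmaps)]]), , drop = FALSE]
      pls <- pls1_association(sub, target, n_perm = config$n_perm,
                              seed = config$seed)
      boot <- bootstrap_gene_zscores(sub, target, n_boot = config$n_boot,
                                     seed = config$seed,
                                     top_k = min(config$top_k, ncol(sub)))
      write_tsv(boot$table, file.path(out_dir, "gene_zscores.tsv"))
      writeLines(boot$top_genes, file.path(out_dir, "top_genes.txt"))
      summary$pls_r_with_target <- pls$r_with_target
      summary$pls_p_perm <- pls$p_perm
      say(sprintf("PLS1: r = %.3f, p_perm = %.4g", pls$r_with_target,
                  pls$p_perm))
    }
    receptor_maps <- resolve_maps(config$receptor_maps)
    if (!is.null(receptor_maps)) {
      sub <- receptor_maps[names(zmaps[[length(zmaps)]]), , drop = FALSE]
      panel <- map_correlation_panel(target, sub, n_perm = config$n_perm,
                                     seed = config$seed,
                                     alpha = config$alpha)
      write_tsv(panel, file.path(out_dir, "receptor_panel.tsv"))
    }
  }

  cfg_out <- unclass(config)
  cfg_out$atlas <- if (is.character(cfg_out$atlas)) cfg_out$atlas else
    "<in-memory>"
  cfg_out$manifest <- if (is.character(cfg_out$manifest)) cfg_out$manifest
    else "<in-memory>"
  cfg_out$gene_maps <- if (is.character(cfg_out$gene_maps) ||
                             is.null(cfg_out$gene_maps)) cfg_out$gene_maps
    else "<in-memory>"
  cfg_out$receptor_maps <- if (is.character(cfg_out$receptor_maps) ||
                                 is.null(cfg_out$receptor_maps))
    cfg_out$receptor_maps else "<in-memory>"
  yaml::write_yaml(cfg_out, file.path(out_dir, "config_resolved.yaml"))
  yaml::write_yaml(summary, file.path(out_dir, "run_summary.yaml"),
                   precision = 15L)
  say("done; outputs in ", out_dir)
  invisible(summary)
}
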
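#' One-command end-to-end demonstration on a synthetic cohort
#'
#' Simulates a cohort, writes it to disk, then runs the whole pipeline:
#' independence filter, classifier screen on the independent hervRNAs,
#' panel construction, resubstitution and leave-one-out classification,
#' and the methylation integration, finally comparing every stage against
#' the simulation ground truth. All outputs are plain text (TSV/JSON) with
#' no timestamps, so a re-run with the same seed is byte-identical.
#'
#' @param outdir output directory (created; must be empty unless `force`).
#' @param seed integer seed used for the simulation config when `cfg` is
#'   not supplied.
#' @param cfg optional [sim_config()]; overrides `seed`.
#' @param filter_cfg a [filter_config()].
#' @param screen_cfg a [screen_config()].
#' @param cluster_gap_bp panel clustering gap (default 200 kbp).
#' @param loo run the leave-one-out cross-validation (default `TRUE`).
#' @param force overwrite a non-empty `outdir`.
#' @return the report, an invisible list (also written as `report.json`
#'   and `report.txt`).
#' @export
run_demo <- function(outdir, seed = 1, cfg = NULL,
                     filter_cfg = filter_config(),
                     screen_cfg = screen_config(),
                     cluster_gap_bp = 2e5, loo = TRUE, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory is not empty (use force = TRUE): ", outdir,
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg)) cfg <- sim_config(seed)

  cohort <- simulate_cohort(cfg)
  write_dataset(cohort, file.path(outdir, "data"), force = force)
  expr <- cohort$expr; loci <- cohort$loci
  labels <- cohort$labels; truth <- cohort$truth

  # stage 1: independence filter
  drivers <- filter_independent(expr, loci, filter_cfg)
  readr::write_tsv(drivers, file.path(outdir, "drivers.tsv"),
                   progress = FALSE)
  tr <- truth[match(drivers$herv_id, truth$herv_id), ]
  is_drv_truth <- tr$role == "driven"
  is_drv_call <- drivers$status == "driven"
  driven_sens <- mean(is_drv_call[is_drv_truth])
  driven_spec <- mean(!is_drv_call[!is_drv_truth])
  independent <- drivers$herv_id[drivers$status == "independent"]

  # stage 2: classifier screen on independently expressed hervRNAs
  cand <- suppressWarnings(
    run_screen(expr, labels, screen_cfg, loci = loci,
               restrict_to = independent))
  readr::write_tsv(cand, file.path(outdir, "candidates.tsv"),
                   progress = FALSE)
  planted <- truth[truth$role == "marker", ]
  recovered <- planted |>
    dplyr::group_by(.data$target_subgroup, .data$cluster_id) |>
    dplyr::summarise(hit = any(.data$herv_id %in% cand$herv_id),
                     .groups = "drop") |>
    dplyr::group_by(.data$target_subgroup) |>
    dplyr::summarise(clusters_recovered = sum(.data$hit),
                     clusters_planted = dplyr::n(), .groups = "drop")

  # stage 3: panel, resubstitution and leave-one-out classification
  panel <- build_panel(cand, cluster_gap_bp, cohort_id = "synthetic-demo")
  write_panel_json(panel, file.path(outdir, "panel.json"))
  calls <- classify_samples(expr, panel)
  readr::write_tsv(calls, file.path(outdir, "calls.tsv"), progress = FALSE)
  ev <- evaluate_calls(calls, labels)
  cv <- NULL
  if (loo) {
    cv <- crossvalidate(expr, loci, labels, screen_cfg, cluster_gap_bp,
                        restrict_to = independent)
    readr::write_tsv(cv$calls, file.path(outdir, "cv_calls.tsv"),
                     progress = FALSE)
  }

  # stage 4: methylation integration over the classifier promoters
  meth_report <- NULL
  if (!is.null(cohort$meth)) {
    prom <- promoter_regions(
      loci[loci$feature_id %in% unique(cand$herv_id), , drop = FALSE])
    pm <- summarize_promoter_beta(cohort$meth, prom,
                                  samples = labels$sample_id)
    mec <- methylation_expression_correlation(pm, expr)
    readr::write_tsv(mec, file.path(outdir, "methylation_correlation.tsv"),
                     progress = FALSE)
    g3 <- if ("Group3" %in% labels$subgroup) "Group3" else
      labels$subgroup[1]
    dm <- differential_methylation(cohort$meth, prom, labels, g3)
    readr::write_tsv(dm, file.path(outdir, "differential_methylation.tsv"),
                     progress = FALSE)
    anti_ids <- truth$herv_id[truth$anticorrelated]
    tested_anti <- intersect(anti_ids, mec$herv_id)
    null_ids <- setdiff(mec$herv_id, anti_ids)
    meth_report <- list(
      n_promoters_tested = nrow(mec),
      anticorrelation_sensitivity =
        if (length(tested_anti) > 0)
          mean(mec$flagged[mec$herv_id %in% tested_anti]) else NA,
      null_flag_rate =
        if (length(null_ids) > 0)
          mean(mec$flagged[mec$herv_id %in% null_ids]) else NA,
      n_hypomethylated = sum(dm$hypomethylated))
  }

  report <- list(
    seed = cfg$seed,
    n_samples = ncol(expr$tpm),
    n_hervs = sum(expr$feature_class == "hervRNA"),
    n_independent = length(independent),
    driven_sensitivity = driven_sens,
    driven_specificity = driven_spec,
    n_classifiers = nrow(cand),
    n_clusters = dplyr::n_distinct(panel$clusters$cluster_id),
    clusters_recovered = recovered,
    resubstitution_accuracy = ev$accuracy,
    loo_accuracy = if (loo) cv$accuracy else NA,
    loo_excluded = if (loo) cv$n_excluded else NA,
    methylation = meth_report)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(format_demo_report(report), file.path(outdir, "report.txt"))
  invisible(report)
}

format_demo_report <- function(r) {
  rec <- r$clusters_recovered
  c(sprintf("synthetic cohort: seed %d, %d samples, %d hervRNAs",
            r$seed, r$n_samples, r$n_hervs),
    sprintf("independence filter: %d independent; driven call sensitivity %.3f, specificity %.3f",
            r$n_independent, r$driven_sensitivity, r$driven_specificity),
    sprintf("classifier screen: %d classifiers in %d clusters",
            r$n_classifiers, r$n_clusters),
    sprintf("  planted clusters recovered: %s",
            paste(sprintf("%s %d/%d", rec$target_subgroup,
                          rec$clusters_recovered, rec$clusters_planted),
                  collapse = ", ")),
    sprintf("classification: resubstitution accuracy %.3f%s",
            r$resubstitution_accuracy,
            if (!is.na(r$loo_accuracy))
              sprintf(", leave-one-out accuracy %.3f (%d folds excluded)",
                      r$loo_accuracy, r$loo_excluded) else ""),
    if (!is.null(r$methylation))
      sprintf("methylation: %d promoters tested; anticorrelation sensitivity %.3f, null flag rate %.3f, %d hypomethylated",
              r$methylation$n_promoters_tested,
              r$methylation$anticorrelation_sensitivity,
              r$methylation$null_flag_rate,
              r$methylation$n_hypomethylated)
    else "methylation: skipped")
}
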
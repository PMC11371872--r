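#' Pipeline configuration
#'
#' Collects all tunable parameters of the analysis pipeline with their
#' defaults: segment target area 200 x 200 um^2, the 99th-percentile summary
#' statistic, cluster-forming threshold t > 2.0, 10,000 permutations, alpha
#' 0.05 over 6 regions, and the <= 10-year antemortem-interval filter. Every
#' default is overridable and the object round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param seed Integer master seed; all pipeline randomness derives from it.
#' @param n_subjects Cohort size for the synthetic stages.
#' @param target_segment_area_um2 Target segment area in square microns.
#' @param statistic Box/ROI summary statistic (see [summary_statistics()]).
#' @param threshold Cluster-forming t threshold.
#' @param n_perm Permutation count for cluster correction.
#' @param alpha Nominal significance level.
#' @param n_regions Number of regions for the Bonferroni threshold.
#' @param max_antemortem_years Antemortem-interval inclusion bound (years);
#'   the boundary is inclusive. Set to 3 for the stricter sensitivity
#'   filter.
#' @param paths Optional named list of input paths (heatmaps, annotations,
#'   cohort CSV, mesh) for runs on real data.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_subjects = 140L,
                            target_segment_area_um2 = 200 * 200,
                            statistic = "q99",
                            threshold = 2.0,
                            n_perm = 10000L,
                            alpha = 0.05,
                            n_regions = 6L,
                            max_antemortem_years = 10,
                            paths = NULL) {
  statistic <- match.arg(statistic, summary_statistics())
  stopifnot(target_segment_area_um2 > 0, threshold > 0, n_perm >= 1,
            alpha > 0, alpha < 1, n_regions >= 1, max_antemortem_years > 0)
  if (is.list(paths) && length(paths) == 0L) paths <- NULL
  structure(
    list(seed = as.integer(seed),
         n_subjects = as.integer(n_subjects),
         target_segment_area_um2 = target_segment_area_um2,
         statistic = statistic,
         threshold = threshold,
         n_perm = as.integer(n_perm),
         alpha = alpha,
         n_regions = as.integer(n_regions),
         max_antemortem_years = max_antemortem_years,
         paths = paths),
    class = "pipeline_config"
  )
}

#' Apply the cohort inclusion filters
#'
#' Excludes subjects whose antemortem interval exceeds the bound (inclusive
#' boundary: an interval of exactly 10 years is kept under the default) and
#' subjects whose ipsilateral hemisphere failed segmentation/image QC.
#' Per-subject eligibility flags and exclusion reasons are returned
#' alongside the filtered table.
#'
#' @param cohort Cohort data frame; must contain `subject_id`,
#'   `antemortem_interval` and `qc_ipsilateral`.
#' @param config A [pipeline_config()] (only `max_antemortem_years` is
#'   used).
#' @return List with `included` (filtered cohort) and `flags` (data frame:
#'   `subject_id`, `antemortem_interval_ok`, `ipsilateral_qc_ok`,
#'   `included`, `reason`).
#' @export
apply_inclusion_filters <- function(cohort, config = pipeline_config()) {
  required <- c("subject_id", "antemortem_interval", "qc_ipsilateral")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  interval_ok <- !is.na(cohort$antemortem_interval) &
    cohort$antemortem_interval <= config$max_antemortem_years
  qc_ok <- !is.na(cohort$qc_ipsilateral) & cohort$qc_ipsilateral
  included <- interval_ok & qc_ok
  reason <- rep("", nrow(cohort))
  reason[!interval_ok] <- sprintf("antemortem interval > %g years",
                                  config$max_antemortem_years)
  reason[interval_ok & !qc_ok] <- "failed ipsilateral QC"
  flags <- data.frame(
    subject_id = cohort$subject_id,
    antemortem_interval_ok = interval_ok,
    ipsilateral_qc_ok = qc_ok,
    included = included,
    reason = reason,
    stringsAsFactors = FALSE)
  list(included = cohort[included, , drop = FALSE], flags = flags)
}

#' Run the full synthetic pipeline end to end
#'
#' Executes every stage against synthetic data generated from the config
#' seed: heatmap quantification on a small set of simulated sampling boxes,
#' cohort generation and inclusion filtering, staging validation (adjacent
#' Braak-stage AUCs of the tangles summary measure), ROI-level standardized
#' models in the whole cohort and both staging subgroups, quantitative vs
#' semi-quantitative model comparison per region, and surface cluster
#' inference on a planted-effect dataset. All tables are written as CSV, the
#' t-map mesh as ASCII PLY, and a JSON run manifest (package version, seed,
#' config hash, per-stage row counts) alongside. Outputs are deterministic
#' given the seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `filters`, `quantification`, `validation`, `models`, `comparisons`,
#'   `surface`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("mtlquant_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # stage 1: heatmap quantification on simulated sampling boxes
  sev_model <- severity_model()
  severities <- c(0.5, 1.5, 3, 5)
  quant_rows <- list()
  for (i in seq_along(severities)) {
    hm <- generate_heatmap(severities[i], box_shape_px = c(160L, 160L),
                           pixel_size_um = 8, model = sev_model,
                           seed = seed + i)
    box <- sampling_box(matrix(TRUE, 160L, 160L), "CA1", pixel_size_um = 8,
                        box_id = paste0("box", i))
    part <- partition_roi(box, config$target_segment_area_um2)
    seg <- segment_averages(hm, part)
    quant_rows[[i]] <- data.frame(
      box_id = paste0("box", i),
      severity = severities[i],
      n_segments = length(seg),
      statistic = config$statistic,
      value = box_summary(seg, config$statistic))
  }
  quantification <- do.call(rbind, quant_rows)

  # stage 2: cohort generation and inclusion filtering
  cohort <- generate_cohort(config$n_subjects, seed = seed)
  filt <- apply_inclusion_filters(cohort, config)
  imaging <- filt$included

  # stage 3: validation of the quantitative summary against staging
  validation <- stagewise_auc(cohort$tangles_q, cohort$braak_stage)

  # stage 4: ROI-level models, whole cohort and subgroups
  preds <- c("tangles_q", "threads_q", "mtl_ptdp_sq")
  models <- list(
    whole = run_cohort_analyses(imaging, preds, "whole",
                                alpha = config$alpha),
    advanced_adnc = run_cohort_analyses(imaging, preds, "advanced_adnc",
                                        alpha = config$alpha),
    late = run_cohort_analyses(imaging, preds, "late", alpha = config$alpha))

  # stage 5: quantitative vs semi-quantitative model comparison
  comparisons <- list()
  for (region in names(imaging_regions())) {
    fq <- fit_region_model(imaging, region,
                           c("tangles_q", "threads_q"),
                           covariates = c("age", "sex", "field_strength",
                                          "antemortem_interval",
                                          "mtl_ptdp_sq"))
    fs <- fit_region_model(imaging, region, "mtl_ptau_sq",
                           covariates = c("age", "sex", "field_strength",
                                          "antemortem_interval",
                                          "mtl_ptdp_sq"))
    comparisons[[region]] <- compare_models(fq, fs)
  }
  comparison_table <- do.call(rbind, lapply(comparisons, function(cmp) {
    data.frame(region = cmp$region, delta_r2_adj = cmp$delta_r2_adj,
               delta_pred_error = cmp$delta_pred_error,
               delta_aicc = cmp$delta_aicc, delta_bic = cmp$delta_bic,
               favours = cmp$favours, evidence = cmp$evidence_label)
  }))

  # stage 6: surface cluster inference on a planted-effect dataset
  mesh <- planar_grid_mesh(32L, 32L)
  n_surf <- min(nrow(imaging), 60L)
  surf <- generate_surface_dataset(
    n_surf, mesh = mesh,
    pathology = imaging$tangles_q[seq_len(n_surf)],
    effect = 0.8, seed = seed + 100L)
  design <- cbind(pathology = surf$pathology)
  sg <- surface_glm(surf$thickness, design, "pathology", mesh,
                    n_perm = config$n_perm, threshold = config$threshold,
                    seed = seed + 200L)

  # outputs
  utils::write.csv(quantification, file.path(out_dir, "quantification.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(filt$flags, file.path(out_dir, "eligibility_flags.csv"),
                   row.names = FALSE)
  utils::write.csv(validation, file.path(out_dir, "stage_validation.csv"),
                   row.names = FALSE)
  for (nm in names(models)) {
    utils::write.csv(models[[nm]]$table,
                     file.path(out_dir, paste0("models_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(comparison_table,
                   file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(summary(sg), file.path(out_dir, "surface_clusters.csv"),
                   row.names = FALSE)
  cluster_id <- numeric(length(sg$tmap))
  for (i in seq_along(sg$clusters)) {
    cluster_id[sg$clusters[[i]]$vertex_ids] <- i
  }
  write_mesh_ply(mesh, file.path(out_dir, "tmap.ply"),
                 scalars = list(t = sg$tmap, cluster = cluster_id))
  write_config(config, file.path(out_dir, "config.json"))

  manifest <- list(
    package = "mtlquant",
    version = as.character(utils::packageVersion("mtlquant")),
    seed = seed,
    config_hash = config_hash(config),
    rows = list(
      cohort = nrow(cohort),
      imaging = nrow(imaging),
      excluded = nrow(cohort) - nrow(imaging),
      quantified_boxes = nrow(quantification),
      clusters = length(sg$clusters)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, filters = filt,
                 quantification = quantification, validation = validation,
                 models = models, comparisons = comparisons,
                 surface = sg, manifest = manifest, out_dir = out_dir))
}
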
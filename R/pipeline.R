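#' Pipeline configuration with study defaults
#'
#' Defaults mirror the study design: TR 2 s, 309 acquired volumes of which
#' the first 3 are discarded (306 analyzed), 204 trials every 3 s with 20 PM
#' trials, 21 subjects with 6 runs each, lags -50..+50 s in 5-lag windows.
#' Any element can be overridden by name.
#'
#' @param ... named overrides of the nested defaults, e.g.
#'   `cohort = list(n_subjects = 3)`.
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scan = list(tr_s = 2, n_volumes = 306L, dummy_volumes = 3L),
    task = list(n_trials = 204L, n_pm = 20L, min_gap = 4L, n_lead_og = 4L,
                soa_s = 3, duration_s = 0.5),
    cohort = list(n_subjects = 21L, runs_per_subject = 6L),
    grid = list(shape = c(12L, 12L, 8L), n_positive = 24L, n_negative = 24L,
                amplitude = 0.5, neg_lead_s = 0, pos_lead_s = 0,
                task_amplitude = 1, noise_sd = 1, drift_slope = 0.2),
    analysis = list(lags = lag_grid(), window_size = 5L,
                    transform = "identity", glm_alpha = 0.05,
                    lag_alpha = 0.05, n_pretests = 5L,
                    roi_threshold = roi_alpha(), correction = "bonferroni"),
    seed = 1L
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Run the full pipeline: simulate, behavior, GLM, lag correlation
#'
#' Simulates a cohort from the configuration, runs the behavioral analyses,
#' the first-level parametric GLM with group random-effects maps, and the
#' lagged cross-correlation with group window contrasts, GLM-similarity
#' curve, and ROI onset analysis. When `out_dir` is given, tidy TSV result
#' tables and a JSON manifest (seeds, parameters, thresholds) are written.
#'
#' @param config from [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `behavior`, `glm`, `lagcorr`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  specs <- do.call(default_voxel_specs,
                   c(list(grid_shape = config$grid$shape),
                     config$grid[setdiff(names(config$grid), "shape")]))
  cohort <- simulate_cohort(
    n_subjects = config$cohort$n_subjects,
    runs_per_subject = config$cohort$runs_per_subject,
    voxel_specs = specs, tr_s = config$scan$tr_s,
    n_volumes = config$scan$n_volumes, task = config$task,
    seed = config$seed)

  behavior <- list(performance = performance_summary(cohort),
                   pre_pm = pre_pm_analysis(cohort),
                   distance = distance_rt_correlation(cohort))

  glm_res <- pipeline_glm(cohort, config)
  lag_res <- pipeline_lagcorr(cohort, glm_res, config)

  out <- list(behavior = behavior, glm = glm_res, lagcorr = lag_res,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# First-level fits per run, subject contrasts, group maps.
pipeline_glm <- function(cohort, config) {
  fits <- lapply(cohort$subjects, function(runs)
    lapply(runs, function(r) {
      dm <- build_design_matrix(r$events, r$motion,
                                tr_s = config$scan$tr_s,
                                n_volumes = config$scan$n_volumes)
      fit_run_glm(r$bold, dm)
    }))
  pmod <- t(vapply(fits, subject_contrast, column = "pmod_RT_OG_correct",
                   numeric(nrow(cohort$voxel_specs))))
  task <- t(vapply(fits, subject_contrast, column = "onset_OG_correct",
                   numeric(nrow(cohort$voxel_specs))))
  mod_map <- group_ttest_map(pmod, alpha = config$analysis$glm_alpha,
                             correction = config$analysis$correction)
  task_map <- group_ttest_map(task, alpha = config$analysis$glm_alpha,
                              correction = config$analysis$correction)
  list(subject_pmod = pmod, subject_task = task,
       modulation_map = mod_map, task_map = task_map,
       deact_pos_overlap = overlap_map(task_map$neg_mask, mod_map$pos_mask))
}

# Per-subject lag profiles, window contrasts, similarity, ROI onsets.
pipeline_lagcorr <- function(cohort, glm_res, config) {
  profs <- lapply(cohort$subjects, subject_profile,
                  lags = config$analysis$lags,
                  transform = config$analysis$transform)
  z <- stack_profiles(profs)
  lags <- config$analysis$lags
  ws <- config$analysis$window_size
  centers <- lags[seq(1 + ws %/% 2, length(lags) - ws %/% 2, by = ws)]
  windows <- lapply(centers, function(cc) (cc - ws %/% 2):(cc + ws %/% 2))
  wmaps <- lapply(windows, function(w)
    group_window_contrast(z, w, alpha = config$analysis$lag_alpha,
                          n_pretests = config$analysis$n_pretests,
                          correction = config$analysis$correction))
  z_mean <- apply(z, c(2, 3), mean, na.rm = TRUE)
  dimnames(z_mean)[[2]] <- as.character(lags)
  sim <- glm_similarity_by_lag(colMeans(glm_res$subject_pmod), z_mean)
  pos_mask <- glm_res$modulation_map$pos_mask
  neg_mask <- glm_res$modulation_map$neg_mask
  rois <- NULL
  if (any(pos_mask) && any(neg_mask)) {
    pos_prof <- roi_profile(z, pos_mask,
                            threshold = config$analysis$roi_threshold)
    neg_prof <- roi_profile(z, neg_mask,
                            threshold = config$analysis$roi_threshold)
    rois <- list(positive = pos_prof, negative = neg_prof,
                 ordering = compare_onsets(neg_prof, pos_prof))
  }
  list(profiles = z, window_maps = wmaps, similarity = sim, rois = rois)
}

# Tidy TSV tables + JSON manifest for a pipeline result.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$behavior$performance$tests,
                     file.path(out_dir, "behavior_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$lagcorr$similarity$similarity,
                     file.path(out_dir, "glm_similarity_by_lag.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$lagcorr$rois)) {
    utils::write.table(res$lagcorr$rois$positive,
                       file.path(out_dir, "roi_profile_positive.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$lagcorr$rois$negative,
                       file.path(out_dir, "roi_profile_negative.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(list(config = res$config,
                      best_similarity_lag = res$lagcorr$similarity$best_lag,
                      roi_ordering = if (!is.null(res$lagcorr$rois))
                        res$lagcorr$rois$ordering else NA),
                 file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
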
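# End-to-end pipeline: quality -> scores -> features -> models -> lead time
# -> agreement, with a reproducible JSON summary. All randomness flows from
# one master seed via fixed offsets, so identical config + seed reproduces an
# identical summary byte for byte.

#' Pipeline configuration
#'
#' @param cohort_dir directory of cohort CSVs to analyse; when `NULL` a
#'   synthetic cohort is simulated from `generator`.
#' @param generator a [generator_config()] used when `cohort_dir` is `NULL`
#'   (its seed is overridden by `seed`).
#' @param sqi_threshold signal-quality threshold, percent.
#' @param window_minutes feature window width.
#' @param first_hours only assessments in the first this-many hours feed
#'   model training (the deployment-relevant early window); `Inf` uses all.
#' @param model_iterations cross-validation repetitions for models A/B/C.
#' @param leadtime_iterations train/test segmentations for the lead-time
#'   analysis.
#' @param k_folds outer folds.
#' @param r2_min univariate screen threshold.
#' @param lambda_grid ridge penalty grid.
#' @param group_by_patient fold grouping (default TRUE).
#' @param target_fpr matched false-positive rate; `NULL` (default) matches
#'   the clinicians' observed documentation FPR.
#' @param grid_cadence_minutes cadence of the detection evaluation grid.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed master seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_dir = NULL, generator = generator_config(),
                            sqi_threshold = 75, window_minutes = 60,
                            first_hours = 12, model_iterations = 1000L,
                            leadtime_iterations = 200L, k_folds = 5L,
                            r2_min = 0.04, lambda_grid = 10^seq(-3, 3, 1),
                            group_by_patient = TRUE, target_fpr = NULL,
                            grid_cadence_minutes = 60L, out_dir = NULL,
                            seed = 1L) {
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("invalid configuration field 'cohort_dir': directory does not exist")
  check_number(sqi_threshold, "sqi_threshold", 0, 100)
  check_number(window_minutes, "window_minutes", lower = 1)
  if (!identical(first_hours, Inf)) check_number(first_hours, "first_hours", lower = 0)
  check_number(model_iterations, "model_iterations", lower = 1)
  check_number(leadtime_iterations, "leadtime_iterations", lower = 1)
  check_number(k_folds, "k_folds", lower = 2)
  check_prob(r2_min, "r2_min")
  if (!is.null(target_fpr)) check_prob(target_fpr, "target_fpr")
  check_number(grid_cadence_minutes, "grid_cadence_minutes", lower = 1)
  check_number(seed, "seed", 0, 2^31 - 10)
  structure(mget(names(formals())), class = "pipeline_config")
}

# clinician classification at each assessment: positive iff an
# advanced-sepsis doc exists at or before the assessment time
clinician_classification <- function(psofa, clin_docs) {
  adv <- clin_docs[clin_docs$diagnosis == "advanced_sepsis", , drop = FALSE]
  first_doc <- tapply(adv$time_min, adv$patient_id, min)
  t_doc <- unname(first_doc[psofa$patient_id])
  !is.na(t_doc) & t_doc <= psofa$time_min
}

#' Run the full analysis pipeline
#'
#' Executes quality filtering, pSOFA scoring, feature extraction, the three
#' candidate ridge models with iterated cross-validation, the clinician
#' comparison at the matched false-positive rate, the lead-time analysis for
#' the best wearable+clinical model, and the manual-versus-wearable agreement
#' summary. When `config$out_dir` is set, writes `capture_metrics.csv`,
#' `psofa.csv`, `features.csv`, `agreement.csv`, `leadtimes.csv` and
#' `summary.json` (stamped with the seed and a config hash); partial outputs
#' are removed if writing fails.
#'
#' @param config a [pipeline_config()].
#' @return the summary list (class `"sepsis_report"`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be created by pipeline_config()")
  seed <- as.integer(config$seed)
  cohort <- if (is.null(config$cohort_dir)) {
    gen <- config$generator
    gen$seed <- seed
    simulate_cohort(gen)
  } else read_cohort(config$cohort_dir)

  qf <- filter_low_quality(cohort$vitals, config$sqi_threshold)
  mpews <- mpews_table()
  ptab <- psofa_table()
  psofa <- score_psofa_cohort(cohort$labs, cohort$manual_obs, cohort$profiles,
                              table = ptab)
  usable <- psofa[!is.na(psofa$total), , drop = FALSE]
  if (nrow(usable) < 10L) stop("too few usable pSOFA assessments to model")

  clin_pred <- clinician_classification(usable, cohort$clin_docs)
  clin_metrics <- classification_metrics(clin_pred, usable$advanced)
  target_fpr <- config$target_fpr %||% clin_metrics$fpr

  anchors <- data.frame(patient_id = usable$patient_id,
                        time_min = usable$time_min,
                        outcome = as.numeric(usable$advanced))
  train_anchors <- anchors[anchors$time_min <= config$first_hours * 60, , drop = FALSE]
  feats <- build_feature_matrix(qf$stream, train_anchors, cohort$profiles,
                                cohort$manual_obs, mpews, config$window_minutes)
  feats <- feats[feats$usable, , drop = FALSE]
  sets <- model_feature_sets(feats, feats$outcome, config$r2_min)
  if (length(sets$B) == 0L) sets$B <- sets$A
  if (length(sets$C) == 0L) sets$C <- intersect(wearable_feature_names(), names(feats))

  cv <- list()
  for (mn in c("A", "B", "C")) {
    spec <- model_spec(mn, sets[[mn]], lambda_grid = config$lambda_grid,
                       r2_min = config$r2_min, k_folds = config$k_folds,
                       n_iterations = config$model_iterations,
                       seed = seed + match(mn, c("A", "B", "C")),
                       group_by_patient = config$group_by_patient,
                       target_fpr = target_fpr)
    cv[[mn]] <- cross_validate(feats, feats$outcome, spec, feats$patient_id)
  }

  comparison <- lapply(c(sensitivity = "sensitivity", accuracy = "accuracy",
                         f1 = "f1"), function(m)
    tryCatch(compare_metric_draws(cv$B$metrics[[m]], clin_metrics[[m]]),
             error = function(e) list(t_statistic = NA_real_,
                                      p_value = NA_real_)))

  # detection grid features for the lead-time analysis
  grid_anchors <- do.call(rbind, lapply(split(qf$stream, qf$stream$patient_id),
    function(v) data.frame(patient_id = v$patient_id[1L],
                           time_min = seq(0, max(v$time_min),
                                          by = config$grid_cadence_minutes))))
  grid_feats <- build_feature_matrix(qf$stream, grid_anchors, cohort$profiles,
                                     cohort$manual_obs, mpews,
                                     config$window_minutes)
  grid_feats <- grid_feats[grid_feats$usable, , drop = FALSE]
  lt_spec <- model_spec("B", sets$B, lambda_grid = config$lambda_grid,
                        k_folds = config$k_folds,
                        n_iterations = config$leadtime_iterations,
                        seed = seed + 7L,
                        group_by_patient = config$group_by_patient,
                        target_fpr = target_fpr)
  lt <- leadtime_analysis(feats, grid_feats, usable, cohort$clin_docs,
                          lt_spec, config$leadtime_iterations)

  agree <- agreement_analysis(cohort$manual_obs, qf$stream)

  summary <- list(
    seed = seed,
    config_hash = config_hash(unclass(config)[setdiff(names(config), "out_dir")]),
    n_patients = nrow(cohort$profiles),
    n_assessments = nrow(psofa),
    n_assessments_missing = sum(is.na(psofa$total)),
    advanced_prevalence = mean(usable$advanced),
    capture_median_fraction = median(qf$metrics$high_quality_fraction),
    models = lapply(cv, function(x) list(
      features = x$spec$feature_names, mean_auc = x$mean_auc, sd_auc = x$sd_auc,
      sensitivity = mean(x$metrics$sensitivity),
      specificity = mean(x$metrics$specificity),
      accuracy = mean(x$metrics$accuracy), f1 = mean(x$metrics$f1),
      fpr = mean(x$metrics$fpr))),
    clinician = clin_metrics,
    target_fpr = target_fpr,
    comparison = lapply(comparison, function(x)
      list(t_statistic = x$t_statistic, p_value = x$p_value)),
    leadtime = if (!is.null(lt$first_detection)) list(
      model_mean_h = lt$first_detection$model_mean_h,
      clinician_mean_h = lt$first_detection$clinician_mean_h,
      mann_whitney_u = lt$first_detection$mann_whitney_u,
      p_value = lt$first_detection$p_value),
    leadtime_transition = if (!is.null(lt$transition)) list(
      model_mean_h = lt$transition$model_mean_h,
      clinician_mean_h = lt$transition$clinician_mean_h,
      p_value = lt$transition$p_value),
    agreement = agree)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    tryCatch({
      wf <- function(obj, name, writer) {
        path <- file.path(config$out_dir, name)
        writer(obj, path)
        written <<- c(written, path)
      }
      csv <- function(obj, path) write.csv(obj, path, row.names = FALSE)
      wf(qf$metrics, "capture_metrics.csv", csv)
      wf(psofa, "psofa.csv", csv)
      wf(feats, "features.csv", csv)
      wf(agree, "agreement.csv", csv)
      if (!is.null(lt$first_detection))
        wf(lt$first_detection$per_patient, "leadtimes.csv", csv)
      wf(summary, "summary.json", function(obj, path)
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, dataframe = "rows"))
    }, error = function(e) {
      file.remove(written[file.exists(written)])
      stop(e)
    })
  }
  class(summary) <- c("sepsis_report", "list")
  invisible(summary)
}

#' @export
print.sepsis_report <- function(x, ...) {
  cat(sprintf("Sepsis pipeline report (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  %d patients; %d assessments (%d missing); advanced prevalence %.2f\n",
              x$n_patients, x$n_assessments, x$n_assessments_missing,
              x$advanced_prevalence))
  cat(sprintf("  median high-quality capture: %.4f\n", x$capture_median_fraction))
  for (mn in names(x$models))
    cat(sprintf("  model %s: AUC %.3f (SD %.3f), sens %.3f, F1 %.3f [%d features]\n",
                mn, x$models[[mn]]$mean_auc, x$models[[mn]]$sd_auc,
                x$models[[mn]]$sensitivity, x$models[[mn]]$f1,
                length(x$models[[mn]]$features)))
  cat(sprintf("  clinician: sens %.3f, spec %.3f, F1 %.3f (FPR %.3f)\n",
              x$clinician$sensitivity, x$clinician$specificity,
              x$clinician$f1, x$clinician$fpr))
  if (!is.null(x$leadtime))
    cat(sprintf("  lead time: model %.2f h vs clinician %.2f h (p = %.3g)\n",
                x$leadtime$model_mean_h, x$leadtime$clinician_mean_h,
                x$leadtime$p_value))
  invisible(x)
}
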
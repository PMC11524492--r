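# Detection lead-time analysis. A diagnosis timeline per patient aligns the
# twice-daily pSOFA criterion series, the model's scored hourly grid, and
# time-stamped clinician documentation. Leads follow the convention
#   lead = (time of first pSOFA total > 8) - (time of first detection),
# so positive leads mean the detector fired before the criterion event;
# negative leads are retained.

#' Build a diagnosis timeline for one patient
#'
#' @param psofa data frame of the patient's assessments (`time_min`, `total`;
#'   missing totals are dropped).
#' @param model_scores data frame with `time_min` and `score` on the model's
#'   evaluation grid.
#' @param threshold classification threshold; a model diagnosis is every grid
#'   evaluation with `score >= threshold`.
#' @param clin_docs data frame with `time_min`, `diagnosis` for the patient;
#'   only `"advanced_sepsis"` entries count as clinician advanced-sepsis
#'   diagnoses.
#' @return object of class `"diagnosis_timeline"`; `evaluable` is `FALSE`
#'   when no usable pSOFA assessment exists.
#' @export
build_timeline <- function(psofa, model_scores, threshold, clin_docs) {
  psofa <- psofa[!is.na(psofa$total), , drop = FALSE]
  psofa <- psofa[order(psofa$time_min), , drop = FALSE]
  model_scores <- model_scores[order(model_scores$time_min), , drop = FALSE]
  positive <- model_scores$score >= threshold
  adv_docs <- clin_docs[clin_docs$diagnosis == "advanced_sepsis", , drop = FALSE]
  structure(list(
    patient_id = psofa$patient_id[1L] %||% model_scores$patient_id[1L] %||% NA,
    psofa_events = psofa,
    model_events = data.frame(time_min = model_scores$time_min,
                              score = model_scores$score, positive = positive),
    clinician_events = adv_docs,
    threshold = threshold,
    n_model_diagnoses = sum(positive),
    n_clinician_diagnoses = nrow(adv_docs),
    evaluable = nrow(psofa) > 0L), class = "diagnosis_timeline")
}

#' @export
print.diagnosis_timeline <- function(x, ...) {
  cat(sprintf("Timeline %s: %d pSOFA events, %d model diagnoses, %d clinician diagnoses\n",
              x$patient_id, nrow(x$psofa_events), x$n_model_diagnoses,
              x$n_clinician_diagnoses))
  invisible(x)
}

#' First-detection lead times
#'
#' Lead (hours) of each detection arm relative to the first pSOFA total > 8:
#' `lead = (first criterion time - first detection time) / 60`. An arm with
#' no detection event yields a missing lead. Errors if the patient never
#' crosses the criterion (such patients contribute to neither arm).
#'
#' @param timeline a [build_timeline()] result.
#' @return named numeric vector `c(model = , clinician = )`, hours.
#' @export
first_detection_leads <- function(timeline) {
  ps <- timeline$psofa_events
  crit <- ps$time_min[ps$total > 8]
  if (length(crit) == 0L)
    stop("patient never crossed the pSOFA > 8 criterion; no lead defined")
  t_crit <- crit[1L]
  t_model <- timeline$model_events$time_min[timeline$model_events$positive][1L]
  t_clin <- timeline$clinician_events$time_min[1L]
  c(model = (t_crit - t_model) / 60, clinician = (t_crit - t_clin) / 60)
}

#' Transition lead times (progressive sepsis)
#'
#' For each assessment with total > 8 whose immediately preceding assessment
#' was not advanced (total <= 8), the lead is the transition time minus the
#' first detection inside the preceding inter-assessment interval
#' `(t_prev, t_transition]`, per arm. Transitions with no detection in the
#' interval yield missing leads.
#'
#' @param timeline a [build_timeline()] result (needs >= 2 pSOFA events).
#' @return data frame with one row per transition: `transition_min`,
#'   `model_lead_h`, `clinician_lead_h`.
#' @export
transition_leads <- function(timeline) {
  ps <- timeline$psofa_events
  if (nrow(ps) < 2L) stop("need at least 2 pSOFA events to find transitions")
  idx <- which(ps$total[-1L] > 8 & ps$total[-nrow(ps)] <= 8) + 1L
  me <- timeline$model_events
  ce <- timeline$clinician_events
  rows <- lapply(idx, function(i) {
    t0 <- ps$time_min[i - 1L]
    t1 <- ps$time_min[i]
    tm <- me$time_min[me$positive & me$time_min > t0 & me$time_min <= t1][1L]
    tc <- ce$time_min[ce$time_min > t0 & ce$time_min <= t1][1L]
    data.frame(transition_min = t1, model_lead_h = (t1 - tm) / 60,
               clinician_lead_h = (t1 - tc) / 60)
  })
  if (length(rows) == 0L)
    return(data.frame(transition_min = numeric(), model_lead_h = numeric(),
                      clinician_lead_h = numeric()))
  do.call(rbind, rows)
}

#' Aggregate lead times across iterations and compare the arms
#'
#' Averages the lead times per patient across iterations (yielding exactly
#' one lead per patient per arm) and compares the model and clinician
#' per-patient leads with a two-sided Mann-Whitney U test.
#'
#' @param leads data frame with columns `patient_id`, `model_lead_h`,
#'   `clinician_lead_h` (and optionally `iteration`); one row per patient per
#'   iteration.
#' @return object of class `"leadtime_result"`: per-patient means, group
#'   means/SDs, `mann_whitney_u`, `p_value`.
#' @export
aggregate_and_test <- function(leads) {
  per_patient <- do.call(rbind, lapply(split(leads, leads$patient_id), function(d)
    data.frame(patient_id = d$patient_id[1L],
               model_lead_h = if (all(is.na(d$model_lead_h))) NA_real_ else
                 mean(d$model_lead_h, na.rm = TRUE),
               clinician_lead_h = if (all(is.na(d$clinician_lead_h))) NA_real_ else
                 mean(d$clinician_lead_h, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  m <- per_patient$model_lead_h[!is.na(per_patient$model_lead_h)]
  cl <- per_patient$clinician_lead_h[!is.na(per_patient$clinician_lead_h)]
  if (length(m) == 0L || length(cl) == 0L)
    stop("an arm has zero evaluable patients")
  wt <- suppressWarnings(wilcox.test(m, cl, alternative = "two.sided"))
  structure(list(per_patient = per_patient,
                 model_mean_h = mean(m), model_sd_h = sd(m),
                 clinician_mean_h = mean(cl), clinician_sd_h = sd(cl),
                 n_model = length(m), n_clinician = length(cl),
                 mann_whitney_u = unname(wt$statistic), p_value = wt$p.value),
            class = "leadtime_result")
}

#' @export
print.leadtime_result <- function(x, ...) {
  cat(sprintf("Lead times (h): model %.2f (SD %.2f, n=%d) vs clinician %.2f (SD %.2f, n=%d)\n",
              x$model_mean_h, x$model_sd_h, x$n_model,
              x$clinician_mean_h, x$clinician_sd_h, x$n_clinician))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.4g\n", x$mann_whitney_u, x$p_value))
  invisible(x)
}

#' Iterated lead-time analysis with a cross-validated detector
#'
#' Repeats the train/test segmentation of the detection model: each
#' iteration partitions patients into folds, trains the ridge model on the
#' assessment-anchored records of the training patients, matches the
#' threshold to `spec$target_fpr` on training scores, then scores the test
#' patients' evaluation-grid features and extracts first-detection and
#' transition leads from their timelines. Patients whose pSOFA never exceeds
#' 8 are excluded. Results are aggregated with [aggregate_and_test()].
#'
#' @param assess_features assessment-anchored feature rows (training data);
#'   must carry `patient_id` and `outcome`.
#' @param grid_features evaluation-grid feature rows (`patient_id`,
#'   `anchor_min`, same feature columns).
#' @param psofa assessments data frame (`patient_id`, `time_min`, `total`).
#' @param clin_docs clinician documentation data frame.
#' @param spec a [model_spec()].
#' @param n_iterations number of train/test segmentations.
#' @return list with elements `first_detection` and `transition` (each a
#'   `"leadtime_result"` or `NULL` if no events), and the raw per-iteration
#'   `leads` data frame.
#' @export
leadtime_analysis <- function(assess_features, grid_features, psofa, clin_docs,
                              spec, n_iterations = 200L) {
  feats <- spec$feature_names
  ok <- complete.cases(as.data.frame(assess_features)[, feats, drop = FALSE]) &
    !is.na(assess_features$outcome)
  af <- assess_features[ok, , drop = FALSE]
  X <- as.matrix(as.data.frame(af)[, feats, drop = FALSE])
  y <- as.numeric(af$outcome)
  pids <- unique(af$patient_id)
  if (length(pids) < spec$k_folds) stop("fewer patients than folds")
  gf_ok <- complete.cases(as.data.frame(grid_features)[, feats, drop = FALSE])
  gf <- grid_features[gf_ok, , drop = FALSE]
  gf_split <- split(gf, gf$patient_id)
  ps_split <- split(psofa[!is.na(psofa$total), , drop = FALSE], psofa$patient_id[!is.na(psofa$total)])
  doc_split <- split(clin_docs, clin_docs$patient_id)
  empty_docs <- clin_docs[0, , drop = FALSE]
  # only patients who ever cross the criterion contribute leads
  eval_pids <- names(ps_split)[vapply(ps_split, function(p) any(p$total > 8), logical(1))]
  set.seed(spec$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  first_rows <- list()
  trans_rows <- list()
  for (it in seq_len(n_iterations)) {
    set.seed(iter_seeds[it])
    fold_of <- sample(rep_len(seq_len(spec$k_folds), length(pids)))
    names(fold_of) <- pids
    fold <- unname(fold_of[af$patient_id])
    for (f in seq_len(spec$k_folds)) {
      tr <- fold != f
      if (sum(tr) < 2L || !any(!tr)) next
      lam <- select_lambda(X[tr, , drop = FALSE], y[tr], spec$lambda_grid,
                           spec$inner_folds)
      fit <- fit_ridge(X[tr, , drop = FALSE], y[tr], lam)
      thr <- threshold_at_fpr(predict(fit, X[tr, , drop = FALSE]) - fit$intercept,
                              y[tr], spec$target_fpr)
      test_pids <- intersect(pids[fold_of == f], eval_pids)
      for (pid in test_pids) {
        g <- gf_split[[pid]]
        if (is.null(g) || nrow(g) == 0L) next
        sc <- data.frame(patient_id = pid, time_min = g$anchor_min,
                         score = predict(fit, as.data.frame(g)[, feats, drop = FALSE]) -
                           fit$intercept)
        tl <- build_timeline(ps_split[[pid]], sc, thr,
                             doc_split[[pid]] %||% empty_docs)
        leads <- first_detection_leads(tl)
        first_rows[[length(first_rows) + 1L]] <- data.frame(
          iteration = it, patient_id = pid,
          model_lead_h = leads[["model"]], clinician_lead_h = leads[["clinician"]],
          stringsAsFactors = FALSE)
        if (nrow(tl$psofa_events) >= 2L) {
          tr_leads <- transition_leads(tl)
          if (nrow(tr_leads))
            trans_rows[[length(trans_rows) + 1L]] <- data.frame(
              iteration = it, patient_id = pid,
              model_lead_h = mean(tr_leads$model_lead_h, na.rm = TRUE),
              clinician_lead_h = mean(tr_leads$clinician_lead_h, na.rm = TRUE),
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  first_df <- if (length(first_rows)) do.call(rbind, first_rows)
  trans_df <- if (length(trans_rows)) do.call(rbind, trans_rows)
  list(
    first_detection = if (!is.null(first_df)) tryCatch(
      aggregate_and_test(first_df), error = function(e) NULL),
    transition = if (!is.null(trans_df)) tryCatch(
      aggregate_and_test(trans_df), error = function(e) NULL),
    leads = first_df)
}
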
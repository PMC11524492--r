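# Synthetic monitored-ICU cohort generator. A latent sepsis-severity index in
# [0, 1] evolves per patient as a bounded random walk on a 5-minute grid
# (reflecting at 0, optionally absorbing at 1) and drives every observable:
# per-minute wearable vitals, hourly manual observations, twice-daily labs,
# and lagged clinician documentation. All timestamps are integer minutes
# since enrollment.

#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of the generator: cohort size, monitored
#' duration, the latent severity process, per-unit-severity effect sizes on
#' vitals/labs/MAP/GCS, measurement noise and device bias, signal-quality
#' dropout bursts, clinician documentation lag, and lab-driven outcome
#' missingness. Defaults emulate the monitored pediatric ICU setting the
#' package targets: 100 children monitored for ~52.5 h on average, ~25%
#' deteriorating to advanced sepsis, ~9% of lab panels missing, and dropout
#' tuned to under 1% low-quality minutes.
#'
#' @param n_patients number of patients to simulate.
#' @param seed RNG seed; identical config + seed reproduces the cohort
#'   byte-for-byte.
#' @param mean_monitor_hours,sd_monitor_hours,min_monitor_hours monitored
#'   duration distribution (truncated normal), hours.
#' @param severity_start_mean,severity_start_sd initial latent severity
#'   (normal, clipped to \[0, 1\]).
#' @param severity_drift_per_hour baseline drift of the severity walk.
#' @param severity_volatility standard deviation of the severity increment per
#'   square-root hour.
#' @param deterioration_prob probability a patient enters a deterioration
#'   episode (an added positive drift beginning at a random onset in the first
#'   half of monitoring).
#' @param deterioration_drift_per_hour added drift during deterioration.
#' @param severity_cutoff latent severity at or above which the ground-truth
#'   advanced flag is set.
#' @param absorb_at_one if TRUE the walk is absorbed at severity 1.
#' @param severity_grid_minutes grid spacing of the latent walk, minutes.
#' @param effect_sizes named list: shift of each observable at severity 1
#'   versus 0 (hr, rr, hrv, skin_t, core_t, activity, map, gcs, spo2, fio2,
#'   platelets, bilirubin, creatinine, wbc).
#' @param stream_noise_sd named list of per-minute wearable noise SDs.
#' @param between_patient_sd named list of between-patient baseline SDs.
#' @param manual_noise_sd named list of manual-measurement noise SDs
#'   (hr, rr, temp, map, spo2).
#' @param manual_bias named list: systematic offset of the manual value
#'   relative to the wearable stream (hr, rr, temp).
#' @param sqi_burst_rate_per_hour,sqi_burst_mean_minutes Poisson rate and mean
#'   (geometric) duration of low-quality SQI bursts.
#' @param doc_lag_meanlog,doc_lag_sdlog lognormal parameters (hours) of the
#'   clinician documentation lag after true advanced-sepsis onset; defaults
#'   give a 2 h median lag.
#' @param doc_false_positive_prob probability that a patient who never truly
#'   develops advanced sepsis nonetheless receives an advanced-sepsis
#'   documentation entry at a uniform random time (clinician
#'   over-diagnosis, which gives the documentation a realistic non-zero
#'   false-positive rate against the pSOFA criterion).
#' @param lab_missing_prob probability that a lab panel is missing, which
#'   renders the matched pSOFA assessment missing downstream.
#' @param lab_noise_sd named list of lab measurement noise SDs.
#' @param baseline_table optional replacement for [age_baselines()].
#' @return a validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 100L,
                             seed = 1L,
                             mean_monitor_hours = 52.5,
                             sd_monitor_hours = 13,
                             min_monitor_hours = 18,
                             severity_start_mean = 0.35,
                             severity_start_sd = 0.15,
                             severity_drift_per_hour = 0,
                             severity_volatility = 0.015,
                             deterioration_prob = 0.25,
                             deterioration_drift_per_hour = 0.10,
                             severity_cutoff = 0.6,
                             absorb_at_one = TRUE,
                             severity_grid_minutes = 5L,
                             effect_sizes = list(
                               hr = 40, rr = 20, hrv = -15, skin_t = 1.2,
                               core_t = 1.5, activity = -0.08, map = -20,
                               gcs = -7, spo2 = -8, fio2 = 0.35,
                               platelets = -230, bilirubin = 3,
                               creatinine = 0.8, wbc = 12),
                             stream_noise_sd = list(
                               hr = 5, rr = 3, hrv = 5, skin_t = 0.25,
                               core_t = 0.2, activity = 0.05),
                             between_patient_sd = list(
                               hr = 8, rr = 3, hrv = 6, skin_t = 0.3,
                               core_t = 0.25, activity = 0.04),
                             manual_noise_sd = list(
                               hr = 4, rr = 2, temp = 0.4, map = 4, spo2 = 1.5),
                             manual_bias = list(hr = -0.04, rr = -0.29, temp = 0),
                             sqi_burst_rate_per_hour = 0.1,
                             sqi_burst_mean_minutes = 5,
                             doc_lag_meanlog = log(2),
                             doc_lag_sdlog = 0.5,
                             doc_false_positive_prob = 0.25,
                             lab_missing_prob = 0.09,
                             lab_noise_sd = list(
                               platelets = 30, bilirubin = 0.3,
                               creatinine = 0.08, wbc = 2),
                             baseline_table = NULL) {
  check_number(n_patients, "n_patients", lower = 1)
  check_number(seed, "seed", lower = 0, upper = 2^31 - 1)
  check_number(mean_monitor_hours, "mean_monitor_hours", lower = 1)
  check_number(sd_monitor_hours, "sd_monitor_hours", lower = 0)
  check_number(min_monitor_hours, "min_monitor_hours", lower = 1)
  check_number(severity_start_mean, "severity_start_mean", 0, 1)
  check_number(severity_start_sd, "severity_start_sd", lower = 0)
  check_number(severity_drift_per_hour, "severity_drift_per_hour")
  check_number(severity_volatility, "severity_volatility", lower = 0)
  check_prob(deterioration_prob, "deterioration_prob")
  check_number(deterioration_drift_per_hour, "deterioration_drift_per_hour", lower = 0)
  check_prob(severity_cutoff, "severity_cutoff")
  check_flag(absorb_at_one, "absorb_at_one")
  check_number(severity_grid_minutes, "severity_grid_minutes", lower = 1)
  vital_keys <- c("hr", "rr", "hrv", "skin_t", "core_t", "activity")
  if (!is.list(effect_sizes) ||
      !all(c(vital_keys, "map", "gcs", "spo2", "fio2", "platelets",
             "bilirubin", "creatinine", "wbc") %in% names(effect_sizes)))
    stop("invalid configuration field 'effect_sizes': incomplete named list",
         call. = FALSE)
  for (k in names(effect_sizes)) check_number(effect_sizes[[k]], paste0("effect_sizes$", k))
  check_sd_list(stream_noise_sd, "stream_noise_sd", vital_keys)
  check_sd_list(between_patient_sd, "between_patient_sd", vital_keys)
  check_sd_list(manual_noise_sd, "manual_noise_sd", c("hr", "rr", "temp", "map", "spo2"))
  for (k in c("hr", "rr", "temp")) check_number(manual_bias[[k]], paste0("manual_bias$", k))
  check_number(sqi_burst_rate_per_hour, "sqi_burst_rate_per_hour", lower = 0)
  check_number(sqi_burst_mean_minutes, "sqi_burst_mean_minutes", lower = 1)
  check_number(doc_lag_meanlog, "doc_lag_meanlog")
  check_number(doc_lag_sdlog, "doc_lag_sdlog", lower = 0)
  check_prob(doc_false_positive_prob, "doc_false_positive_prob")
  check_prob(lab_missing_prob, "lab_missing_prob")
  check_sd_list(lab_noise_sd, "lab_noise_sd", c("platelets", "bilirubin", "creatinine", "wbc"))
  cfg <- mget(names(formals()))
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  cfg$severity_grid_minutes <- as.integer(severity_grid_minutes)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  patients: %d, mean monitored %.1f h, seed %d\n",
              x$n_patients, x$mean_monitor_hours, x$seed))
  cat(sprintf("  severity: start %.2f (SD %.2f), volatility %.3f/sqrt(h), cutoff %.2f\n",
              x$severity_start_mean, x$severity_start_sd,
              x$severity_volatility, x$severity_cutoff))
  cat(sprintf("  deterioration: p = %.2f, drift +%.2f/h\n",
              x$deterioration_prob, x$deterioration_drift_per_hour))
  cat(sprintf("  lab missingness: %.2f; doc lag median %.1f h\n",
              x$lab_missing_prob, exp(x$doc_lag_meanlog)))
  invisible(x)
}

# demographics / anthropometry; extra column monitor_hours drives durations
simulate_profiles <- function(config) {
  n <- config$n_patients
  age <- pmax(2, pmin(215, round(rlnorm(n, log(9), 1))))
  female <- runif(n) < 0.41
  weight <- ifelse(age < 12, 4 + 0.45 * age, 2 * (age / 12) + 8) * exp(rnorm(n, 0, 0.08))
  height <- pmax(45, 46 + 6.5 * sqrt(age)) * exp(rnorm(n, 0, 0.03))
  maln <- runif(n) < 0.46
  muac <- pmax(80, ifelse(maln, rnorm(n, 105, 6), rnorm(n, 130, 8)))
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_months = as.numeric(age),
    sex = ifelse(female, "female", "male"),
    weight_kg = round(weight, 2),
    height_cm = round(height, 1),
    muac_mm = round(muac, 1),
    malnutrition = maln,
    diarrhea = runif(n) < 0.98,
    peripheral_edema = runif(n) < 0.10,
    jaundice = runif(n) < 0.05,
    delayed_skin_pinch = runif(n) < 0.30,
    sunken_eyes = runif(n) < 0.40,
    pupillary_reaction = ifelse(runif(n) < 0.05, "abnormal", "normal"),
    general_appearance = sample(c("well", "ill", "critical"), n,
                                replace = TRUE, prob = c(0.15, 0.60, 0.25)),
    monitor_hours = pmax(config$min_monitor_hours,
                         rnorm(n, config$mean_monitor_hours, config$sd_monitor_hours)),
    stringsAsFactors = FALSE)
}

#' Simulate a latent severity path for one patient
#'
#' Bounded random walk on a uniform grid: reflecting at 0, optionally
#' absorbing at 1, with a baseline drift plus an optional deterioration
#' episode (positive drift from a random onset in the first half of
#' monitoring, entered with probability `deterioration_prob`). The
#' ground-truth advanced flag is `severity >= severity_cutoff`.
#'
#' Randomness is taken from the current RNG stream; [simulate_cohort()] seeds
#' it once from the config.
#'
#' @param profile one-row data frame with at least `patient_id` and
#'   `monitor_hours`.
#' @param config a [generator_config()].
#' @return data frame with columns `patient_id`, `time_min`, `severity`,
#'   `advanced_truth`.
#' @export
simulate_severity_path <- function(profile, config) {
  profile <- as_one_row(profile)
  dur_h <- profile$monitor_hours
  if (!is_number(dur_h) || dur_h <= 0)
    stop("non-positive monitored duration for patient ", profile$patient_id)
  dt_h <- config$severity_grid_minutes / 60
  n <- floor(dur_h * 60 / config$severity_grid_minutes) + 1L
  times <- (seq_len(n) - 1L) * config$severity_grid_minutes
  start <- min(1, max(0, rnorm(1, config$severity_start_mean, config$severity_start_sd)))
  deteriorates <- runif(1) < config$deterioration_prob
  onset_h <- runif(1, 0, 0.5 * dur_h)
  drift <- rep(config$severity_drift_per_hour, n - 1L)
  if (deteriorates)
    drift <- drift + ifelse(times[-n] / 60 >= onset_h,
                            config$deterioration_drift_per_hour, 0)
  inc <- rnorm(n - 1L, drift * dt_h, config$severity_volatility * sqrt(dt_h))
  s <- numeric(n)
  s[1L] <- start
  for (i in seq_len(n - 1L)) {
    v <- s[i] + inc[i]
    if (v < 0) v <- -v            # reflect at 0
    if (v > 1) v <- 1
    if (config$absorb_at_one && s[i] >= 1) v <- 1
    s[i + 1L] <- v
  }
  data.frame(patient_id = profile$patient_id, time_min = as.integer(times),
             severity = s, advanced_truth = s >= config$severity_cutoff,
             stringsAsFactors = FALSE)
}

#' Render observable data from a latent severity path
#'
#' Produces, for one patient, the per-minute wearable stream (vitals + SQI
#' with low-quality dropout bursts), hourly manual observations (stream value
#' plus configured bias and measurement noise for HR/RR/T; severity-driven
#' MAP, SpO2, FiO2, GCS, capillary refill, urine output), twice-daily lab
#' panels with configurable missingness, and clinician documentation events
#' whose advanced-sepsis entry lags true onset by a lognormal delay.
#'
#' @param path output of [simulate_severity_path()].
#' @param profile one-row profile data frame.
#' @param config a [generator_config()].
#' @return list with elements `vitals`, `manual_obs`, `labs`, `clin_docs`.
#' @export
render_observables <- function(path, profile, config) {
  profile <- as_one_row(profile)
  baselines <- config$baseline_table %||% age_baselines()
  base <- baseline_band(baselines, profile$age_months)
  pid <- profile$patient_id
  dur_min <- max(path$time_min)
  minutes <- 0:dur_min
  n <- length(minutes)
  sev <- approx(path$time_min, path$severity, xout = minutes, rule = 2)$y
  eff <- config$effect_sizes
  nsd <- config$stream_noise_sd
  bsd <- config$between_patient_sd

  signal <- function(key, base_val, lo = -Inf) {
    b <- base_val + rnorm(1, 0, bsd[[key]])
    pmax(lo, b + eff[[key]] * sev + rnorm(n, 0, nsd[[key]]))
  }
  hr <- signal("hr", base$hr, 20)
  rr <- signal("rr", base$rr, 4)
  hrv <- signal("hrv", base$hrv, 1)
  skin <- signal("skin_t", base$skin_t, 30)
  core <- signal("core_t", base$core_t, 30)
  act <- signal("activity", base$activity, 0)

  sqi <- pmin(100, rnorm(n, 97, 1.5))
  n_burst <- rpois(1, config$sqi_burst_rate_per_hour * dur_min / 60)
  if (n_burst > 0) {
    for (j in seq_len(n_burst)) {
      s0 <- sample.int(n, 1L)
      len <- 1L + rgeom(1, 1 / config$sqi_burst_mean_minutes)
      idx <- s0:min(n, s0 + len - 1L)
      sqi[idx] <- runif(length(idx), 20, 74.5)
    }
  }
  vitals <- data.frame(
    patient_id = pid, time_min = minutes,
    hr_bpm = round(hr, 1), rr_brpm = round(rr, 1), hrv_ms = round(hrv, 1),
    skin_t_c = round(skin, 2), core_t_c = round(core, 2),
    activity = round(act, 3), sqi_pct = round(sqi, 1),
    stringsAsFactors = FALSE)

  obs_min <- seq(0L, dur_min, by = 60L)
  i <- obs_min + 1L
  k <- length(i)
  msd <- config$manual_noise_sd
  mb <- config$manual_bias
  sev_o <- sev[i]
  gcs <- as.integer(round(pmin(15, pmax(3, 15 + eff$gcs * sev_o + rnorm(k, 0, 0.5)))))
  manual_obs <- data.frame(
    patient_id = pid, time_min = obs_min,
    hr_bpm = round(vitals$hr_bpm[i] + mb$hr + rnorm(k, 0, msd$hr), 1),
    rr_brpm = round(vitals$rr_brpm[i] + mb$rr + rnorm(k, 0, msd$rr), 1),
    temp_c = round(vitals$core_t_c[i] + mb$temp + rnorm(k, 0, msd$temp), 2),
    temp_route = if (profile$age_months < 60) "rectal" else "oral",
    map_mmhg = round(base$map + eff$map * sev_o + rnorm(k, 0, msd$map), 1),
    spo2_pct = round(pmin(100, pmax(55, base$spo2 + eff$spo2 * sev_o +
                                      rnorm(k, 0, msd$spo2))), 1),
    fio2_fraction = round(pmin(1, pmax(0.21, 0.21 + eff$fio2 * sev_o)), 2),
    gcs = gcs,
    avpu = c("U", "P", "V", "A")[findInterval(gcs, c(3, 4, 9, 13))],
    cap_refill_s = round(pmax(1, 2 + 3 * sev_o + rnorm(k, 0, 0.3)), 1),
    urine_output_ml_kg_h = round(pmax(0, 2 - 1.8 * sev_o + rnorm(k, 0, 0.2)), 2),
    stringsAsFactors = FALSE)

  lab_min <- seq(0L, dur_min, by = 720L)
  j <- lab_min + 1L
  m <- length(j)
  lsd <- config$lab_noise_sd
  labs <- data.frame(
    patient_id = pid, time_min = lab_min,
    platelets_10e3_ul = round(pmax(5, base$platelets + eff$platelets * sev[j] +
                                     rnorm(m, 0, lsd$platelets)), 0),
    bilirubin_mg_dl = round(pmax(0.1, base$bilirubin + eff$bilirubin * sev[j] +
                                   rnorm(m, 0, lsd$bilirubin)), 2),
    creatinine_mg_dl = round(pmax(0.05, base$creatinine + eff$creatinine * sev[j] +
                                    rnorm(m, 0, lsd$creatinine)), 2),
    wbc_10e3_ul = round(pmax(1, base$wbc + eff$wbc * sev[j] + rnorm(m, 0, lsd$wbc)), 1),
    missing = runif(m) < config$lab_missing_prob,
    stringsAsFactors = FALSE)
  for (col in c("platelets_10e3_ul", "bilirubin_mg_dl", "creatinine_mg_dl", "wbc_10e3_ul"))
    labs[[col]][labs$missing] <- NA_real_

  docs <- list()
  sep_lag_min <- round(rlnorm(1, config$doc_lag_meanlog, config$doc_lag_sdlog) * 60)
  t_sep <- 60L + as.integer(sep_lag_min)
  if (t_sep <= dur_min)
    docs[[length(docs) + 1L]] <- data.frame(
      patient_id = pid, time_min = t_sep, diagnosis = "sepsis",
      stringsAsFactors = FALSE)
  adv_idx <- which(path$advanced_truth)
  if (length(adv_idx)) {
    lag_min <- round(rlnorm(1, config$doc_lag_meanlog, config$doc_lag_sdlog) * 60)
    t_adv <- path$time_min[adv_idx[1L]] + as.integer(lag_min)
    if (t_adv <= dur_min)
      docs[[length(docs) + 1L]] <- data.frame(
        patient_id = pid, time_min = t_adv, diagnosis = "advanced_sepsis",
        stringsAsFactors = FALSE)
  } else if (runif(1) < config$doc_false_positive_prob) {
    # clinician over-diagnosis: spurious advanced-sepsis entry
    docs[[length(docs) + 1L]] <- data.frame(
      patient_id = pid, time_min = as.integer(round(runif(1, 0, dur_min))),
      diagnosis = "advanced_sepsis", stringsAsFactors = FALSE)
  }
  clin_docs <- if (length(docs)) do.call(rbind, docs) else
    data.frame(patient_id = character(), time_min = integer(),
               diagnosis = character(), stringsAsFactors = FALSE)

  list(vitals = vitals, manual_obs = manual_obs, labs = labs, clin_docs = clin_docs)
}

#' Simulate a complete monitored cohort
#'
#' Seeds the RNG once from the config and generates profiles, latent severity
#' paths, wearable streams, manual observations, lab panels and clinician
#' documentation for every patient. Identical config + seed yields an
#' identical cohort.
#'
#' @param config a [generator_config()].
#' @return an object of class `"sepsis_cohort"`: a list of data frames
#'   `profiles`, `severity`, `vitals`, `manual_obs`, `labs`, `clin_docs`,
#'   plus the `config` used.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must be created by generator_config()")
  set.seed(config$seed)
  profiles <- simulate_profiles(config)
  sev <- vit <- obs <- lab <- doc <- vector("list", nrow(profiles))
  for (p in seq_len(nrow(profiles))) {
    prof <- profiles[p, , drop = FALSE]
    path <- simulate_severity_path(prof, config)
    rend <- render_observables(path, prof, config)
    sev[[p]] <- path
    vit[[p]] <- rend$vitals
    obs[[p]] <- rend$manual_obs
    lab[[p]] <- rend$labs
    doc[[p]] <- rend$clin_docs
  }
  structure(list(
    profiles = profiles,
    severity = do.call(rbind, sev),
    vitals = do.call(rbind, vit),
    manual_obs = do.call(rbind, obs),
    labs = do.call(rbind, lab),
    clin_docs = do.call(rbind, doc),
    config = config), class = "sepsis_cohort")
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat(sprintf("Synthetic sepsis cohort: %d patients, %d stream minutes, %d lab panels\n",
              nrow(x$profiles), nrow(x$vitals), nrow(x$labs)))
  adv <- tapply(x$severity$advanced_truth, x$severity$patient_id, any)
  cat(sprintf("  ever-advanced (latent truth): %d/%d patients; %d clinician docs\n",
              sum(adv), length(adv), nrow(x$clin_docs)))
  invisible(x)
}
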
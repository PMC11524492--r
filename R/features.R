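# Windowed wearable feature engineering. Each feature vector is anchored at a
# time (a pSOFA assessment, or a point on an hourly grid for detection
# timelines) and summarises the quality-filtered stream over a centred,
# half-open window [anchor - w/2, anchor + w/2): mean, sample SD, worst
# (most extreme) value, and the fraction of minutes in the MPEWS red zone.

stream_vitals <- c(hr = "hr_bpm", rr = "rr_brpm", hrv = "hrv_ms",
                   skin_t = "skin_t_c", core_t = "core_t_c",
                   activity = "activity")
zoned_vitals <- c("hr", "rr", "skin_t", "core_t")

#' Most extreme value of a vital-sign series
#'
#' "Most extreme" is judged relative to the age band's normal range: the value
#' maximising |value - midpoint| / half-width, so bradycardia can out-rank
#' tachycardia when it is further from normal in age-relative terms. A raw
#' mode (absolute deviation from the midpoint, unnormalised) is available.
#' Vitals without age norms (activity, HRV) use the deviation from `center`,
#' the patient's own stream median. Ties return the earliest element.
#'
#' @param series numeric vector, ordered by time.
#' @param vital_kind vital kind with normal bounds in `norm_table`, or `NULL`
#'   to use `center`.
#' @param age_months patient age (required with `vital_kind`).
#' @param norm_table an [mpews_table()] carrying normal ranges.
#' @param mode `"normalized"` (default) or `"raw"`.
#' @param center reference value for vitals without age norms; defaults to
#'   `median(series)`.
#' @return the most extreme observed value (always an element of `series`).
#' @export
worst_value <- function(series, vital_kind = NULL, age_months = NULL,
                        norm_table = mpews_table(),
                        mode = c("normalized", "raw"), center = NULL) {
  if (length(series) == 0L) stop("empty series: no worst value")
  mode <- match.arg(mode)
  if (!is.null(vital_kind)) {
    band <- threshold_band(norm_table, vital_kind, age_months)
    if (is.na(band$normal_low) || is.na(band$normal_high))
      stop("no normal range recorded for vital kind '", vital_kind, "'")
    mid <- (band$normal_low + band$normal_high) / 2
    hw <- (band$normal_high - band$normal_low) / 2
    ext <- if (mode == "normalized") abs(series - mid) / hw else abs(series - mid)
  } else {
    center <- center %||% median(series)
    ext <- abs(series - center)
  }
  series[which.max(ext)]
}

#' Fraction of time in the MPEWS red zone
#'
#' @param series numeric vector of kept minutes.
#' @inheritParams mpews_zone
#' @return fraction in \[0, 1\].
#' @export
pct_red <- function(series, vital_kind, age_months, table = mpews_table()) {
  if (length(series) == 0L) stop("empty series: red-zone fraction undefined")
  mean(mpews_zone(vital_kind, series, age_months, table) == "red")
}

# per-patient extraction context, precomputed once
feature_context <- function(vit, profile, mpews) {
  ctx <- list(vit = vit[order(vit$time_min), , drop = FALSE],
              age = profile$age_months, bands = list(), centers = list())
  for (v in zoned_vitals) {
    band <- threshold_band(mpews, v, profile$age_months)
    ctx$bands[[v]] <- list(mid = (band$normal_low + band$normal_high) / 2,
                           hw = (band$normal_high - band$normal_low) / 2,
                           red_low = band$red_low, red_high = band$red_high)
  }
  for (v in c("hrv", "activity"))
    ctx$centers[[v]] <- median(ctx$vit[[stream_vitals[[v]]]])
  ctx
}

window_features <- function(ctx, anchor, window_minutes) {
  half <- window_minutes / 2
  t <- ctx$vit$time_min
  lo <- findInterval(anchor - half - 1e-9, t) + 1L
  hi <- findInterval(anchor + half - 1e-9, t)
  out <- list(n_minutes = max(0L, hi - lo + 1L))
  out$usable <- out$n_minutes >= 1L
  for (v in names(stream_vitals)) {
    x <- if (out$usable) ctx$vit[[stream_vitals[[v]]]][lo:hi] else numeric(0)
    if (length(x) == 0L) {
      out[[paste0(v, "_mean")]] <- out[[paste0(v, "_sd")]] <-
        out[[paste0(v, "_worst")]] <- NA_real_
      if (v %in% zoned_vitals) out[[paste0(v, "_pct_red")]] <- NA_real_
      next
    }
    out[[paste0(v, "_mean")]] <- mean(x)
    out[[paste0(v, "_sd")]] <- if (length(x) > 1L) sd(x) else 0
    if (v %in% zoned_vitals) {
      b <- ctx$bands[[v]]
      out[[paste0(v, "_worst")]] <- x[which.max(abs(x - b$mid) / b$hw)]
      out[[paste0(v, "_pct_red")]] <- mean(x <= b$red_low | x >= b$red_high)
    } else {
      out[[paste0(v, "_worst")]] <- x[which.max(abs(x - ctx$centers[[v]]))]
    }
  }
  out
}

manual_feature_row <- function(profile, obs_row) {
  list(age_months = profile$age_months,
       sex_male = as.numeric(profile$sex == "male"),
       weight_kg = profile$weight_kg,
       height_cm = profile$height_cm,
       muac_mm = profile$muac_mm,
       malnutrition = as.numeric(profile$malnutrition),
       diarrhea = as.numeric(profile$diarrhea),
       peripheral_edema = as.numeric(profile$peripheral_edema),
       jaundice = as.numeric(profile$jaundice),
       delayed_skin_pinch = as.numeric(profile$delayed_skin_pinch),
       sunken_eyes = as.numeric(profile$sunken_eyes),
       pupillary_abnormal = as.numeric(profile$pupillary_reaction == "abnormal"),
       general_appearance_ord = match(profile$general_appearance,
                                      c("well", "ill", "critical")) - 1,
       cap_refill_s = obs_row$cap_refill_s %||% NA_real_,
       map_mmhg = obs_row$map_mmhg %||% NA_real_,
       spo2_fio2 = if (!is.null(obs_row$spo2_pct))
         obs_row$spo2_pct / obs_row$fio2_fraction else NA_real_)
}

#' Extract one feature vector
#'
#' Summarises the quality-filtered stream of a single patient over the
#' half-open window centred on `anchor_time`, and copies the candidate manual
#' features from the profile and the nearest manual observation.
#'
#' @param stream quality-filtered vitals data frame for one patient.
#' @param anchor_time anchor, minutes since enrollment.
#' @param profile one-row patient profile.
#' @param manual_obs optional manual observations for the patient; the row
#'   nearest the anchor contributes MAP, SpO2:FiO2 and capillary refill.
#' @param mpews an [mpews_table()].
#' @param window_minutes window width (default 60: 30 min either side).
#' @return one-row data frame; `usable` is `FALSE` when the window holds no
#'   kept minutes (such rows are excluded downstream).
#' @export
extract_features <- function(stream, anchor_time, profile, manual_obs = NULL,
                             mpews = mpews_table(), window_minutes = 60) {
  profile <- as_one_row(profile)
  ctx <- feature_context(stream, profile, mpews)
  row <- window_features(ctx, anchor_time, window_minutes)
  obs_row <- list()
  if (!is.null(manual_obs) && nrow(manual_obs) > 0L)
    obs_row <- as.list(manual_obs[which.min(abs(manual_obs$time_min - anchor_time)), ])
  out <- c(list(patient_id = profile$patient_id, anchor_min = anchor_time),
           row, manual_feature_row(profile, obs_row))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Build the feature matrix for a set of anchors
#'
#' Applies [extract_features()] efficiently over a table of anchors (one row
#' per patient and anchor time), carrying through an optional `outcome`
#' column.
#'
#' @param vitals quality-filtered vitals for the cohort.
#' @param anchors data frame with `patient_id`, `time_min`, and optionally
#'   `outcome`.
#' @param profiles,manual_obs cohort tables.
#' @param mpews an [mpews_table()].
#' @param window_minutes window width in minutes.
#' @return data frame, one row per anchor, with wearable and manual features,
#'   `n_minutes`, `usable`, and `outcome` (if supplied).
#' @export
build_feature_matrix <- function(vitals, anchors, profiles, manual_obs = NULL,
                                 mpews = mpews_table(), window_minutes = 60) {
  vit_split <- split(vitals, vitals$patient_id)
  obs_split <- if (!is.null(manual_obs)) split(manual_obs, manual_obs$patient_id)
  rows <- vector("list", nrow(anchors))
  for (pid in unique(anchors$patient_id)) {
    prof <- as_one_row(profiles[profiles$patient_id == pid, , drop = FALSE])
    vit <- vit_split[[pid]]
    if (is.null(vit) || nrow(vit) == 0L) next
    ctx <- feature_context(vit, prof, mpews)
    obs <- if (!is.null(obs_split)) obs_split[[pid]]
    mf_static <- manual_feature_row(prof, list())
    idx <- which(anchors$patient_id == pid)
    for (i in idx) {
      a <- anchors$time_min[i]
      row <- window_features(ctx, a, window_minutes)
      mf <- mf_static
      if (!is.null(obs) && nrow(obs) > 0L) {
        o <- as.list(obs[which.min(abs(obs$time_min - a)), ])
        mf$cap_refill_s <- o$cap_refill_s
        mf$map_mmhg <- o$map_mmhg
        mf$spo2_fio2 <- o$spo2_pct / o$fio2_fraction
      }
      rows[[i]] <- as.data.frame(
        c(list(patient_id = pid, anchor_min = a), row, mf,
          if ("outcome" %in% names(anchors)) list(outcome = anchors$outcome[i])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Names of the wearable-derived feature columns
#' @return character vector of column names produced by
#'   [build_feature_matrix()] from the wearable stream alone.
#' @export
wearable_feature_names <- function() {
  unlist(lapply(names(stream_vitals), function(v)
    c(paste0(v, c("_mean", "_sd", "_worst")),
      if (v %in% zoned_vitals) paste0(v, "_pct_red"))))
}

#' Names of the manually collected candidate feature columns
#' @return character vector of manual feature column names.
#' @export
manual_feature_names <- function() {
  c("age_months", "sex_male", "weight_kg", "height_cm", "muac_mm",
    "malnutrition", "diarrhea", "peripheral_edema", "jaundice",
    "delayed_skin_pinch", "sunken_eyes", "pupillary_abnormal",
    "general_appearance_ord", "cap_refill_s", "map_mmhg", "spo2_fio2")
}
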
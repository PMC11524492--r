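# Severity scoring: pSOFA (the study outcome), Goldstein SIRS (eligibility),
# and MPEWS red-zone classification (feature thresholds). All cutoffs come
# from editable tables (see tables.R), never from inline constants.

count_below <- function(value, bounds) sum(value < bounds)
count_at_or_above <- function(value, bounds) sum(value >= bounds)

# vasoactive dose tiers: data frame with columns drug, dose (ug/kg/min)
vasoactive_dose_score <- function(doses) {
  if (is.null(doses) || nrow(doses) == 0L) return(0L)
  drug <- tolower(doses$drug)
  dose <- doses$dose
  score <- 0L
  for (i in seq_along(drug)) {
    s <- switch(drug[i],
      dopamine = if (dose[i] > 15) 4L else if (dose[i] > 5) 3L else 2L,
      dobutamine = 2L,
      epinephrine = ,
      norepinephrine = if (dose[i] > 0.1) 4L else 3L,
      2L)
    score <- max(score, s)
  }
  score
}

#' Compute a pSOFA assessment
#'
#' Scores the six pSOFA organ systems (respiratory, coagulation, hepatic,
#' cardiovascular, neurologic, renal; 0--4 each) from one manual observation
#' and its matched lab panel. Respiratory scoring uses the SpO2:FiO2 ratio
#' when PaO2 is absent (scores 3--4 require respiratory support, inferred from
#' FiO2 > 0.21 when not supplied); cardiovascular scoring uses the
#' age-adjusted MAP cutoff and vasoactive support; renal cutoffs are selected
#' by age band. Advanced sepsis is a total strictly greater than 8.
#'
#' If the lab panel is flagged missing (or a required lab value is absent) the
#' assessment is returned with a missing total so downstream model code can
#' exclude it; no imputation is performed.
#'
#' @param obs one-row manual observation (needs `spo2_pct`, `fio2_fraction`,
#'   `map_mmhg`, `gcs`; optionally `pao2_mmhg`).
#' @param labs one-row lab panel (needs `platelets_10e3_ul`,
#'   `bilirubin_mg_dl`, `creatinine_mg_dl`; optionally `missing`).
#' @param profile one-row patient profile (needs `age_months`).
#' @param vasopressor_count number of concurrent vasoactive agents; mapped to
#'   cardiovascular scores 2/3/4 for 1/2/>=3 agents.
#' @param vasoactive_doses optional data frame with columns `drug`, `dose`
#'   (micrograms/kg/min); when given, dose tiers override the count-based
#'   mapping.
#' @param respiratory_support logical; default infers support from
#'   FiO2 > 0.21.
#' @param table a [psofa_table()].
#' @return one-row data frame of class `"psofa_assessment"` with the six
#'   subscores, `total`, `advanced`, and `missing`.
#' @export
compute_psofa <- function(obs, labs, profile, vasopressor_count = 0L,
                          vasoactive_doses = NULL, respiratory_support = NULL,
                          table = psofa_table()) {
  obs <- as_one_row(obs)
  labs <- as_one_row(labs)
  profile <- as_one_row(profile)
  age <- profile$age_months
  if (!is_number(age)) stop("patient age is required for pSOFA scoring")
  fio2 <- obs$fio2_fraction
  if (!is_number(fio2) || fio2 <= 0) stop("fio2_fraction must be > 0")
  if (!is_number(vasopressor_count) || vasopressor_count < 0)
    stop("vasopressor_count must be a non-negative count")
  # age-band lookups happen up front so coverage errors fire even for
  # missing-lab assessments
  cv_band <- psofa_age_band(table$cardiovascular$map_age_bands, age, "cardiovascular")
  renal_band <- psofa_age_band(table$renal$creatinine_age_bands, age, "renal")

  lab_missing <- isTRUE(labs$missing) ||
    !is_number(labs$platelets_10e3_ul) || !is_number(labs$bilirubin_mg_dl) ||
    !is_number(labs$creatinine_mg_dl)

  support <- if (is.null(respiratory_support)) fio2 > 0.21 else isTRUE(respiratory_support)
  resp <- if (is_number(obs$pao2_mmhg %||% NULL)) {
    count_below(obs$pao2_mmhg / fio2, table$respiratory$pf_ratio_lower)
  } else {
    count_below(obs$spo2_pct / fio2, table$respiratory$sf_ratio_lower)
  }
  if (!support) resp <- min(resp, table$respiratory$support_required_from - 1L)

  neuro <- count_below(obs$gcs, table$neurologic$gcs_lower)

  map_score <- if (obs$map_mmhg < cv_band$map_min) 1L else 0L
  vaso_score <- if (!is.null(vasoactive_doses)) {
    vasoactive_dose_score(vasoactive_doses)
  } else if (vasopressor_count >= 1) {
    tiers <- unlist(table$cardiovascular$vasoactive_count_scores)
    tiers[min(vasopressor_count, length(tiers))]
  } else 0L
  cardio <- max(map_score, vaso_score)

  if (lab_missing) {
    coag <- hepatic <- renal <- NA_integer_
  } else {
    coag <- count_below(labs$platelets_10e3_ul, table$coagulation$platelets_lower)
    hepatic <- count_at_or_above(labs$bilirubin_mg_dl, table$hepatic$bilirubin_upper)
    renal <- count_at_or_above(labs$creatinine_mg_dl, unlist(renal_band$lower))
  }
  total <- if (lab_missing) NA_integer_ else
    as.integer(resp + coag + hepatic + cardio + neuro + renal)
  out <- data.frame(
    patient_id = profile$patient_id %||% NA_character_,
    time_min = obs$time_min %||% NA_real_,
    respiratory = as.integer(resp), coagulation = as.integer(coag),
    hepatic = as.integer(hepatic), cardiovascular = as.integer(cardio),
    neurologic = as.integer(neuro), renal = as.integer(renal),
    total = total, advanced = if (is.na(total)) NA else total > 8,
    missing = lab_missing, stringsAsFactors = FALSE)
  class(out) <- c("psofa_assessment", "data.frame")
  out
}

#' Score pSOFA for a whole cohort
#'
#' Pairs each lab panel with the nearest manual observation of the same
#' patient (they must lie within `tolerance_min` of each other) and scores
#' each pair with [compute_psofa()]. Assessments from missing lab panels keep
#' a missing total and are excluded by the modeling code.
#'
#' @param labs,manual_obs,profiles cohort data frames.
#' @param table a [psofa_table()].
#' @param tolerance_min maximum |lab time - observation time| in minutes.
#' @return data frame of assessments (one row per usable lab panel).
#' @export
score_psofa_cohort <- function(labs, manual_obs, profiles,
                               table = psofa_table(), tolerance_min = 60) {
  out <- vector("list", nrow(labs))
  obs_split <- split(manual_obs, manual_obs$patient_id)
  prof_split <- split(profiles, profiles$patient_id)
  skipped <- 0L
  for (i in seq_len(nrow(labs))) {
    lab <- labs[i, , drop = FALSE]
    obs <- obs_split[[lab$patient_id]]
    prof <- prof_split[[lab$patient_id]]
    if (is.null(obs) || is.null(prof)) { skipped <- skipped + 1L; next }
    d <- abs(obs$time_min - lab$time_min)
    if (min(d) > tolerance_min) { skipped <- skipped + 1L; next }
    out[[i]] <- compute_psofa(obs[which.min(d), , drop = FALSE], lab, prof,
                              table = table)
  }
  if (skipped > 0L)
    warning(skipped, " lab panel(s) had no manual observation within ",
            tolerance_min, " minutes and were skipped")
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Goldstein SIRS criteria
#'
#' TRUE when at least two of the four criteria are met and at least one of
#' them is the temperature or leukocyte-count abnormality: (1) core
#' temperature > 38.5 or < 36 C; (2) tachycardia above the age bound (or
#' bradycardia below it, infants); (3) tachypnoea above the age bound or
#' mechanical ventilation; (4) leukocyte count elevated or depressed for age.
#'
#' When the leukocyte count is unavailable and the determinate criteria leave
#' the verdict open, `NA` is returned (indeterminate) rather than `FALSE`.
#'
#' @param obs one-row manual observation (`temp_c`, `hr_bpm`, `rr_brpm`).
#' @param wbc leukocyte count, 10^3/uL, or `NA`.
#' @param profile one-row profile (needs `age_months`).
#' @param ventilated mechanical ventilation flag.
#' @param norms an [age_norms()] table.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
goldstein_sirs <- function(obs, wbc, profile, ventilated = FALSE,
                           norms = age_norms()) {
  obs <- as_one_row(obs)
  profile <- as_one_row(profile)
  age <- profile$age_months
  hit <- which(norms$min_months <= age & age < norms$max_months)
  if (length(hit) == 0L)
    stop(sprintf("age %s months is outside the SIRS age-norm bands", format(age)))
  b <- norms[hit[1L], , drop = FALSE]
  temp_ab <- !is.na(obs$temp_c) &&
    (obs$temp_c > attr(norms, "fever_above_c") ||
     obs$temp_c < attr(norms, "hypothermia_below_c"))
  hr_ab <- obs$hr_bpm > b$hr_high ||
    (!is.na(b$hr_low) && obs$hr_bpm < b$hr_low)
  rr_ab <- isTRUE(ventilated) || obs$rr_brpm > b$rr_high
  wbc_ab <- if (is.na(wbc)) NA else (wbc > b$wbc_high || wbc < b$wbc_low)
  met <- c(temp_ab, hr_ab, rr_ab, wbc_ab)
  n_min <- sum(met, na.rm = TRUE)
  n_max <- n_min + sum(is.na(met))
  key_min <- isTRUE(temp_ab) || isTRUE(wbc_ab)
  key_max <- key_min || is.na(wbc_ab)
  if (n_min >= 2 && key_min) TRUE
  else if (n_max >= 2 && key_max) NA
  else FALSE
}

#' Classify a vital-sign value against the MPEWS red ("danger") zone
#'
#' Red when the value lies at or beyond the age band's red bounds (bounds
#' inclusive, the early-warning-score convention of triggering at the printed
#' threshold); otherwise normal. Vectorized over `value`.
#'
#' @param vital_kind one of the vital kinds in the table (`"hr"`, `"rr"`,
#'   `"skin_t"`, `"core_t"` in the shipped defaults).
#' @param value numeric vector of measurements.
#' @param age_months patient age.
#' @param table an [mpews_table()].
#' @return character vector, `"red"` or `"normal"`.
#' @export
mpews_zone <- function(vital_kind, value, age_months, table = mpews_table()) {
  band <- threshold_band(table, vital_kind, age_months)
  ifelse(value <= band$red_low | value >= band$red_high, "red", "normal")
}
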
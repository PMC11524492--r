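# Threshold / reference tables. All tables ship as editable YAML under
# inst/extdata and are loaded into plain data frames (or nested lists for the
# pSOFA cutoffs). Age bands are half-open [min_months, max_months).

default_table_path <- function(file)
  system.file("extdata", file, package = "sepsiswear", mustWork = TRUE)

#' Load the MPEWS-style age-band vital-sign threshold table
#'
#' Returns the red ("danger") zone bounds and normal reference ranges per age
#' band and vital kind. Red bounds are inclusive: a value at or beyond a bound
#' is red. The shipped defaults follow pediatric early-warning-score banding
#' conventions and are meant to be replaced by site-specific values where
#' available.
#'
#' @param path optional path to a YAML file with the same schema as the
#'   shipped `mpews_thresholds.yaml`.
#' @return a data frame with one row per (band, vital) and columns `band`,
#'   `min_months`, `max_months`, `vital`, `red_low`, `red_high`, `normal_low`,
#'   `normal_high`.
#' @export
mpews_table <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% default_table_path("mpews_thresholds.yaml"))
  rows <- list()
  for (band in raw$bands) {
    vitals <- setdiff(names(band), c("name", "min_months", "max_months"))
    for (v in vitals) {
      th <- band[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        band = band$name, min_months = as.numeric(band$min_months),
        max_months = as.numeric(band$max_months), vital = v,
        red_low = as.numeric(th$red_low), red_high = as.numeric(th$red_high),
        normal_low = as.numeric(th$normal_low %||% NA),
        normal_high = as.numeric(th$normal_high %||% NA),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  validate_band_table(tab, what = "MPEWS threshold")
  bad <- tab$red_low >= tab$red_high
  if (any(bad))
    stop("MPEWS threshold table: red_low must be < red_high (band ",
         tab$band[which(bad)[1L]], ", vital ", tab$vital[which(bad)[1L]], ")")
  class(tab) <- c("mpews_table", "data.frame")
  tab
}

# bands per vital must tile age without overlap
validate_band_table <- function(tab, what) {
  for (v in unique(tab$vital %||% "all")) {
    sub <- if (is.null(tab$vital)) tab else tab[tab$vital == v, , drop = FALSE]
    sub <- sub[order(sub$min_months), , drop = FALSE]
    if (any(sub$min_months >= sub$max_months))
      stop(what, " table: empty age band for vital ", v)
    if (nrow(sub) > 1L && any(sub$min_months[-1L] != sub$max_months[-nrow(sub)]))
      stop(what, " table: age bands must tile without gaps or overlap (vital ", v, ")")
  }
  invisible(tab)
}

# row lookup shared by scoring and feature code
threshold_band <- function(table, vital_kind, age_months) {
  sub <- table[table$vital == vital_kind, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("unknown vital kind '%s': not present in the threshold table",
                 vital_kind), call. = FALSE)
  hit <- which(sub$min_months <= age_months & age_months < sub$max_months)
  if (length(hit) == 0L)
    stop(sprintf(
      "age %s months is outside threshold-table coverage (bands span [%s, %s) months)",
      format(age_months), format(min(sub$min_months)), format(max(sub$max_months))),
      call. = FALSE)
  sub[hit[1L], , drop = FALSE]
}

#' Load the pSOFA cutoff table
#'
#' The pediatric Sequential Organ Failure Assessment cutoffs (six organ
#' systems, subscores 0--4) encoded as an editable, versioned data file rather
#' than hard-coded constants, so the scoring rules are auditable.
#'
#' @param path optional path to a YAML file with the same schema as the
#'   shipped `psofa_table.yaml`.
#' @return a nested list of cutoffs with class `"psofa_table"`.
#' @export
psofa_table <- function(path = NULL) {
  tab <- yaml::read_yaml(path %||% default_table_path("psofa_table.yaml"))
  needed <- c("respiratory", "coagulation", "hepatic", "neurologic",
              "cardiovascular", "renal")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("pSOFA table is missing sections: ", paste(missing, collapse = ", "))
  for (s in c("sf_ratio_lower", "pf_ratio_lower"))
    if (length(tab$respiratory[[s]]) != 4L)
      stop("pSOFA table: respiratory$", s, " must have 4 bounds")
  class(tab) <- "psofa_table"
  tab
}

# age-band pick inside the nested pSOFA list
psofa_age_band <- function(bands, age_months, what) {
  for (b in bands)
    if (age_months >= b$min_months && age_months < b$max_months) return(b)
  stop(sprintf("age %s months is outside the pSOFA %s age bands",
               format(age_months), what), call. = FALSE)
}

#' Load the Goldstein SIRS age-specific reference bounds
#'
#' Tachycardia/bradycardia, tachypnoea and leukocyte-count bounds by age band,
#' plus the core-temperature fever/hypothermia cutoffs, as used by
#' [goldstein_sirs()].
#'
#' @param path optional path to a YAML file with the same schema as the
#'   shipped `age_vital_norms.yaml`.
#' @return a data frame of bands with attributes `fever_above_c` and
#'   `hypothermia_below_c`.
#' @export
age_norms <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% default_table_path("age_vital_norms.yaml"))
  tab <- do.call(rbind, lapply(raw$bands, function(b)
    data.frame(min_months = b$min_months, max_months = b$max_months,
               hr_high = b$hr_high, hr_low = as.numeric(b$hr_low %||% NA),
               rr_high = b$rr_high, wbc_high = b$wbc_high, wbc_low = b$wbc_low)))
  validate_band_table(tab, what = "age-norm")
  attr(tab, "fever_above_c") <- raw$fever_above_c
  attr(tab, "hypothermia_below_c") <- raw$hypothermia_below_c
  tab
}

#' Load the generator's age-band baseline table
#'
#' Resting expected values per signal for a patient at latent severity zero;
#' the synthetic cohort generator adds severity effects and noise on top of
#' these.
#'
#' @param path optional path to a YAML file with the same schema as the
#'   shipped `age_baselines.yaml`.
#' @return a data frame with one row per age band.
#' @export
age_baselines <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% default_table_path("age_baselines.yaml"))
  tab <- do.call(rbind, lapply(raw$bands, as.data.frame))
  validate_band_table(tab, what = "baseline")
  tab
}

baseline_band <- function(baselines, age_months) {
  hit <- which(baselines$min_months <= age_months & age_months < baselines$max_months)
  if (length(hit) == 0L)
    stop(sprintf(
      "age %s months is outside baseline-table coverage (bands span [%s, %s) months)",
      format(age_months), format(min(baselines$min_months)),
      format(max(baselines$max_months))), call. = FALSE)
  baselines[hit[1L], , drop = FALSE]
}
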
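# Cohort directory layout: one directory per cohort with profiles.csv,
# severity.csv, vitals.csv, manual_obs.csv, labs.csv, clin_docs.csv and a
# config.yaml echo. CSVs are written with a header row, UTF-8, standard
# quoting. Unknown extra columns are tolerated with a warning on read.

cohort_files <- c(profiles = "profiles.csv", severity = "severity.csv",
                  vitals = "vitals.csv", manual_obs = "manual_obs.csv",
                  labs = "labs.csv", clin_docs = "clin_docs.csv")

cohort_schema <- list(
  profiles = c("patient_id", "age_months", "sex", "weight_kg", "height_cm",
               "muac_mm", "malnutrition", "diarrhea", "peripheral_edema",
               "jaundice", "delayed_skin_pinch", "sunken_eyes",
               "pupillary_reaction", "general_appearance"),
  severity = c("patient_id", "time_min", "severity", "advanced_truth"),
  vitals = c("patient_id", "time_min", "hr_bpm", "rr_brpm", "hrv_ms",
             "skin_t_c", "core_t_c", "activity", "sqi_pct"),
  manual_obs = c("patient_id", "time_min", "hr_bpm", "rr_brpm", "temp_c",
                 "temp_route", "map_mmhg", "spo2_pct", "fio2_fraction",
                 "gcs", "avpu", "cap_refill_s", "urine_output_ml_kg_h"),
  labs = c("patient_id", "time_min", "platelets_10e3_ul", "bilirubin_mg_dl",
           "creatinine_mg_dl", "wbc_10e3_ul", "missing"),
  clin_docs = c("patient_id", "time_min", "diagnosis"))

#' Write a cohort to a directory of CSV files
#'
#' @param cohort a `"sepsis_cohort"` (or a compatible named list of data
#'   frames).
#' @param dir output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort_files))
    write.csv(cohort[[nm]], file.path(dir, cohort_files[[nm]]),
              row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(cohort$config)) {
    cfg <- unclass(cohort$config)
    cfg$baseline_table <- NULL
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

row_error <- function(file, row, column, msg)
  stop(sprintf("%s: row %d, column '%s': %s", file, row, column, msg),
       call. = FALSE)

check_numeric_col <- function(df, file, col, lower = -Inf, upper = Inf,
                              na_ok = FALSE) {
  x <- df[[col]]
  if (!is.numeric(x) && !is.logical(x))
    row_error(file, 1L, col, "expected a numeric column")
  bad <- if (na_ok) which(!is.na(x) & (x < lower | x > upper))
         else which(is.na(x) | x < lower | x > upper)
  if (length(bad))
    row_error(file, bad[1L], col,
              sprintf("value out of [%s, %s]", format(lower), format(upper)))
  invisible(TRUE)
}

validate_cohort_table <- function(df, kind, file = cohort_files[[kind]]) {
  need <- cohort_schema[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), c(need, "monitor_hours"))
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s): %s", file,
                    paste(extra, collapse = ", ")), call. = FALSE)
  switch(kind,
    profiles = {
      if (anyDuplicated(df$patient_id))
        row_error(file, anyDuplicated(df$patient_id), "patient_id",
                  "duplicate patient id")
      check_numeric_col(df, file, "age_months", lower = 2)
      for (col in c("weight_kg", "height_cm", "muac_mm"))
        check_numeric_col(df, file, col, lower = 1e-9)
    },
    severity = {
      check_numeric_col(df, file, "severity", 0, 1)
      check_numeric_col(df, file, "time_min", lower = 0)
    },
    vitals = {
      check_numeric_col(df, file, "sqi_pct", 0, 100)
      for (col in c("hr_bpm", "rr_brpm", "hrv_ms", "skin_t_c", "core_t_c", "activity")) {
        bad <- which(!is.na(df$sqi_pct) & !is.finite(df[[col]]))
        if (length(bad)) row_error(file, bad[1L], col,
                                   "non-finite vital where SQI is recorded")
      }
      check_strict_time(df, file)
    },
    manual_obs = {
      check_numeric_col(df, file, "spo2_pct", 1e-9, 100)
      check_numeric_col(df, file, "fio2_fraction", 0.21, 1)
      check_numeric_col(df, file, "gcs", 3, 15)
    },
    labs = {
      for (col in c("platelets_10e3_ul", "bilirubin_mg_dl",
                    "creatinine_mg_dl", "wbc_10e3_ul")) {
        bad <- which(!df$missing & (is.na(df[[col]]) | df[[col]] <= 0))
        if (length(bad)) row_error(file, bad[1L], col,
                                   "non-positive or absent value in a non-missing panel")
      }
    },
    clin_docs = {
      bad <- which(!df$diagnosis %in% c("sepsis", "advanced_sepsis"))
      if (length(bad)) row_error(file, bad[1L], "diagnosis",
                                 "must be 'sepsis' or 'advanced_sepsis'")
    })
  invisible(df)
}

check_strict_time <- function(df, file) {
  for (pid in unique(df$patient_id)) {
    t <- df$time_min[df$patient_id == pid]
    bad <- which(diff(t) <= 0)
    if (length(bad))
      row_error(file, which(df$patient_id == pid)[bad[1L] + 1L], "time_min",
                sprintf("timestamps not strictly increasing for patient %s", pid))
  }
  invisible(TRUE)
}

#' Read and validate a cohort directory
#'
#' Schema violations are reported with the file, row and column of the first
#' offending value.
#'
#' @param dir directory written by [write_cohort()] (or files in the same
#'   schema from a real device export).
#' @return an object of class `"sepsis_cohort"`.
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (nm in names(cohort_files)) {
    path <- file.path(dir, cohort_files[[nm]])
    if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
    df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    validate_cohort_table(df, nm)
    out[[nm]] <- df
  }
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) out$config <- yaml::read_yaml(cfg_path)
  structure(out, class = "sepsis_cohort")
}
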
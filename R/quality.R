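# Signal-quality filtering. The wearable reports a per-minute signal quality
# index (SQI, 0-100%); minutes whose SQI fell below the threshold are deemed
# low quality and removed from all downstream analysis (no imputation).

#' Filter low-quality minutes from a wearable stream
#'
#' Keeps exactly the minutes with `sqi_pct >= sqi_threshold_pct` (the boundary
#' minute is kept: only windows that fell *below* the threshold are removed)
#' and reports per-patient data-capture metrics. The input may contain one or
#' several patients.
#'
#' @param stream a vitals data frame with columns `patient_id`, `time_min`,
#'   and `sqi_pct` (plus any vital columns).
#' @param sqi_threshold_pct threshold in percent, default 75.
#' @return a list of class `"quality_filter"`: `stream` (kept minutes) and
#'   `metrics`, a per-patient data frame with `monitored_hours`,
#'   `high_quality_fraction`, `n_minutes_total`, `n_minutes_kept`.
#' @export
filter_low_quality <- function(stream, sqi_threshold_pct = 75) {
  if (!is.data.frame(stream) || !all(c("patient_id", "sqi_pct") %in% names(stream)))
    stop("stream must be a data frame with 'patient_id' and 'sqi_pct' columns")
  if (nrow(stream) == 0L)
    stop("empty vital stream: nothing to filter")
  check_number(sqi_threshold_pct, "sqi_threshold_pct", 0, 100)
  keep <- !is.na(stream$sqi_pct) & stream$sqi_pct >= sqi_threshold_pct
  kept <- stream[keep, , drop = FALSE]
  ids <- unique(stream$patient_id)
  total <- as.integer(table(factor(stream$patient_id, levels = ids)))
  kept_n <- as.integer(table(factor(kept$patient_id, levels = ids)))
  metrics <- data.frame(
    patient_id = ids,
    monitored_hours = total / 60,
    high_quality_fraction = ifelse(total > 0, kept_n / total, 0),
    n_minutes_total = total,
    n_minutes_kept = kept_n,
    stringsAsFactors = FALSE)
  structure(list(stream = kept, metrics = metrics,
                 sqi_threshold_pct = sqi_threshold_pct),
            class = "quality_filter")
}

#' @export
print.quality_filter <- function(x, ...) {
  cat(sprintf("SQI filter at %.1f%%: kept %d of %d minutes (%d patients)\n",
              x$sqi_threshold_pct, sum(x$metrics$n_minutes_kept),
              sum(x$metrics$n_minutes_total), nrow(x$metrics)))
  cat(sprintf("  median per-patient high-quality fraction: %.4f\n",
              median(x$metrics$high_quality_fraction)))
  invisible(x)
}
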
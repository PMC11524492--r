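# Manual-versus-wearable vital-sign agreement: time-based pairing, Pearson
# correlation, mean absolute error, and Bland-Altman limits of agreement with
# a repeated-measures (variance components) option. Differences are always
# wearable minus manual; the manual value is the reference standard.

manual_vital_cols <- c(hr = "hr_bpm", rr = "rr_brpm",
                       skin_t = "temp_c", core_t = "temp_c")
wearable_vital_cols <- c(hr = "hr_bpm", rr = "rr_brpm",
                         skin_t = "skin_t_c", core_t = "core_t_c")

#' Pair manual observations with wearable stream minutes
#'
#' Each manual observation is paired with the nearest-in-time kept stream
#' minute of the same patient, provided the two fall within the same
#' five-minute tolerance; equidistant candidates resolve to the earlier
#' minute. Unpaired observations are dropped and counted in the `n_unpaired`
#' attribute.
#'
#' @param manual_obs manual observation data frame.
#' @param stream quality-filtered vitals data frame.
#' @param vital_kind `"hr"`, `"rr"`, `"skin_t"`, or `"core_t"`.
#' @param tolerance_minutes pairing tolerance, default 5.
#' @return data frame of paired measurements (`manual_value`,
#'   `wearable_value`, times, patient id) with attribute `n_unpaired`.
#' @export
pair_measurements <- function(manual_obs, stream, vital_kind = "hr",
                              tolerance_minutes = 5) {
  if (!vital_kind %in% names(manual_vital_cols))
    stop("unknown vital kind '", vital_kind, "'")
  mcol <- manual_vital_cols[[vital_kind]]
  wcol <- wearable_vital_cols[[vital_kind]]
  st_split <- lapply(split(stream, stream$patient_id),
                     function(s) s[order(s$time_min), , drop = FALSE])
  rows <- vector("list", nrow(manual_obs))
  unpaired <- 0L
  for (i in seq_len(nrow(manual_obs))) {
    m <- manual_obs[i, ]
    st <- st_split[[m$patient_id]]
    if (is.null(st) || nrow(st) == 0L || is.na(m[[mcol]])) {
      unpaired <- unpaired + 1L
      next
    }
    d <- abs(st$time_min - m$time_min)
    j <- which.min(d)                       # ties -> earlier minute
    if (d[j] > tolerance_minutes || is.na(st[[wcol]][j])) {
      unpaired <- unpaired + 1L
      next
    }
    rows[[i]] <- data.frame(
      patient_id = m$patient_id, vital_kind = vital_kind,
      manual_value = m[[mcol]], wearable_value = st[[wcol]][j],
      manual_time = m$time_min, wearable_time = st$time_min[j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(), vital_kind = character(),
                      manual_value = numeric(), wearable_value = numeric(),
                      manual_time = numeric(), wearable_time = numeric())
  attr(out, "n_unpaired") <- unpaired
  out
}

#' Pearson correlation and mean absolute error of paired measurements
#'
#' @param pairs output of [pair_measurements()].
#' @return list with `pearson_r`, `mae`, `n_pairs`. With zero variance in
#'   either coordinate the correlation is undefined: `pearson_r` is `NA` with
#'   a warning, while the MAE is still returned.
#' @export
correlation_mae <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs for a correlation")
  m <- pairs$manual_value
  w <- pairs$wearable_value
  mae <- mean(abs(w - m))
  if (sd(m) == 0 || sd(w) == 0) {
    warning("zero variance in one coordinate: correlation undefined")
    r <- NA_real_
  } else r <- cor(m, w)
  list(pearson_r = r, mae = mae, n_pairs = nrow(pairs))
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean difference (wearable minus manual); limits of agreement
#' are bias +/- 1.96 SD. With `method = "pooled"` the SD is the sample SD of
#' all differences. With `method = "variance_components"` (the default, for
#' repeated measures per patient) the SD combines the within-patient and
#' between-patient variance components from a one-way random-effects
#' decomposition of the differences, so replicated patients do not narrow the
#' limits artificially. When no patient has replicate pairs the two methods
#' coincide and the pooled computation is used.
#'
#' @param pairs output of [pair_measurements()].
#' @param method `"variance_components"` or `"pooled"`.
#' @return object of class `"agreement_result"`: `vital_kind`, `n_pairs`,
#'   `pearson_r`, `mae`, `bias`, `sd_d`, `loa_low`, `loa_high`, `method`.
#' @export
bland_altman <- function(pairs, method = c("variance_components", "pooled")) {
  method <- match.arg(method)
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  d <- pairs$wearable_value - pairs$manual_value
  bias <- mean(d)
  if (method == "variance_components") {
    ni <- table(pairs$patient_id)
    if (all(ni == 1L)) {
      method <- "pooled"                  # degenerate: identical results
    } else if (sum(ni >= 2L) < 2L) {
      stop("insufficient replication for variance_components ",
           "(need >= 2 patients with >= 2 pairs); use method = 'pooled'")
    }
  }
  if (method == "pooled") {
    sd_d <- sd(d)
  } else {
    g <- factor(pairs$patient_id)
    k <- nlevels(g)
    N <- length(d)
    ni <- as.numeric(table(g))
    gm <- tapply(d, g, mean)
    msb <- sum(ni * (gm - bias)^2) / (k - 1)
    msw <- sum((d - gm[g])^2) / (N - k)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    sigma_b2 <- max(0, (msb - msw) / n0)
    sd_d <- sqrt(sigma_b2 + msw)
  }
  r_mae <- if (nrow(pairs) >= 3L)
    suppressWarnings(correlation_mae(pairs)) else list(pearson_r = NA, mae = mean(abs(d)))
  structure(list(
    vital_kind = pairs$vital_kind[1L] %||% NA_character_,
    n_pairs = nrow(pairs), n_patients = length(unique(pairs$patient_id)),
    pearson_r = r_mae$pearson_r, mae = r_mae$mae,
    bias = bias, sd_d = sd_d,
    loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
    method = method), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement (%s, %d pairs, %s method)\n",
              x$vital_kind, x$n_pairs, x$method))
  cat(sprintf("  Pearson r = %.3f, MAE = %.3f\n", x$pearson_r, x$mae))
  cat(sprintf("  bias = %.3f, limits of agreement (%.3f, %.3f)\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Agreement summary for the standard four vitals
#'
#' Pairs and summarises HR, RR, skin and core temperature in one call.
#'
#' @param manual_obs,stream cohort tables (stream quality-filtered).
#' @param vitals vital kinds to analyse.
#' @param method passed to [bland_altman()].
#' @param tolerance_minutes passed to [pair_measurements()].
#' @return data frame, one row per vital kind.
#' @export
agreement_analysis <- function(manual_obs, stream,
                               vitals = c("hr", "rr", "skin_t", "core_t"),
                               method = "variance_components",
                               tolerance_minutes = 5) {
  do.call(rbind, lapply(vitals, function(v) {
    pr <- pair_measurements(manual_obs, stream, v, tolerance_minutes)
    ba <- bland_altman(pr, method = method)
    data.frame(vital_kind = v, n_pairs = ba$n_pairs, pearson_r = ba$pearson_r,
               mae = ba$mae, bias = ba$bias, loa_low = ba$loa_low,
               loa_high = ba$loa_high, method = ba$method,
               stringsAsFactors = FALSE)
  }))
}

#' Bland-Altman plot
#'
#' @param pairs output of [pair_measurements()].
#' @param result optional precomputed [bland_altman()] result.
#' @param ... passed to [plot()].
#' @return the `"agreement_result"` used, invisibly.
#' @export
plot_bland_altman <- function(pairs, result = NULL, ...) {
  result <- result %||% bland_altman(pairs)
  avg <- (pairs$wearable_value + pairs$manual_value) / 2
  d <- pairs$wearable_value - pairs$manual_value
  plot(avg, d, xlab = "mean of wearable and manual",
       ylab = "wearable - manual", ...)
  abline(h = result$bias, lty = 1)
  abline(h = c(result$loa_low, result$loa_high), lty = 2)
  invisible(result)
}
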
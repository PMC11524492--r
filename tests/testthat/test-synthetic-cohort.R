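# cohort generator: determinism, latent-path behaviour, observable rendering

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (nm in c("profiles", "severity", "vitals", "manual_obs", "labs", "clin_docs"))
    expect_identical(a[[nm]], b[[nm]])
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(lab_missing_prob = 1.5), "lab_missing_prob")
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(stream_noise_sd = list(hr = -1)), "stream_noise_sd")
  expect_error(generator_config(deterioration_prob = -0.1), "deterioration_prob")
})

test_that("zero volatility and drift give a constant path below the cutoff", {
  cfg <- tiny_config(severity_start_mean = 0.2, severity_start_sd = 0,
                     severity_volatility = 0, deterioration_prob = 0)
  set.seed(1)
  path <- simulate_severity_path(make_profile(monitor_hours = 10), cfg)
  expect_true(all(path$severity == 0.2))
  expect_false(any(path$advanced_truth))
  expect_true(all(diff(path$time_min) == cfg$severity_grid_minutes))
})

test_that("a monotone drift to 1 makes the advanced flag absorbing", {
  cfg <- tiny_config(severity_start_mean = 0.2, severity_start_sd = 0,
                     severity_volatility = 0, deterioration_prob = 1,
                     deterioration_drift_per_hour = 0.5)
  set.seed(2)
  path <- simulate_severity_path(make_profile(monitor_hours = 20), cfg)
  expect_true(any(path$advanced_truth))
  first <- which(path$advanced_truth)[1]
  expect_true(all(path$advanced_truth[first:nrow(path)]))
  expect_equal(max(path$severity), 1)
})

test_that("non-positive monitored duration is rejected", {
  expect_error(simulate_severity_path(make_profile(monitor_hours = 0), tiny_config()),
               "non-positive")
})

test_that("deterioration probability controls the ever-advanced fraction", {
  cfg <- tiny_config(severity_start_mean = 0.3, severity_start_sd = 0,
                     severity_volatility = 0, deterioration_prob = 0.25)
  set.seed(11)
  ever <- vapply(1:200, function(i) {
    any(simulate_severity_path(make_profile(monitor_hours = 30), cfg)$advanced_truth)
  }, logical(1))
  expect_lt(abs(mean(ever) - 0.25), 0.1)
})

test_that("advanced truth is recoverable from the severity path and cutoff", {
  co <- simulate_cohort(tiny_config())
  expect_identical(co$severity$advanced_truth,
                   co$severity$severity >= co$config$severity_cutoff)
})

test_that("zero noise and zero effects reproduce the age-band baseline exactly", {
  zero <- function(x) stats::setNames(as.list(rep(0, length(x))), x)
  cfg <- tiny_config(
    effect_sizes = utils::modifyList(generator_config()$effect_sizes,
                                     zero(names(generator_config()$effect_sizes))),
    stream_noise_sd = zero(c("hr", "rr", "hrv", "skin_t", "core_t", "activity")),
    between_patient_sd = zero(c("hr", "rr", "hrv", "skin_t", "core_t", "activity")))
  set.seed(3)
  prof <- make_profile(age_months = 6, monitor_hours = 5)
  path <- simulate_severity_path(prof, cfg)
  rend <- render_observables(path, prof, cfg)
  base <- age_baselines()
  b <- base[base$min_months <= 6 & 6 < base$max_months, ]
  expect_true(all(rend$vitals$hr_bpm == b$hr))
  expect_true(all(rend$vitals$rr_brpm == b$rr))
  expect_true(all(rend$vitals$core_t_c == b$core_t))
})

test_that("with zero effect sizes severity is uncorrelated with the vitals", {
  zero <- function(x) stats::setNames(as.list(rep(0, length(x))), x)
  cfg <- tiny_config(
    n_patients = 5, mean_monitor_hours = 35, sd_monitor_hours = 0,
    effect_sizes = utils::modifyList(generator_config()$effect_sizes,
                                     zero(names(generator_config()$effect_sizes))),
    between_patient_sd = zero(c("hr", "rr", "hrv", "skin_t", "core_t", "activity")),
    seed = 13)
  co <- simulate_cohort(cfg)
  sev <- merge(co$vitals[, c("patient_id", "time_min", "hr_bpm")],
               co$severity, by = c("patient_id", "time_min"))
  expect_gt(nrow(co$vitals), 10000)
  # centre within patient so age-band baseline differences cannot confound
  ctr <- function(x, g) x - ave(x, g)
  r <- cor(ctr(sev$severity, sev$patient_id), ctr(sev$hr_bpm, sev$patient_id))
  expect_lt(abs(r), 0.05)
})

test_that("the heart-rate effect size is recovered from forced severity groups", {
  base <- list(severity_start_sd = 0, severity_volatility = 0,
               deterioration_prob = 0, n_patients = 3,
               mean_monitor_hours = 28, sd_monitor_hours = 0,
               between_patient_sd = list(hr = 0, rr = 0, hrv = 0, skin_t = 0,
                                         core_t = 0, activity = 0))
  hi <- simulate_cohort(do.call(tiny_config,
                                c(base, list(severity_start_mean = 1, seed = 21))))
  lo <- simulate_cohort(do.call(tiny_config,
                                c(base, list(severity_start_mean = 0, seed = 22))))
  expect_gt(nrow(hi$vitals), 5000)
  diff_hr <- mean(hi$vitals$hr_bpm) - mean(lo$vitals$hr_bpm)
  expect_lt(abs(diff_hr - generator_config()$effect_sizes$hr), 2)
})

test_that("lab panel missingness tracks the configured probability", {
  cfg <- tiny_config(n_patients = 120, mean_monitor_hours = 48,
                     sd_monitor_hours = 6, lab_missing_prob = 0.09, seed = 31)
  co <- simulate_cohort(cfg)
  expect_gte(nrow(co$labs), 500)
  expect_lt(abs(mean(co$labs$missing) - 0.09), 0.03)
  expect_true(all(is.na(co$labs$platelets_10e3_ul[co$labs$missing])))
})

test_that("a degenerate documentation lag places the advanced doc exactly on time", {
  cfg <- tiny_config(n_patients = 12, doc_lag_sdlog = 0,
                     doc_false_positive_prob = 0, seed = 41)
  co <- simulate_cohort(cfg)
  adv_docs <- co$clin_docs[co$clin_docs$diagnosis == "advanced_sepsis", ]
  expect_gt(nrow(adv_docs), 0)
  for (i in seq_len(nrow(adv_docs))) {
    sev <- co$severity[co$severity$patient_id == adv_docs$patient_id[i], ]
    t_first <- sev$time_min[which(sev$advanced_truth)[1]]
    expect_equal(adv_docs$time_min[i], t_first + 120)
  }
})

test_that("manual minus stream differences match the configured bias and noise", {
  cfg <- tiny_config(n_patients = 100, mean_monitor_hours = 52.5,
                     sd_monitor_hours = 13,
                     manual_bias = list(hr = 2, rr = -0.29, temp = 0),
                     seed = 51)
  co <- simulate_cohort(cfg)
  m <- merge(co$manual_obs[, c("patient_id", "time_min", "hr_bpm")],
             co$vitals[, c("patient_id", "time_min", "hr_bpm")],
             by = c("patient_id", "time_min"), suffixes = c("_man", "_str"))
  expect_gte(nrow(m), 5000)
  d <- m$hr_bpm_man - m$hr_bpm_str
  expect_lt(abs(mean(d) - 2) / 2, 0.10)
  expect_lt(abs(sd(d) - cfg$manual_noise_sd$hr) / cfg$manual_noise_sd$hr, 0.10)
})

test_that("ages outside the baseline table are reported with coverage bounds", {
  cfg <- tiny_config()
  set.seed(6)
  prof <- make_profile(age_months = 300, monitor_hours = 5)
  path <- simulate_severity_path(prof, cfg)
  expect_error(render_observables(path, prof, cfg), "coverage")
})
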
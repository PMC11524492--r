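# pSOFA, Goldstein SIRS and MPEWS zone classification

normal_inputs <- function() list(
  obs = make_obs(spo2 = 100, fio2 = 0.21, map = 70, gcs = 15L),
  labs = make_labs(platelets = 300, bilirubin = 0.4, creatinine = 0.2),
  profile = make_profile(age_months = 6))

test_that("all-normal inputs score pSOFA 0 and all-worst inputs score 24", {
  x <- normal_inputs()
  ps <- compute_psofa(x$obs, x$labs, x$profile)
  expect_equal(ps$total, 0L)
  expect_false(ps$advanced)

  worst <- compute_psofa(
    make_obs(spo2 = 60, fio2 = 1, map = 20, gcs = 3L),
    make_labs(platelets = 5, bilirubin = 20, creatinine = 9),
    x$profile, vasopressor_count = 3)
  expect_equal(worst$total, 24L)
  expect_true(worst$advanced)
  expect_true(all(unlist(worst[c("respiratory", "coagulation", "hepatic",
                                 "cardiovascular", "neurologic", "renal")]) == 4L))
})

test_that("the mixed-dysfunction example matches the published-table subscores", {
  # SpO2:FiO2 200 on support, platelets 120, bilirubin 2.5, MAP below the
  # age cutoff without vasoactives, GCS 12, normal creatinine; subscores
  # frozen from the published pSOFA cutoffs
  ps <- compute_psofa(
    make_obs(spo2 = 96, fio2 = 0.48, map = 50, gcs = 12L),
    make_labs(platelets = 120, bilirubin = 2.5, creatinine = 0.2),
    make_profile(age_months = 6))
  expect_equal(ps$respiratory, 3L)
  expect_equal(ps$coagulation, 1L)
  expect_equal(ps$hepatic, 2L)
  expect_equal(ps$cardiovascular, 1L)
  expect_equal(ps$neurologic, 2L)
  expect_equal(ps$renal, 0L)
  expect_equal(ps$total, 9L)
  expect_equal(ps$total, with(ps, respiratory + coagulation + hepatic +
                                cardiovascular + neurologic + renal))
  expect_true(ps$advanced)
})

test_that("respiratory scores above 2 require respiratory support", {
  x <- normal_inputs()
  on_support <- compute_psofa(make_obs(spo2 = 85, fio2 = 0.6), x$labs, x$profile,
                              respiratory_support = TRUE)
  off_support <- compute_psofa(make_obs(spo2 = 85, fio2 = 0.6), x$labs, x$profile,
                               respiratory_support = FALSE)
  expect_equal(on_support$respiratory, 4L)
  expect_equal(off_support$respiratory, 2L)
})

test_that("vasoactive support escalates the cardiovascular subscore", {
  x <- normal_inputs()
  counts <- vapply(0:4, function(k)
    compute_psofa(x$obs, x$labs, x$profile, vasopressor_count = k)$cardiovascular,
    integer(1))
  expect_equal(counts, c(0L, 2L, 3L, 4L, 4L))
  dosed <- compute_psofa(x$obs, x$labs, x$profile,
                         vasoactive_doses = data.frame(drug = "dopamine", dose = 4))
  expect_equal(dosed$cardiovascular, 2L)
  dosed_hi <- compute_psofa(x$obs, x$labs, x$profile,
                            vasoactive_doses = data.frame(drug = "norepinephrine",
                                                          dose = 0.3))
  expect_equal(dosed_hi$cardiovascular, 4L)
})

test_that("invalid FiO2 and uncovered ages are rejected", {
  x <- normal_inputs()
  expect_error(compute_psofa(make_obs(fio2 = 0), x$labs, x$profile), "fio2")
  expect_error(compute_psofa(x$obs, x$labs, make_profile(age_months = 300)),
               "age bands")
})

test_that("missing labs yield a missing total flagged for exclusion", {
  x <- normal_inputs()
  ps <- compute_psofa(x$obs, make_labs(missing = TRUE, platelets = NA,
                                       bilirubin = NA, creatinine = NA),
                      x$profile)
  expect_true(ps$missing)
  expect_true(is.na(ps$total))
  expect_true(is.na(ps$advanced))
})

test_that("pSOFA is monotone under single-input worsening", {
  x <- normal_inputs()
  base <- compute_psofa(make_obs(spo2 = 95, fio2 = 0.4, map = 58, gcs = 12L),
                        make_labs(platelets = 140, bilirubin = 2.1,
                                  creatinine = 0.6),
                        x$profile, vasopressor_count = 1)
  worse_one <- list(
    compute_psofa(make_obs(spo2 = 80, fio2 = 0.4, map = 58, gcs = 12L),
                  make_labs(platelets = 140, bilirubin = 2.1, creatinine = 0.6),
                  x$profile, vasopressor_count = 1),
    compute_psofa(make_obs(spo2 = 95, fio2 = 0.4, map = 40, gcs = 6L),
                  make_labs(platelets = 140, bilirubin = 2.1, creatinine = 0.6),
                  x$profile, vasopressor_count = 1),
    compute_psofa(make_obs(spo2 = 95, fio2 = 0.4, map = 58, gcs = 12L),
                  make_labs(platelets = 15, bilirubin = 13, creatinine = 1.5),
                  x$profile, vasopressor_count = 2))
  for (w in worse_one) expect_gte(w$total, base$total)
})

test_that("cohort-level scoring pairs labs with the nearest observation", {
  co <- simulate_cohort(tiny_config(seed = 71))
  ps <- score_psofa_cohort(co$labs, co$manual_obs, co$profiles)
  expect_equal(nrow(ps), nrow(co$labs))
  expect_true(all(ps$total[!is.na(ps$total)] >= 0 &
                  ps$total[!is.na(ps$total)] <= 24))
  expect_equal(sum(is.na(ps$total)), sum(co$labs$missing))
})

test_that("Goldstein SIRS requires the temperature-or-leukocyte key criterion", {
  prof <- make_profile(age_months = 6)
  # fever + age-adjusted tachycardia
  expect_true(goldstein_sirs(make_obs(temp = 39.2, hr = 185, rr = 30),
                             wbc = 10, prof))
  # tachycardia + tachypnoea only: no key criterion
  expect_false(goldstein_sirs(make_obs(temp = 37.0, hr = 185, rr = 40),
                              wbc = 10, prof))
  # everything normal
  expect_false(goldstein_sirs(make_obs(temp = 37.0, hr = 120, rr = 30),
                              wbc = 10, prof))
  # hypothermia + leukopenia
  expect_true(goldstein_sirs(make_obs(temp = 35.5, hr = 120, rr = 30),
                             wbc = 3, prof))
  # ventilation satisfies the respiratory criterion
  expect_true(goldstein_sirs(make_obs(temp = 39.0, hr = 120, rr = 20),
                             wbc = 10, prof, ventilated = TRUE))
})

test_that("a missing leukocyte count leaves an open verdict indeterminate", {
  prof <- make_profile(age_months = 6)
  # tachycardic, normal temperature: abnormal WBC would tip it to TRUE
  expect_true(is.na(goldstein_sirs(make_obs(temp = 37, hr = 185, rr = 30),
                                   wbc = NA, prof)))
  # nothing else abnormal: WBC alone could never reach two criteria
  expect_false(goldstein_sirs(make_obs(temp = 37, hr = 120, rr = 30),
                              wbc = NA, prof))
})

test_that("MPEWS red zone bounds are inclusive and age-specific", {
  expect_equal(mpews_zone("hr", 195, 6), "red")
  expect_equal(mpews_zone("hr", 180, 6), "red")        # at the bound
  expect_equal(mpews_zone("hr", 130, 6), "normal")
  expect_equal(mpews_zone("hr", 90, 6), "red")         # bradycardic bound
  expect_equal(mpews_zone("hr", c(195, 130), 6), c("red", "normal"))
  expect_equal(mpews_zone("hr", 150, 160), "red")      # adolescent band
  expect_error(mpews_zone("blood_sugar", 5, 6), "unknown vital kind")
})

test_that("red HR values always lie outside the band's normal range", {
  tab <- mpews_table()
  sub <- tab[tab$vital == "hr", ]
  for (i in seq_len(nrow(sub))) {
    age <- sub$min_months[i]
    vals <- seq(30, 250, by = 1)
    red <- mpews_zone("hr", vals, age, tab) == "red"
    inside_normal <- vals > sub$normal_low[i] & vals < sub$normal_high[i]
    expect_false(any(red & inside_normal))
  }
})
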
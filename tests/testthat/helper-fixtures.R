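# fixtures are built in code; nothing is read from disk

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 3L, seed = 7L, mean_monitor_hours = 24,
                   sd_monitor_hours = 4, min_monitor_hours = 12)
  do.call(generator_config, utils::modifyList(defaults, args))
}

make_profile <- function(patient_id = "P1", age_months = 6,
                         monitor_hours = 24, ...) {
  out <- list(patient_id = patient_id, age_months = age_months,
              sex = "male", weight_kg = 7, height_cm = 65, muac_mm = 125,
              malnutrition = FALSE, diarrhea = TRUE, peripheral_edema = FALSE,
              jaundice = FALSE, delayed_skin_pinch = FALSE,
              sunken_eyes = FALSE, pupillary_reaction = "normal",
              general_appearance = "ill", monitor_hours = monitor_hours)
  as.data.frame(utils::modifyList(out, list(...)), stringsAsFactors = FALSE)
}

make_stream <- function(patient_id = "P1", time_min = 0:59, hr = 120, rr = 35,
                        hrv = 40, skin = 36.5, core = 37, activity = 0.2,
                        sqi = 100) {
  n <- length(time_min)
  data.frame(patient_id = rep_len(patient_id, n), time_min = time_min,
             hr_bpm = rep_len(hr, n), rr_brpm = rep_len(rr, n),
             hrv_ms = rep_len(hrv, n), skin_t_c = rep_len(skin, n),
             core_t_c = rep_len(core, n), activity = rep_len(activity, n),
             sqi_pct = rep_len(sqi, n), stringsAsFactors = FALSE)
}

make_obs <- function(time_min = 0, spo2 = 100, fio2 = 0.21, map = 70,
                     gcs = 15L, hr = 120, rr = 30, temp = 37) {
  data.frame(patient_id = "P1", time_min = time_min, hr_bpm = hr,
             rr_brpm = rr, temp_c = temp, temp_route = "rectal",
             map_mmhg = map, spo2_pct = spo2, fio2_fraction = fio2,
             gcs = gcs, avpu = "A", cap_refill_s = 2,
             urine_output_ml_kg_h = 2, stringsAsFactors = FALSE)
}

make_labs <- function(time_min = 0, platelets = 300, bilirubin = 0.4,
                      creatinine = 0.2, wbc = 10, missing = FALSE) {
  data.frame(patient_id = "P1", time_min = time_min,
             platelets_10e3_ul = platelets, bilirubin_mg_dl = bilirubin,
             creatinine_mg_dl = creatinine, wbc_10e3_ul = wbc,
             missing = missing, stringsAsFactors = FALSE)
}

# pairs table in the shape pair_measurements() produces
make_pairs <- function(manual, wearable, patient_id = "P1") {
  data.frame(patient_id = rep_len(patient_id, length(manual)),
             vital_kind = "hr", manual_value = manual,
             wearable_value = wearable,
             manual_time = seq_along(manual) * 60,
             wearable_time = seq_along(manual) * 60,
             stringsAsFactors = FALSE)
}
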
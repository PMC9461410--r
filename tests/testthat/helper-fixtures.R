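# Fixtures built in code: questionnaire entries, hourly series, tiny
# simulation configs.

q_entry <- function(pid, ts, symptoms = "", temperature_c = NA_real_) {
  data.frame(participant_id = pid,
             timestamp = parse_timestamp(ts),
             symptoms = symptoms, temperature_c = temperature_c,
             stringsAsFactors = FALSE)
}

q_entries <- function(...) do.call(rbind, list(...))

# hourly series over [-168, 336) from a value function of hour offset;
# `missing_hours` are masked
hs_full <- function(value_fn = function(h) rep(60, length(h)),
                    missing_hours = integer(0), pid = "P1",
                    channel = "heart_rate",
                    origin = parse_timestamp("2021-08-03 10:00:00")) {
  h <- seq(-168L, 335L)
  v <- value_fn(h)
  s <- ifelse(is.na(v) | h %in% missing_hours, "missing", "observed")
  v[s == "missing"] <- NA_real_
  new_hourly_series(h, v, s, pid, channel, origin)
}

# noise-free deterministic config; any field can be overridden
quiet_config <- function(...) {
  zero <- c(heart_rate = 0, stress = 0)
  defaults <- list(n_participants = 1, circadian_amplitude = zero,
                   participant_sd = zero, hourly_sd = zero, noise_sd = zero,
                   gap_rate = 0)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

zero_curve <- function() response_curve_params(peak_elevation = 0)

# one roster row
fake_participant <- function(pid = "P1", severity = "none",
                             vt = "2021-08-03 10:25:00", age = 50,
                             sex = "female", cond = FALSE, dose = 3L) {
  data.frame(participant_id = pid, age = age, sex = sex,
             underlying_condition = cond, dose = dose,
             vaccination_time = parse_timestamp(vt), true_severity = severity,
             stringsAsFactors = FALSE)
}
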
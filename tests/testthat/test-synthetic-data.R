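# synthetic cohort generator

test_that("configuration is validated", {
  expect_error(simulation_config(severity_mix = c(0.5, 0.4, 0.4)),
               "severity_mix")
  expect_error(simulation_config(gap_rate = -1), "gap_rate")
  expect_error(reporting_model(compliance = 1.2), "\\[0, 1\\]")
  expect_error(simulate_stream(fake_participant(), "spo2",
                               config = quiet_config()), "unknown channel")
})

test_that("generate_cohort draws severity from the mix and ages in range", {
  cfg <- simulation_config(n_participants = 100,
                           severity_mix = c(none = 0.5, mild = 0.35,
                                            severe = 0.15), seed = 7)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 100)
  expect_true(all(coh$age >= 18 & coh$age <= 88))
  expect_true(all(coh$sex %in% c("female", "male")))
  counts <- table(factor(coh$true_severity, levels = c("none", "mild",
                                                       "severe")))
  # within 4 multinomial standard deviations of (50, 35, 15)
  exp_n <- c(50, 35, 15)
  sds <- sqrt(exp_n * (1 - exp_n / 100))
  expect_true(all(abs(as.integer(counts) - exp_n) <= 4 * sds))
  # degenerate mixture
  one <- generate_cohort(simulation_config(n_participants = 1,
                                           severity_mix = c(1, 0, 0)))
  expect_identical(one$true_severity, "none")
})

test_that("fixed seed gives identical output; substreams are stable", {
  cfg <- simulation_config(n_participants = 20, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  big <- generate_cohort(simulation_config(n_participants = 40, seed = 11))
  expect_identical(generate_cohort(cfg), big[1:20, ])
  p <- generate_cohort(cfg)[3, ]
  s1 <- simulate_stream(p, "stress", config = cfg)
  s2 <- simulate_stream(p, "stress", config = cfg)
  expect_identical(s1, s2)
  q1 <- generate_questionnaires(p, cfg$reporting, seed = 5)
  expect_identical(q1, generate_questionnaires(p, cfg$reporting, seed = 5))
})

test_that("streams have exact device cadence and physiological clipping", {
  cfg <- simulation_config(n_participants = 1, noise_sd = c(heart_rate = 40,
                                                            stress = 60),
                           seed = 3)
  p <- generate_cohort(cfg)[1, ]
  hr <- simulate_stream(p, "heart_rate", config = cfg)
  st <- simulate_stream(p, "stress", config = cfg)
  expect_true(all(diff(as.numeric(hr$timestamp)) == 15))
  expect_true(all(diff(as.numeric(st$timestamp)) == 180))
  # spans [-168h, +336h) around the vaccination hour
  org <- as.numeric(format(parse_timestamp(p$vaccination_time), "%s"))
  expect_equal(nrow(hr), 504 * 240)
  expect_equal(nrow(st), 504 * 20)
  expect_true(all(st$value >= 1 & st$value <= 100))
  expect_true(all(hr$value >= 30))
})

test_that("noise-free hourly means match the analytic signal", {
  cfg <- quiet_config(circadian_amplitude = c(heart_rate = 4, stress = 8))
  p <- fake_participant(severity = "severe")
  curve <- default_curve("heart_rate", "severe")
  s <- simulate_stream(p, "heart_rate", curve, cfg)
  hs <- hourly_average(s, p$vaccination_time)
  # oracle: average the signal evaluated directly at the sample instants
  vt <- as.numeric(parse_timestamp(p$vaccination_time))
  tt <- as.numeric(s$timestamp)
  hod <- (tt %% 86400) / 3600
  expected_samples <- cfg$circadian_mean[["heart_rate"]] +
    4 * (-cos(2 * pi * (hod - 4) / 24)) +
    response_curve(curve, (tt - vt) / 3600)
  hour <- floor((tt - (vt - vt %% 3600)) / 3600)
  exp_means <- tapply(expected_samples, hour, mean)
  got <- hs$value[match(as.integer(names(exp_means)), hs$hour)]
  expect_lt(max(abs(got - as.numeric(exp_means))), 1e-9)
  # severe curve is anchored at ~9 bpm at 24 h post-dose
  expect_equal(response_curve(curve, 24), 9)
  expect_equal(response_curve(curve, c(-5, 0)), c(0, 0))
})

test_that("zero response curve leaves post hourly means at baseline", {
  cfg <- quiet_config()
  p <- fake_participant()
  s <- simulate_stream(p, "heart_rate", zero_curve(), cfg)
  hs <- hourly_average(s, p$vaccination_time)
  expect_lt(max(abs(hs$value - cfg$circadian_mean[["heart_rate"]])), 1e-12)
})

test_that("injected gaps drive interpolation and masking downstream", {
  cfg <- quiet_config()
  p <- fake_participant()
  s <- simulate_stream(p, "heart_rate", zero_curve(), cfg)
  expect_identical(inject_gaps(s, gap_rate = 0), s)
  expect_error(inject_gaps(s, gap_rate = -0.1), "gap_rate")
  org <- vaxwatch:::floor_hour(parse_timestamp(p$vaccination_time))
  drop_hours <- function(s, hours) {
    off <- vaxwatch:::hour_offset(parse_timestamp(s$timestamp), org)
    s[!off %in% hours, , drop = FALSE]
  }
  # a 3 h gap is linearly interpolated: exactly 3 filled cells
  hs3 <- hourly_average(drop_hours(s, 40:42), p$vaccination_time)
  fixed <- interpolate_gaps(hs3)
  expect_equal(sum(fixed$status == "interpolated"), 3)
  expect_true(all(fixed$status[fixed$hour %in% 40:42] == "interpolated"))
  # an 8 h gap stays masked
  hs8 <- hourly_average(drop_hours(s, 100:107), p$vaccination_time)
  fixed8 <- interpolate_gaps(hs8)
  expect_true(all(fixed8$status[fixed8$hour %in% 100:107] == "missing"))
  # the stated-world default config exercises the > 5 h exclusion path
  cohort <- simulate_cohort(simulation_config(n_participants = 15, seed = 2))
  long_gap <- vapply(cohort$hourly, function(h) {
    r <- rle(h$status == "missing")
    any(r$values & r$lengths > 5)
  }, logical(1))
  expect_true(any(long_gap))
})

test_that("questionnaire generator respects the reporting model", {
  # zero reporting -> no symptoms -> tier none
  mute <- reporting_model(p_mild = c(none = 0, mild = 0, severe = 0),
                          p_severe = c(none = 0, mild = 0, severe = 0),
                          baseline_rate = 0, compliance = 1,
                          duplicate_rate = 0)
  p <- fake_participant(severity = "severe")
  q <- generate_questionnaires(p, mute, seed = 4)
  expect_true(all(q$symptoms == ""))
  expect_equal(tier_cohort(p, q)$tier, "none")
  # certain severe reporting -> tier severe
  loud <- reporting_model(p_severe = c(none = 0, mild = 0, severe = 1),
                          compliance = 1, duplicate_rate = 0,
                          p_fever_temp = 0)
  q2 <- generate_questionnaires(p, loud, seed = 4)
  expect_equal(tier_cohort(p, q2)$tier, "severe")
  # per-day reporting fraction matches the binomial oracle
  pr <- 0.6
  model <- reporting_model(p_mild = c(none = 0, mild = pr, severe = 0),
                           p_severe = c(none = 0, mild = 0, severe = 0),
                           baseline_rate = 0, compliance = 1,
                           duplicate_rate = 0)
  n_day0 <- 0; n_tot <- 0
  for (i in 1:300) {
    pi <- fake_participant(pid = sprintf("M%03d", i), severity = "mild")
    qi <- generate_questionnaires(pi, model, seed = 1000 + i)
    day0 <- qi[as.Date(qi$timestamp) ==
                 as.Date(parse_timestamp(pi$vaccination_time)), ]
    n_tot <- n_tot + 1
    if (nrow(day0) && nzchar(day0$symptoms[1])) n_day0 <- n_day0 + 1
  }
  ci <- stats::binom.test(n_day0, n_tot, pr)$conf.int
  expect_true(pr >= ci[1] && pr <= ci[2])
})

test_that("hourly fast path agrees with the raw-cadence path up to noise", {
  cfg <- quiet_config(circadian_amplitude = c(heart_rate = 4, stress = 0))
  p <- fake_participant(severity = "mild")
  hs_raw <- hourly_average(
    simulate_stream(p, "heart_rate", config = cfg), p$vaccination_time)
  hs_fast <- simulate_hourly(p, "heart_rate", config = cfg, gaps = FALSE)
  # same grid; values differ only by quadrature of the response curve and
  # discrete-vs-continuous circadian averaging (both < 0.05 bpm)
  expect_identical(hs_raw$hour, hs_fast$hour)
  expect_lt(max(abs(hs_raw$value - hs_fast$value)), 0.05)
})
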
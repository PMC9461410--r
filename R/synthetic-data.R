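# Synthetic cohort generator. Emulates the data structure the analysis
# assumes: per-participant circadian baselines with participant-level
# random effects, a severity-dependent post-vaccination elevation peaking
# near 24 h, device-charging gaps, and probabilistic daily symptom
# reporting. Every draw is taken from a per-participant RNG substream split
# off the master seed, so changing the cohort size never reshuffles
# existing participants.

.CHANNELS <- c("heart_rate", "stress")
.CADENCE_S <- c(heart_rate = 15, stress = 180)
.HR_FLOOR <- 30

#' Symptom reporting model
#'
#' Per-severity probabilities governing the daily questionnaire generator.
#' `p_mild`/`p_severe` are per-day probabilities (post-vaccination days
#' 0-2) that a participant of each true severity reports at least one
#' mild/severe-list symptom; under-reporting (severe physiology with no
#' symptoms) is emulated by values below 1. `baseline_rate` is the per-day
#' probability of a background mild symptom on any day, `compliance` the
#' per-day probability of submitting at all, `duplicate_rate` the
#' probability of an extra same-day morning submission (exercises the
#' last-entry-per-day rule), and `p_fever_temp` the probability that a
#' severe-day report goes through the feeling-hot-plus-temperature path
#' rather than a direct severe token.
#'
#' @param p_mild,p_severe named numeric vectors over none/mild/severe.
#' @param baseline_rate,compliance,duplicate_rate,p_fever_temp scalars in
#'   `[0, 1]`.
#' @return list of class `reporting_model`.
#' @export
reporting_model <- function(p_mild = c(none = 0.05, mild = 0.85, severe = 0.90),
                            p_severe = c(none = 0, mild = 0.02, severe = 0.85),
                            baseline_rate = 0.03,
                            compliance = 0.95,
                            duplicate_rate = 0.05,
                            p_fever_temp = 0.2) {
  probs <- c(p_mild, p_severe, baseline_rate, compliance, duplicate_rate,
             p_fever_temp)
  if (any(probs < 0 | probs > 1)) {
    stop("reporting model probabilities must lie in [0, 1]")
  }
  stopifnot(all(.TIERS %in% names(p_mild)), all(.TIERS %in% names(p_severe)))
  structure(list(p_mild = p_mild, p_severe = p_severe,
                 baseline_rate = baseline_rate, compliance = compliance,
                 duplicate_rate = duplicate_rate,
                 p_fever_temp = p_fever_temp),
            class = "reporting_model")
}

#' Simulation configuration
#'
#' The stated world of the generator. Channel-level parameters are named
#' vectors over `heart_rate` and `stress`; defaults put the heart-rate
#' baseline near 65 bpm with a 4 bpm circadian swing (trough at 04:00) and
#' the stress index near 30 points with an 8-point swing. `participant_sd`
#' is the between-participant random-intercept scale, `hourly_sd` a
#' within-participant hour-level disturbance (activity, posture) shared by
#' all samples in an hour, and `noise_sd` the sample-level measurement
#' noise. `gap_rate` is the expected number of device-off gaps per day and
#' `gap_length_mean_h` the mean (exponential) gap length in hours.
#'
#' @param n_participants cohort size.
#' @param severity_mix probabilities over none/mild/severe; must sum to 1.
#' @param dose dose number recorded in the roster (2 or 3).
#' @param circadian_mean,circadian_amplitude,participant_sd,hourly_sd,noise_sd
#'   named numeric vectors over channels (scalars are recycled).
#' @param gap_rate expected gaps per day (>= 0).
#' @param gap_length_mean_h mean gap length in hours (> 0).
#' @param reporting a `reporting_model`.
#' @param start_date first possible vaccination date (local).
#' @param seed master integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 100,
                              severity_mix = c(none = 0.55, mild = 0.35,
                                               severe = 0.10),
                              dose = 3L,
                              circadian_mean = c(heart_rate = 65, stress = 30),
                              circadian_amplitude = c(heart_rate = 4,
                                                      stress = 8),
                              participant_sd = c(heart_rate = 6, stress = 8),
                              hourly_sd = c(heart_rate = 3, stress = 7),
                              noise_sd = c(heart_rate = 5, stress = 15),
                              gap_rate = 0.3,
                              gap_length_mean_h = 2,
                              reporting = reporting_model(),
                              start_date = "2021-08-01",
                              seed = 1L) {
  stopifnot(n_participants >= 1)
  if (length(severity_mix) != 3L || any(severity_mix < 0) ||
      abs(sum(severity_mix) - 1) > 1e-8) {
    stop("severity_mix must be 3 non-negative probabilities summing to 1")
  }
  if (is.null(names(severity_mix))) names(severity_mix) <- .TIERS
  as_channel <- function(x) {
    if (length(x) == 1L) x <- c(heart_rate = unname(x), stress = unname(x))
    stopifnot(all(.CHANNELS %in% names(x)), all(x[.CHANNELS] >= 0))
    x[.CHANNELS]
  }
  if (gap_rate < 0) stop("gap_rate must be >= 0")
  stopifnot(gap_length_mean_h > 0, inherits(reporting, "reporting_model"))
  structure(list(
    n_participants = as.integer(n_participants),
    severity_mix = severity_mix[.TIERS],
    dose = as.integer(dose),
    circadian_mean = as_channel(circadian_mean),
    circadian_amplitude = as_channel(circadian_amplitude),
    participant_sd = as_channel(participant_sd),
    hourly_sd = as_channel(hourly_sd),
    noise_sd = as_channel(noise_sd),
    gap_rate = gap_rate,
    gap_length_mean_h = gap_length_mean_h,
    reporting = reporting,
    start_date = start_date,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# stable small hash of a participant id, for RNG substreams
id_hash <- function(id) {
  vapply(as.character(id), function(s) {
    h <- 0
    for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 1048573
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Generate a participant roster
#'
#' Draws demographics (age truncated-normal 50 +/- 15 within `[18, 88]`,
#' 57% female, 35% with an underlying condition), a daytime vaccination
#' timestamp within four weeks of `start_date`, and a ground-truth severity
#' label from `severity_mix`.
#'
#' @param config a `simulation_config`.
#' @return data.frame with columns participant_id, age, sex,
#'   underlying_condition, dose, vaccination_time, true_severity.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  base <- parse_timestamp(paste0(config$start_date, " 00:00:00"))
  rows <- lapply(seq_len(n), function(i) {
    with_seed(participant_seed(config$seed, i), {
      age <- round(stats::rnorm(1, 50, 15))
      age <- min(max(age, 18), 88)
      sex <- if (stats::runif(1) < 0.57) "female" else "male"
      cond <- stats::runif(1) < 0.35
      sev <- sample(.TIERS, 1, prob = config$severity_mix)
      day <- floor(stats::runif(1, 0, 28))
      hr <- floor(stats::runif(1, 8, 20))
      mn <- floor(stats::runif(1, 0, 60))
      vt <- base + day * 86400 + hr * 3600 + mn * 60
      data.frame(participant_id = sprintf("P%04d", i),
                 age = as.integer(age), sex = sex,
                 underlying_condition = cond, dose = config$dose,
                 vaccination_time = vt, true_severity = sev,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

# circadian deviation term (unit amplitude), trough at 04:00 local
circadian_term <- function(time) {
  hod <- (as.numeric(time) %% 86400) / 3600
  -cos(2 * pi * (hod - 4) / 24)
}

# participant-specific baseline level for one channel
participant_baseline <- function(participant, channel, config) {
  k <- id_hash(participant$participant_id)
  salt <- if (channel == "heart_rate") 101L else 202L
  with_seed(participant_seed(config$seed, k, salt),
            config$circadian_mean[[channel]] +
              stats::rnorm(1, 0, config$participant_sd[[channel]]))
}

#' Simulate a raw wearable stream
#'
#' Emits device-cadence samples (15 s heart rate, 3 min stress) spanning the
#' 7 days before through 14 days after the participant's vaccination. Each
#' sample is participant baseline + circadian sinusoid + severity response
#' curve + hour-level disturbance + sample noise; stress is clipped to
#' `[1, 100]`, heart rate to a 30 bpm physiological floor.
#'
#' @param participant one roster row (data.frame or list).
#' @param channel `"heart_rate"` or `"stress"`.
#' @param curve a `response_curve`; defaults to the severity-anchored curve
#'   for the participant's `true_severity`.
#' @param config a `simulation_config`.
#' @return data.frame(participant_id, channel, timestamp, value).
#' @export
simulate_stream <- function(participant, channel, curve = NULL, config) {
  if (!channel %in% .CHANNELS) stop("unknown channel: ", channel)
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(curve)) curve <- default_curve(channel, participant$true_severity)
  vt <- parse_timestamp(participant$vaccination_time)
  origin <- floor_hour(vt)
  t0 <- as.numeric(origin) - 168 * 3600
  t1 <- as.numeric(origin) + 336 * 3600
  dt <- .CADENCE_S[[channel]]
  times <- seq(t0, t1 - dt, by = dt)
  hrs_since_vax <- (times - as.numeric(vt)) / 3600
  b <- participant_baseline(participant, channel, config)
  hour_idx <- floor((times - t0) / 3600) + 1L
  n_hours <- max(hour_idx)
  k <- id_hash(participant$participant_id)
  salt <- if (channel == "heart_rate") 303L else 404L
  noise <- with_seed(participant_seed(config$seed, k, salt), {
    hn <- stats::rnorm(n_hours, 0, config$hourly_sd[[channel]])
    hn[hour_idx] + stats::rnorm(length(times), 0, config$noise_sd[[channel]])
  })
  value <- b + config$circadian_amplitude[[channel]] * circadian_term(times) +
    response_curve(curve, hrs_since_vax) + noise
  value <- if (channel == "stress") pmin(pmax(value, 1), 100)
           else pmax(value, .HR_FLOOR)
  data.frame(participant_id = participant$participant_id, channel = channel,
             timestamp = as.POSIXct(times, origin = "1970-01-01", tz = .VW_TZ),
             value = value, stringsAsFactors = FALSE)
}

#' Simulate an hourly series directly (fast path)
#'
#' Cohort-scale simulation studies do not need device-cadence streams; this
#' emits the hourly means the preprocessing stage would produce, with the
#' circadian term integrated analytically over each hour, the response
#' curve averaged at four in-hour quadrature points, the hour-level
#' disturbance at full strength and the sample noise shrunk by
#' `sqrt(samples per hour)`. Device gaps mark whole hours missing.
#'
#' @inheritParams simulate_stream
#' @param gaps logical; inject charging gaps from the config rates.
#' @return an `hourly_series` spanning hours `[-168, 336)`.
#' @export
simulate_hourly <- function(participant, channel, curve = NULL, config,
                            gaps = TRUE) {
  if (!channel %in% .CHANNELS) stop("unknown channel: ", channel)
  if (is.null(curve)) curve <- default_curve(channel, participant$true_severity)
  vt <- parse_timestamp(participant$vaccination_time)
  origin <- floor_hour(vt)
  hours <- seq(-168L, 335L)
  hstart <- as.numeric(origin) + hours * 3600
  # exact mean of the unit circadian sinusoid over [h, h+1)
  ph <- function(tt) sin(2 * pi * (((tt %% 86400) / 3600) - 4) / 24)
  circ_mean <- -(24 / (2 * pi)) * (ph(hstart + 3600) - ph(hstart))
  # response curve averaged at 4 quadrature points per hour
  q <- c(0.125, 0.375, 0.625, 0.875)
  cv <- rowMeans(vapply(q, function(f) {
    response_curve(curve, (hstart + f * 3600 - as.numeric(vt)) / 3600)
  }, numeric(length(hstart))))
  b <- participant_baseline(participant, channel, config)
  k <- id_hash(participant$participant_id)
  salt <- if (channel == "heart_rate") 303L else 404L
  nps <- 3600 / .CADENCE_S[[channel]]
  noise <- with_seed(participant_seed(config$seed, k, salt), {
    stats::rnorm(length(hours), 0, config$hourly_sd[[channel]]) +
      stats::rnorm(length(hours), 0, config$noise_sd[[channel]] / sqrt(nps))
  })
  value <- b + config$circadian_amplitude[[channel]] * circ_mean + cv + noise
  value <- if (channel == "stress") pmin(pmax(value, 1), 100)
           else pmax(value, .HR_FLOOR)
  status <- rep("observed", length(hours))
  if (gaps && config$gap_rate > 0) {
    gp <- with_seed(participant_seed(config$seed, k, 505L),
                    .draw_gaps(21, config$gap_rate, config$gap_length_mean_h))
    if (nrow(gp)) {
      gs <- (gp$start_h - 168) ; ge <- gs + gp$len_h
      for (j in seq_len(nrow(gp))) {
        hit <- which(hours + 0.5 >= gs[j] & hours + 0.5 < ge[j])
        status[hit] <- "missing"
      }
      value[status == "missing"] <- NA_real_
    }
  }
  new_hourly_series(hours, value, status,
                    participant_id = participant$participant_id,
                    channel = channel, origin = origin)
}

# draw gap windows over a span of `days`; start_h measured from span start
.draw_gaps <- function(days, gap_rate, mean_len_h) {
  n <- stats::rpois(1, gap_rate * days)
  if (n == 0) return(data.frame(start_h = numeric(0), len_h = numeric(0)))
  data.frame(start_h = stats::runif(n, 0, days * 24),
             len_h = stats::rexp(n, 1 / mean_len_h))
}

#' Remove contiguous runs of samples (device-charging gaps)
#'
#' @param samples data.frame from [simulate_stream()].
#' @param gap_rate expected gaps per day (>= 0).
#' @param gap_length_mean_h mean exponential gap length in hours.
#' @param seed integer seed.
#' @return the samples with gap runs removed.
#' @export
inject_gaps <- function(samples, gap_rate, gap_length_mean_h = 2, seed = 1L) {
  if (gap_rate < 0) stop("gap_rate must be >= 0")
  stopifnot(nrow(samples) > 0)
  if (gap_rate == 0) return(samples)
  tt <- as.numeric(samples$timestamp)
  span_days <- (max(tt) - min(tt)) / 86400
  gp <- with_seed(seed, .draw_gaps(span_days, gap_rate, gap_length_mean_h))
  if (!nrow(gp)) return(samples)
  keep <- rep(TRUE, nrow(samples))
  rel <- tt - min(tt)
  for (j in seq_len(nrow(gp))) {
    keep <- keep & !(rel >= gp$start_h[j] * 3600 &
                       rel < (gp$start_h[j] + gp$len_h[j]) * 3600)
  }
  samples[keep, , drop = FALSE]
}

#' Generate daily questionnaire entries for one participant
#'
#' One evening submission per day (days -7..+7 around vaccination) with
#' probability `compliance`; occasionally an extra morning entry on the same
#' day. Post-vaccination days 0-2 carry severity-dependent symptom
#' reporting; all days carry a small background mild-symptom rate. Severe
#' reports go through either a direct severe token or the
#' feeling-hot-plus-temperature (> 38.9 C) path.
#'
#' @param participant one roster row.
#' @param model a `reporting_model`.
#' @param seed integer seed (defaults to a participant substream).
#' @return data.frame(participant_id, timestamp, symptoms, temperature_c);
#'   `symptoms` is a semicolon-joined string, possibly empty.
#' @export
generate_questionnaires <- function(participant, model = reporting_model(),
                                    seed = NULL) {
  stopifnot(inherits(model, "reporting_model"))
  vt <- parse_timestamp(participant$vaccination_time)
  vdate <- local_date(vt)
  sev <- participant$true_severity
  if (is.null(seed)) {
    seed <- participant_seed(0L, id_hash(participant$participant_id), 606L)
  }
  with_seed(seed, {
    out <- list()
    for (d in -7:7) {
      if (stats::runif(1) > model$compliance) next
      day <- vdate + d
      syms <- character(0)
      temp <- NA_real_
      if (stats::runif(1) < model$baseline_rate) {
        syms <- c(syms, sample(mild_symptoms, 1))
      }
      if (d >= 0 && d <= 2) {
        if (stats::runif(1) < model$p_mild[[sev]]) {
          syms <- c(syms, sample(setdiff(mild_symptoms, "feeling hot"),
                                 sample(1:3, 1)))
        }
        if (stats::runif(1) < model$p_severe[[sev]]) {
          if (stats::runif(1) < model$p_fever_temp) {
            syms <- c(syms, "feeling hot")
            temp <- round(stats::runif(1, 39, 40.2), 1)
          } else {
            syms <- c(syms, sample(severe_symptoms, 1))
          }
        }
      }
      stamp <- function(hour_lo, hour_hi) {
        as.POSIXct(as.numeric(as.POSIXct(paste(day, "00:00:00"),
                                         tz = .VW_TZ)) +
                     stats::runif(1, hour_lo, hour_hi) * 3600,
                   origin = "1970-01-01", tz = .VW_TZ)
      }
      evening <- stamp(18, 23)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = participant$participant_id, timestamp = evening,
        symptoms = join_symptoms(unique(syms)), temperature_c = temp,
        stringsAsFactors = FALSE)
      if (stats::runif(1) < model$duplicate_rate) {
        # earlier same-day entry with a subset of symptoms
        sub <- syms[stats::runif(length(syms)) < 0.5]
        out[[length(out) + 1L]] <- data.frame(
          participant_id = participant$participant_id,
          timestamp = stamp(8, 12),
          symptoms = join_symptoms(unique(sub)), temperature_c = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      return(data.frame(participant_id = character(0),
                        timestamp = as.POSIXct(character(0), tz = .VW_TZ),
                        symptoms = character(0), temperature_c = numeric(0)))
    }
    res <- do.call(rbind, out)
    res[order(res$timestamp), , drop = FALSE]
  })
}

#' Simulate a full cohort
#'
#' @param config a `simulation_config`.
#' @param hourly logical; if `TRUE` (the fast path for simulation studies)
#'   wearable data is generated directly as hourly series, otherwise as raw
#'   device-cadence samples with injected gaps.
#' @param channels channels to simulate.
#' @return list with `roster`, `questionnaires`, and either `hourly` (a list
#'   of `hourly_series`) or `wearable` (a samples data.frame).
#' @export
simulate_cohort <- function(config, hourly = TRUE,
                            channels = .CHANNELS) {
  roster <- generate_cohort(config)
  qs <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    generate_questionnaires(
      p, config$reporting,
      seed = participant_seed(config$seed, id_hash(p$participant_id), 606L))
  }))
  out <- list(roster = roster, questionnaires = qs)
  if (hourly) {
    series <- list()
    for (i in seq_len(nrow(roster))) {
      p <- roster[i, ]
      for (ch in channels) {
        series[[paste(p$participant_id, ch, sep = ".")]] <-
          simulate_hourly(p, ch, config = config)
      }
    }
    out$hourly <- series
  } else {
    wear <- list()
    for (i in seq_len(nrow(roster))) {
      p <- roster[i, ]
      for (ch in channels) {
        s <- simulate_stream(p, ch, config = config)
        if (config$gap_rate > 0) {
          s <- inject_gaps(s, config$gap_rate, config$gap_length_mean_h,
                           seed = participant_seed(
                             config$seed, id_hash(p$participant_id), 505L))
        }
        wear[[length(wear) + 1L]] <- s
      }
    }
    out$wearable <- do.call(rbind, wear)
  }
  out
}

#' Write a simulated cohort to the canonical CSV schemas
#'
#' Writes `roster.csv`, `wearable.csv` and `questionnaire.csv` (the
#' pipeline's input schemas) into `dir`.
#'
#' @param sim result of [simulate_cohort()] with `hourly = FALSE`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_simulation <- function(sim, dir) {
  if (is.null(sim$wearable)) {
    stop("write_simulation needs a raw-cadence cohort ",
         "(simulate_cohort(..., hourly = FALSE))")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roster <- sim$roster
  roster$vaccination_time <- format_timestamp(roster$vaccination_time)
  roster$underlying_condition <- tolower(roster$underlying_condition)
  wear <- sim$wearable
  wear$timestamp <- format_timestamp(wear$timestamp)
  qs <- sim$questionnaires
  qs$timestamp <- format_timestamp(qs$timestamp)
  paths <- file.path(dir, c("roster.csv", "wearable.csv",
                            "questionnaire.csv"))
  utils::write.csv(roster, paths[1], row.names = FALSE)
  data.table::fwrite(data.table::as.data.table(wear), paths[2])
  utils::write.csv(qs, paths[3], row.names = FALSE)
  invisible(paths)
}
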
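# Post-vaccination response curve: a smooth pulse that is exactly zero at
# and before the vaccination instant, rises to `peak_elevation` at
# `peak_time` hours, decays towards zero, and may carry a delayed negative
# undershoot (seen in the stress channel of severe reactors, which dips
# below baseline before recovering). The pulse is log-normal-shaped in
# time: exp(-(log(t / peak_time))^2 / (2 s^2)) with separate log-widths on
# the rising and decaying side, parameterised by half-height times.

#' Response-curve parameters
#'
#' Construct the parameter set of a post-vaccination elevation curve for one
#' channel/severity combination.
#'
#' @param peak_elevation maximum elevation above baseline, in channel units
#'   (beats/min for heart rate, points for the 1-100 stress index).
#' @param peak_time hours after vaccination at which the elevation peaks
#'   (default 24, matching the observed peak near one day post-dose).
#' @param rise_time hours before the peak at which the curve is at half
#'   height; must be positive and less than `peak_time`.
#' @param decay_time hours after the peak at which the curve is back to half
#'   height.
#' @param undershoot_depth depth (positive number, channel units) of an
#'   optional delayed below-baseline phase; 0 disables it.
#' @param undershoot_recovery hours after `peak_time` at which the
#'   undershoot is deepest.
#' @return object of class `response_curve`.
#' @export
response_curve_params <- function(peak_elevation,
                                  peak_time = 24,
                                  rise_time = 12,
                                  decay_time = 24,
                                  undershoot_depth = 0,
                                  undershoot_recovery = 120) {
  stopifnot(peak_time > 0, rise_time > 0, rise_time < peak_time,
            decay_time > 0, undershoot_depth >= 0, undershoot_recovery > 0)
  structure(list(peak_elevation = peak_elevation, peak_time = peak_time,
                 rise_time = rise_time, decay_time = decay_time,
                 undershoot_depth = undershoot_depth,
                 undershoot_recovery = undershoot_recovery),
            class = "response_curve")
}

# log-width such that the pulse is at half height at time `t_half`
.log_half_width <- function(t_half, t_peak) {
  abs(log(t_half / t_peak)) / sqrt(2 * log(2))
}

#' Evaluate a response curve
#'
#' @param params a `response_curve` object.
#' @param t hours since vaccination (vectorised); values at `t <= 0` give 0.
#' @return numeric vector of elevations in channel units.
#' @export
response_curve <- function(params, t) {
  stopifnot(inherits(params, "response_curve"))
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- params$peak_time
  tt <- t[pos]
  s_rise <- .log_half_width(tp - params$rise_time, tp)
  s_decay <- .log_half_width(tp + params$decay_time, tp)
  s <- ifelse(tt < tp, s_rise, s_decay)
  main <- params$peak_elevation * exp(-(log(tt / tp))^2 / (2 * s^2))
  if (params$undershoot_depth > 0) {
    tu <- tp + params$undershoot_recovery
    su <- 0.35  # fixed log-scale width of the undershoot pulse
    main <- main - params$undershoot_depth *
      exp(-(log(tt / tu))^2 / (2 * su^2))
  }
  out[pos] <- main
  out
}

#' Default severity-anchored response curves
#'
#' Peak elevations default to 2.8/5/9 beats per minute (heart rate) and
#' 6/10/21 points (stress) for none/mild/severe reactors, anchoring the
#' generator to the magnitudes reported for third-dose cohorts. The severe
#' stress curve carries an undershoot so the simulated cohort dips below
#' baseline before recovering around day 11.
#'
#' @param channel `"heart_rate"` or `"stress"`.
#' @param severity `"none"`, `"mild"` or `"severe"`.
#' @return a `response_curve` object.
#' @export
default_curve <- function(channel = c("heart_rate", "stress"),
                          severity = c("none", "mild", "severe")) {
  channel <- match.arg(channel)
  severity <- match.arg(severity)
  peaks <- list(heart_rate = c(none = 2.8, mild = 5, severe = 9),
                stress     = c(none = 6, mild = 10, severe = 21))
  depth <- if (channel == "stress" && severity == "severe") 4 else 0
  response_curve_params(peak_elevation = unname(peaks[[channel]][severity]),
                        undershoot_depth = depth)
}
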
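# Cohort-level statistics on baseline-matched differences: hourly mean
# curves with t-based 95% CIs across participants, 72 h window means by
# severity stratum, Welch's two-sided t-test between strata, and peak /
# return-to-baseline summaries.

#' Stack matched-difference series into a long table
#'
#' @param diffs list of `matched_diff` objects.
#' @return data.frame(participant_id, channel, hour, diff).
#' @export
stack_diffs <- function(diffs) {
  rows <- lapply(diffs, function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(participant_id = attr(d, "participant_id"),
               channel = attr(d, "channel"), hour = d$hour, diff = d$diff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), channel = character(0),
                      hour = integer(0), diff = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Hourly cohort mean-difference curve
#'
#' Per hour offset, the mean matched difference over the participants with a
#' value at that hour, with a t-distribution 95% CI across participants
#' (hours with fewer than two contributors carry no CI).
#'
#' @param diffs long diff table from [stack_diffs()] (one channel), already
#'   restricted to included participants.
#' @param level confidence level.
#' @return data.frame(hour, mean_diff, ci_low, ci_high, n) of class
#'   `cohort_curve`.
#' @export
cohort_curve <- function(diffs, level = 0.95) {
  if (!nrow(diffs)) {
    message("cohort_curve: empty stratum")
    return(structure(data.frame(hour = integer(0), mean_diff = numeric(0),
                                ci_low = numeric(0), ci_high = numeric(0),
                                n = integer(0)),
                     class = c("cohort_curve", "data.frame")))
  }
  dt <- data.table::as.data.table(diffs)
  agg <- dt[, list(mean_diff = mean(diff), sd = stats::sd(diff),
                   n = .N), by = "hour"]
  data.table::setorderv(agg, "hour")
  a <- (1 - level) / 2
  half <- rep(NA_real_, nrow(agg))
  ok <- agg$n >= 2
  half[ok] <- stats::qt(1 - a, agg$n[ok] - 1) * agg$sd[ok] / sqrt(agg$n[ok])
  structure(data.frame(hour = agg$hour, mean_diff = agg$mean_diff,
                       ci_low = agg$mean_diff - half,
                       ci_high = agg$mean_diff + half, n = agg$n),
            class = c("cohort_curve", "data.frame"))
}

#' Per-participant 72 h window means and group summary
#'
#' Each participant's value is the mean of their available hourly matched
#' differences over `window` (default the first 72 h post-vaccination); the
#' group mean and t-based CI are computed over those per-participant values.
#'
#' @param diffs long diff table (one channel, one stratum).
#' @param window half-open hour window, default `c(0, 72)`.
#' @param level confidence level.
#' @return list of class `window_summary`: per_participant (data.frame),
#'   mean, ci_low, ci_high, n.
#' @export
window_mean <- function(diffs, window = c(0, 72), level = 0.95) {
  sub <- diffs[diffs$hour >= window[1] & diffs$hour < window[2], ,
               drop = FALSE]
  if (!nrow(sub)) stop("no participants with data in the window")
  dt <- data.table::as.data.table(sub)
  per <- dt[, list(value = mean(diff), n_hours = .N), by = "participant_id"]
  v <- per$value
  n <- length(v)
  a <- (1 - level) / 2
  half <- if (n >= 2) stats::qt(1 - a, n - 1) * stats::sd(v) / sqrt(n)
          else NA_real_
  structure(list(per_participant = as.data.frame(per), mean = mean(v),
                 ci_low = mean(v) - half, ci_high = mean(v) + half, n = n),
            class = "window_summary")
}

#' Welch's two-sample t-test
#'
#' Two-sided location test that does not assume equal variances:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom. When both variances are zero the
#' statistic is degenerate; equal means return p = 1 by convention and
#' unequal means are an error.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list of class `welch_test`: t, df, p, mean_a, mean_b.
#' @export
welch_test <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  ma <- mean(values_a); mb <- mean(values_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(structure(list(t = 0, df = na + nb - 2, p = 1,
                            mean_a = ma, mean_b = mb), class = "welch_test"))
    }
    stop("both groups degenerate (zero variance) with unequal means")
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_a = ma, mean_b = mb),
            class = "welch_test")
}

#' Peak and return-to-baseline of a cohort curve
#'
#' The peak is the argmax of the mean difference over the first 72 h; the
#' return hour is the first hour after the peak from which the hourly 95%
#' CI contains zero for at least 24 consecutive hours (0 if the curve's CI
#' contains zero from hour 0 and never leaves, i.e. there is nothing to
#' return from).
#'
#' @param curve a `cohort_curve` over `[0, 336)`.
#' @param sustain_h consecutive CI-contains-zero hours required (default 24).
#' @return list(peak_hour, peak_value, return_hour); `return_hour` is NA if
#'   the curve never settles.
#' @export
peak_and_return <- function(curve, sustain_h = 24L) {
  if (!nrow(curve)) stop("empty curve")
  in72 <- curve[curve$hour >= 0 & curve$hour < 72, , drop = FALSE]
  if (!nrow(in72)) stop("curve has no hours in [0, 72)")
  pk <- in72[which.max(in72$mean_diff), ]
  after <- curve[curve$hour >= pk$hour, , drop = FALSE]
  covers <- !is.na(after$ci_low) & after$ci_low <= 0 & after$ci_high >= 0
  ret <- NA_integer_
  run <- 0L
  for (i in seq_along(covers)) {
    run <- if (covers[i]) run + 1L else 0L
    if (run >= sustain_h) {
      ret <- after$hour[i - run + 1L]
      break
    }
  }
  list(peak_hour = pk$hour, peak_value = pk$mean_diff, return_hour = ret)
}

#' Stratified difference analysis
#'
#' Cohort curves, 72 h window summaries, peak/return summaries per severity
#' stratum (plus "all"), and pairwise Welch tests on the per-participant
#' window means.
#'
#' @param diffs long diff table for one channel.
#' @param tiers data.frame(participant_id, tier).
#' @param level confidence level.
#' @return list with `curves`, `windows`, `peaks` (named by stratum) and
#'   `tests` (data.frame group_a, group_b, t, df, p).
#' @export
stratified_differences <- function(diffs, tiers, level = 0.95) {
  m <- merge(diffs, tiers[, c("participant_id", "tier")],
             by = "participant_id")
  m <- m[!is.na(m$tier), , drop = FALSE]
  strata <- c(list(all = m), split(m, m$tier))
  curves <- lapply(strata, cohort_curve, level = level)
  windows <- lapply(strata, function(d) {
    if (!nrow(d)) return(NULL)
    window_mean(d, level = level)
  })
  peaks <- lapply(curves, function(cv) {
    if (!nrow(cv)) return(NULL)
    peak_and_return(cv)
  })
  pres <- .TIERS[.TIERS %in% names(windows)]
  tests <- list()
  if (length(pres) >= 2) {
    for (i in seq_len(length(pres) - 1L)) {
      for (j in seq((i + 1L), length(pres))) {
        a <- windows[[pres[i]]]; b <- windows[[pres[j]]]
        if (is.null(a) || is.null(b) || a$n < 2 || b$n < 2) next
        wt <- welch_test(a$per_participant$value, b$per_participant$value)
        tests[[length(tests) + 1L]] <- data.frame(
          group_a = pres[i], group_b = pres[j], t = wt$t, df = wt$df,
          p = wt$p, stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = curves, windows = windows, peaks = peaks,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(group_a = character(0), group_b = character(0),
                    t = numeric(0), df = numeric(0), p = numeric(0)))
}
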
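# Wearable preprocessing: interpolate short gaps, smooth with a centred
# 5-hour moving average, and form per-participant baseline-matched
# differences (post hour h vs the baseline hour one/two weeks earlier with
# the same day-of-week and hour-of-day). Pipeline order is fixed:
# hourly_average -> interpolate_gaps -> moving_average -> match_baseline.

#' Linearly interpolate short gaps
#'
#' Missing runs of 1-4 consecutive hours bounded on both sides by observed
#' cells are filled on the straight line between the bounding values and
#' marked `interpolated`. Runs of 5 or more hours, and runs touching either
#' end of the series, stay missing (participants are excluded from analysis
#' during those hours).
#'
#' @param series an `hourly_series`.
#' @param max_gap longest run length that is filled (default 4, i.e.
#'   strictly fewer than 5 missing hours).
#' @return an `hourly_series` with short gaps filled.
#' @export
interpolate_gaps <- function(series, max_gap = 4L) {
  stopifnot(inherits(series, "hourly_series"))
  v <- series$value; s <- series$status
  miss <- s == "missing"
  if (!any(miss)) return(series)
  r <- rle(miss)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    len <- r$lengths[j]
    if (len > max_gap) next
    a <- starts[j] - 1L; b <- ends[j] + 1L
    if (a < 1L || b > length(v)) next       # run touches a series edge
    if (is.na(v[a]) || is.na(v[b])) next
    w <- seq_len(len) / (len + 1)
    v[starts[j]:ends[j]] <- v[a] * (1 - w) + v[b] * w
    s[starts[j]:ends[j]] <- "interpolated"
  }
  new_hourly_series(series$hour, v, s, attr(series, "participant_id"),
                    attr(series, "channel"), attr(series, "origin"))
}

#' Centred moving average
#'
#' Each non-missing cell is replaced by the mean of the centred
#' `window`-cell neighbourhood (h-2 .. h+2 for the default 5), taken over
#' the non-missing cells available in the window; edge cells use the
#' available subset. Missing cells stay missing: smoothing never
#' reintroduces values into excluded hours.
#'
#' @param series an `hourly_series` (gaps already interpolated).
#' @param window odd window width in hours (default 5).
#' @return a smoothed `hourly_series`.
#' @export
moving_average <- function(series, window = 5L) {
  stopifnot(inherits(series, "hourly_series"))
  if (window %% 2L == 0L) stop("moving-average window must be odd")
  half <- (window - 1L) %/% 2L
  v <- series$value
  n <- length(v)
  ok <- !is.na(v)
  vz <- ifelse(ok, v, 0)
  # windowed sums via padded cumulative sums
  cs <- cumsum(c(0, vz)); cn <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  sums <- cs[hi + 1L] - cs[lo]
  cnts <- cn[hi + 1L] - cn[lo]
  out <- ifelse(ok & cnts > 0, sums / cnts, NA_real_)
  new_hourly_series(series$hour, out, ifelse(ok, series$status, "missing"),
                    attr(series, "participant_id"), attr(series, "channel"),
                    attr(series, "origin"))
}

#' Baseline-matched difference series
#'
#' Matches each post-vaccination hour offset `h` in `[0, 336)` to the
#' baseline hour `(h mod 168) - 168`: the identical day-of-week and
#' hour-of-day one (or, in the second post week, two) weeks earlier, since
#' the baseline window is exactly one week. The difference `post - baseline`
#' is defined only where both matched cells are non-missing.
#'
#' @param post an `hourly_series` over `[0, 336)` (windowed if wider).
#' @param baseline an `hourly_series` over exactly `[-168, 0)`.
#' @return object of class `matched_diff`: data.frame(hour, diff) with
#'   participant/channel attributes.
#' @export
match_baseline <- function(post, baseline) {
  stopifnot(inherits(post, "hourly_series"),
            inherits(baseline, "hourly_series"))
  if (!identical(attr(post, "channel"), attr(baseline, "channel"))) {
    stop("post and baseline series must share a channel")
  }
  if (min(baseline$hour) != -168L || max(baseline$hour) != -1L) {
    stop("baseline window must be exactly the 168 hours [-168, 0)")
  }
  post <- window_series(post, 0L, 336L)
  bl_val <- baseline$value
  bl_ok <- baseline$status != "missing"
  h <- post$hour
  bidx <- (h %% 168L) + 1L               # baseline hour (h mod 168) - 168
  ok <- post$status != "missing" & bl_ok[bidx]
  structure(data.frame(hour = h[ok],
                       diff = post$value[ok] - bl_val[bidx][ok]),
            participant_id = attr(post, "participant_id"),
            channel = attr(post, "channel"),
            class = c("matched_diff", "data.frame"))
}

#' Run the full preprocessing chain for one participant/channel
#'
#' @param series an `hourly_series` over `[-168, 336)` (e.g. from
#'   [hourly_average()] or [simulate_hourly()]).
#' @param smooth logical; apply the 5 h moving average (the panel stage uses
#'   interpolated but unsmoothed data).
#' @return list with `interpolated`, `smoothed` (or NULL) and `diffs`.
#' @export
preprocess_series <- function(series, smooth = TRUE) {
  interp <- interpolate_gaps(series)
  sm <- if (smooth) moving_average(interp) else NULL
  use <- if (smooth) sm else interp
  diffs <- match_baseline(window_series(use, 0L, 336L),
                          window_series(use, -168L, 0L))
  list(interpolated = interp, smoothed = sm, diffs = diffs)
}

#' Preprocess a raw wearable table for a whole cohort
#'
#' Splits the samples by participant and channel, bins them into hourly
#' series anchored at each participant's vaccination hour, and runs the
#' fixed chain interpolate -> smooth -> match.
#'
#' @param wearable data.frame(participant_id, channel, timestamp, value).
#' @param roster roster data.frame with `vaccination_time`.
#' @return list of per-participant/channel results as in
#'   [preprocess_series()], plus the raw hourly series, named
#'   `"<participant_id>.<channel>"`.
#' @export
preprocess_wearable <- function(wearable, roster) {
  wearable$timestamp <- parse_timestamp(wearable$timestamp)
  vt <- stats::setNames(parse_timestamp(roster$vaccination_time),
                        roster$participant_id)
  out <- list()
  sp <- split(wearable,
              list(wearable$participant_id, wearable$channel), drop = TRUE)
  for (chunk in sp) {
    pid <- chunk$participant_id[1]
    if (!pid %in% names(vt)) next
    hs <- hourly_average(chunk, vt[[pid]])
    res <- preprocess_series(hs)
    res$hourly <- hs
    out[[paste(pid, chunk$channel[1], sep = ".")]] <- res
  }
  out
}

#' Flatten preprocessing results to the hourly/diff CSV schemas
#'
#' @param prep result of [preprocess_wearable()] (or a list of
#'   `preprocess_series()` results named `"<id>.<channel>"`).
#' @return list of two data.frames: `hourly` (participant_id, channel,
#'   hour_offset, value, status; the interpolated, unsmoothed variant) and
#'   `diffs` (participant_id, channel, hour_offset, diff).
#' @export
preprocessed_tables <- function(prep) {
  hl <- lapply(prep, function(r) {
    s <- r$interpolated
    data.frame(participant_id = attr(s, "participant_id"),
               channel = attr(s, "channel"), hour_offset = s$hour,
               value = s$value, status = s$status, stringsAsFactors = FALSE)
  })
  dl <- lapply(prep, function(r) {
    d <- r$diffs
    if (!nrow(d)) return(NULL)
    data.frame(participant_id = attr(d, "participant_id"),
               channel = attr(d, "channel"), hour_offset = d$hour,
               diff = d$diff, stringsAsFactors = FALSE)
  })
  list(hourly = do.call(rbind, c(hl, list(make.row.names = FALSE))),
       diffs = do.call(rbind, c(dl, list(make.row.names = FALSE))))
}
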
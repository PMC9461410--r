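# HourlySeries: one participant/channel, a contiguous grid of wall-clock
# hours indexed by integer offset from the hour containing the vaccination
# timestamp. Cell status is "observed" (mean of in-hour samples),
# "interpolated" (filled short gap) or "missing".

.STATUS <- c("observed", "interpolated", "missing")

#' Construct an hourly series
#'
#' @param hour integer hour offsets (need not be contiguous; the grid is
#'   completed with missing cells).
#' @param value numeric values (NA where missing).
#' @param status character statuses; defaults to observed/missing by NA-ness.
#' @param participant_id,channel identifiers.
#' @param origin POSIXct hour boundary the offsets are relative to.
#' @return object of class `hourly_series`: a data.frame(hour, value,
#'   status) with attributes.
#' @export
new_hourly_series <- function(hour, value, status = NULL,
                              participant_id = NA_character_,
                              channel = NA_character_, origin = NULL) {
  hour <- as.integer(hour)
  stopifnot(!anyDuplicated(hour), length(hour) == length(value))
  if (is.null(status)) status <- ifelse(is.na(value), "missing", "observed")
  stopifnot(all(status %in% .STATUS))
  o <- order(hour)
  hour <- hour[o]; value <- as.numeric(value)[o]; status <- status[o]
  full <- seq(min(hour), max(hour))
  if (length(full) != length(hour)) {
    v <- rep(NA_real_, length(full)); s <- rep("missing", length(full))
    idx <- match(hour, full)
    v[idx] <- value; s[idx] <- status
    hour <- full; value <- v; status <- s
  }
  value[status == "missing"] <- NA_real_
  structure(data.frame(hour = hour, value = value, status = status,
                       stringsAsFactors = FALSE),
            participant_id = participant_id, channel = channel,
            origin = origin, class = c("hourly_series", "data.frame"))
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series> %s / %s, hours [%d, %d], %d observed, %d interpolated, %d missing\n",
              attr(x, "participant_id"), attr(x, "channel"),
              min(x$hour), max(x$hour),
              sum(x$status == "observed"), sum(x$status == "interpolated"),
              sum(x$status == "missing")))
  invisible(x)
}

# restrict a series to hour offsets in [lo, hi)
#' Restrict an hourly series to a window of hour offsets
#' @param series an `hourly_series`.
#' @param lo,hi half-open window bounds `[lo, hi)` in hour offsets.
#' @return the restricted `hourly_series` (grid completed with missing
#'   cells if the series does not span the window).
#' @export
window_series <- function(series, lo, hi) {
  stopifnot(inherits(series, "hourly_series"), lo < hi)
  keep <- series$hour >= lo & series$hour < hi
  h <- seq(as.integer(lo), as.integer(hi) - 1L)
  v <- rep(NA_real_, length(h)); s <- rep("missing", length(h))
  idx <- match(series$hour[keep], h)
  v[idx] <- series$value[keep]; s[idx] <- series$status[keep]
  new_hourly_series(h, v, s, attr(series, "participant_id"),
                    attr(series, "channel"), attr(series, "origin"))
}

#' Compute hourly averages of a raw wearable stream
#'
#' Samples are binned into wall-clock hours (not vaccination-anchored
#' offsets, because downstream baseline matching is calendar-based); each
#' hour with at least one sample becomes an observed cell holding the
#' unweighted mean, hours with none are missing. The hour-offset index is
#' relative to the hour containing `origin`.
#'
#' @param samples data.frame(participant_id, channel, timestamp, value) for
#'   one participant and one channel.
#' @param origin vaccination timestamp (any instant; flooring to the hour is
#'   done here).
#' @param range integer window `[lo, hi)` of hour offsets retained
#'   (default the full baseline-through-post span `[-168, 336)`).
#' @return an `hourly_series`.
#' @export
hourly_average <- function(samples, origin, range = c(-168L, 336L)) {
  stopifnot(nrow(samples) > 0)
  if (length(unique(samples$channel)) > 1L) {
    stop("hourly_average expects a single channel, got: ",
         paste(unique(samples$channel), collapse = ", "))
  }
  if (length(unique(samples$participant_id)) > 1L) {
    stop("hourly_average expects a single participant")
  }
  org <- floor_hour(parse_timestamp(origin))
  off <- hour_offset(parse_timestamp(samples$timestamp), org)
  keep <- off >= range[1] & off < range[2]
  means <- tapply(samples$value[keep], off[keep], mean)
  h <- seq(as.integer(range[1]), as.integer(range[2]) - 1L)
  v <- rep(NA_real_, length(h))
  if (length(means)) v[match(as.integer(names(means)), h)] <- as.numeric(means)
  new_hourly_series(h, v, participant_id = samples$participant_id[1],
                    channel = samples$channel[1], origin = org)
}
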
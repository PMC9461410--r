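# Cohort inclusion rules: at least one baseline questionnaire, at least one
# questionnaire within 72 h post-vaccination, and wearable data at matching
# day-of-week/hour-of-day cells in both periods. A participant whose
# wearable data covers only one calendar day in a period is excluded unless
# that single day is calendar-matched in the other period (in which case a
# matched cell pair exists and the carve-out applies).

.INCLUSION_REASONS <- c("no_baseline_questionnaire", "no_post72_questionnaire",
                        "no_matched_wearable", "single_day_only")

#' Apply the inclusion criteria to one participant and dose
#'
#' @param participant one roster row.
#' @param questionnaires this participant's (deduplicated) entries.
#' @param series an `hourly_series` over `[-168, 336)` (after
#'   interpolation), or a list of them (one per channel: any channel
#'   satisfying the wearable criterion suffices).
#' @return list of class `inclusion_decision`: participant_id, dose,
#'   included, reasons (character vector of codes).
#' @export
apply_inclusion <- function(participant, questionnaires, series) {
  vt <- parse_timestamp(participant$vaccination_time)
  reasons <- character(0)
  ts <- if (nrow(questionnaires)) parse_timestamp(questionnaires$timestamp)
        else as.POSIXct(numeric(0), origin = "1970-01-01", tz = .VW_TZ)
  if (!any(ts >= vt - 7 * 86400 & ts < vt)) {
    reasons <- c(reasons, "no_baseline_questionnaire")
  }
  if (!any(ts >= vt & ts <= vt + 72 * 3600)) {
    reasons <- c(reasons, "no_post72_questionnaire")
  }
  if (inherits(series, "hourly_series")) series <- list(series)
  matched <- FALSE
  single_day <- FALSE
  for (s in series) {
    base <- window_series(s, -168L, 0L)
    post <- window_series(s, 0L, 336L)
    b_ok <- base$status != "missing"
    p_ok <- post$status != "missing"
    if (any(p_ok & b_ok[(post$hour %% 168L) + 1L])) matched <- TRUE
    # calendar dates with any non-missing cell, per period
    org <- attr(s, "origin")
    dates_of <- function(w, ok) {
      unique(local_date(org + w$hour[ok] * 3600))
    }
    if (length(dates_of(base, b_ok)) == 1L ||
        length(dates_of(post, p_ok)) == 1L) single_day <- TRUE
  }
  if (!matched) {
    reasons <- c(reasons, "no_matched_wearable")
    if (single_day) reasons <- c(reasons, "single_day_only")
  }
  structure(list(participant_id = participant$participant_id,
                 dose = participant$dose, included = length(reasons) == 0L,
                 reasons = reasons),
            class = "inclusion_decision")
}

#' Apply inclusion to a whole cohort
#'
#' @param roster roster data.frame.
#' @param questionnaires cohort questionnaire data.frame (deduplication is
#'   applied per participant here).
#' @param prep preprocessing results from [preprocess_wearable()] (or any
#'   list of `preprocess_series()` results named `"<id>.<channel>"`).
#' @return data.frame(participant_id, dose, included, reasons) with reasons
#'   pipe-joined.
#' @export
cohort_inclusion <- function(roster, questionnaires, prep) {
  questionnaires$timestamp <- parse_timestamp(questionnaires$timestamp)
  qs <- split(questionnaires, questionnaires$participant_id)
  keys <- names(prep)
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    q <- qs[[p$participant_id]]
    if (is.null(q)) q <- questionnaires[0, , drop = FALSE]
    else q <- dedupe_daily(q)
    mine <- prep[grep(paste0("^", p$participant_id, "\\."), keys)]
    series <- lapply(mine, function(r) r$interpolated)
    if (!length(series)) {
      dec <- list(participant_id = p$participant_id, dose = p$dose,
                  included = FALSE, reasons = "no_matched_wearable")
    } else {
      dec <- apply_inclusion(p, q, series)
    }
    data.frame(participant_id = dec$participant_id, dose = dec$dose,
               included = dec$included,
               reasons = paste(dec$reasons, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
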
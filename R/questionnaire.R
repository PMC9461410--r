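# Questionnaire analysis: last-entry-per-day deduplication, symptom and
# participant severity tiering with baseline subtraction, beta-distribution
# proportion intervals, and stratified tier cross-tabulations.

#' Keep only the last questionnaire entry per calendar day
#'
#' Multiple same-day submissions are resolved by keeping the entry with the
#' latest timestamp on each local calendar date (later entries are taken to
#' reflect the whole day; submissions cannot be edited, only resubmitted).
#'
#' @param entries data.frame(participant_id, timestamp, symptoms,
#'   temperature_c) for a single participant.
#' @return the deduplicated entries, ordered by timestamp.
#' @export
dedupe_daily <- function(entries) {
  if (!nrow(entries)) return(entries)
  if (length(unique(entries$participant_id)) > 1L) {
    stop("dedupe_daily expects entries for a single participant")
  }
  ts <- parse_timestamp(entries$timestamp)
  day <- local_date(ts)
  keep <- unlist(lapply(split(seq_along(ts), day),
                        function(ix) ix[which.max(as.numeric(ts[ix]))]),
                 use.names = FALSE)
  out <- entries[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one symptom as mild or severe
#'
#' Membership lookup in the mild/severe vocabularies, with one special
#' case: "feeling hot" escalates to severe (fever) only when a recorded
#' temperature strictly exceeds 38.9 C; with no recorded temperature, or a
#' temperature at or below 38.9 C, it stays mild. Free-text tokens outside
#' the vocabulary raise an error naming the token (callers that tolerate
#' free text filter first).
#'
#' @param symptom symptom token (case-insensitive).
#' @param temperature_c optional recorded body temperature in C.
#' @return `"mild"` or `"severe"`.
#' @export
classify_symptom <- function(symptom, temperature_c = NA_real_) {
  s <- tolower(trimws(symptom))
  if (s == "feeling hot") {
    if (!is.na(temperature_c) && temperature_c > .FEVER_THRESHOLD_C) {
      return("severe")
    }
    return("mild")
  }
  if (s %in% severe_symptoms) return("severe")
  if (s %in% mild_symptoms) return("mild")
  stop("unknown symptom token: '", symptom, "'")
}

#' Classify a participant's reaction severity for one dose
#'
#' Symptoms present in the baseline entry (the last questionnaire of the
#' 7-day pre-vaccination period) are assumed pre-existing and removed from
#' every post-vaccination entry; the tier is then the maximum severity of
#' the remaining symptoms over all deduplicated entries within 72 h of
#' vaccination. One severe symptom on a single day dominates mild symptoms
#' on every day. Out-of-vocabulary (free-text) symptoms are dropped with a
#' warning. No remaining symptoms gives `"none"`.
#'
#' @param post_entries deduplicated entries within 72 h after vaccination.
#' @param baseline_entry a single entry (data.frame row or list) or NULL;
#'   must exist for included participants.
#' @return `"none"`, `"mild"` or `"severe"`.
#' @export
classify_reaction <- function(post_entries, baseline_entry) {
  if (is.null(baseline_entry) || (is.data.frame(baseline_entry) &&
                                  nrow(baseline_entry) == 0L)) {
    stop("baseline entry required (participant should have been excluded)")
  }
  if (!nrow(post_entries)) {
    stop("no post-vaccination entries (participant should have been excluded)")
  }
  base_syms <- split_symptoms(if (is.data.frame(baseline_entry)) {
    baseline_entry$symptoms[1]
  } else baseline_entry$symptoms)
  tier <- "none"
  for (i in seq_len(nrow(post_entries))) {
    syms <- setdiff(split_symptoms(post_entries$symptoms[i]), base_syms)
    for (s in syms) {
      if (!s %in% all_symptoms) {
        warning("ignoring free-text symptom with no severity mapping: '",
                s, "'")
        next
      }
      cls <- classify_symptom(s, post_entries$temperature_c[i])
      if (tier_rank(cls) > tier_rank(tier)) tier <- cls
    }
    if (tier == "severe") break
  }
  tier
}

#' Tier every participant in a cohort
#'
#' Applies deduplication, the baseline-entry rule and [classify_reaction()]
#' per participant. Participants failing the questionnaire inclusion
#' criteria get tier `NA`.
#'
#' @param roster roster data.frame.
#' @param questionnaires questionnaire data.frame for the whole cohort.
#' @return data.frame(participant_id, dose, tier).
#' @export
tier_cohort <- function(roster, questionnaires) {
  questionnaires$timestamp <- parse_timestamp(questionnaires$timestamp)
  qs <- split(questionnaires, questionnaires$participant_id)
  tiers <- vapply(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    q <- qs[[p$participant_id]]
    if (is.null(q)) return(NA_character_)
    q <- dedupe_daily(q)
    vt <- parse_timestamp(p$vaccination_time)
    base <- q[q$timestamp >= vt - 7 * 86400 & q$timestamp < vt, , drop = FALSE]
    post <- q[q$timestamp >= vt & q$timestamp <= vt + 72 * 3600, ,
              drop = FALSE]
    if (!nrow(base) || !nrow(post)) return(NA_character_)
    classify_reaction(post, base[nrow(base), ])
  }, character(1))
  data.frame(participant_id = roster$participant_id, dose = roster$dose,
             tier = tiers, stringsAsFactors = FALSE)
}

#' Proportion with a beta-distribution confidence interval
#'
#' The interval for a reporting proportion k/n is taken from
#' Beta(alpha = k, beta = n - k) at the (1-level)/2 and 1-(1-level)/2
#' quantiles. The degenerate cases k = 0 and k = n (where one Beta
#' parameter would be 0) collapse to the one-sided limits `[0, 0]` and
#' `[1, 1]`.
#'
#' @param k number of participants reporting.
#' @param n cohort size (>= 1).
#' @param level confidence level (default 0.95).
#' @return list of class `proportion_estimate`: k, n, proportion, ci_low,
#'   ci_high.
#' @export
symptom_proportion <- function(k, n, level = 0.95) {
  if (k > n) stop("k must not exceed n")
  stopifnot(k >= 0, n >= 1, level > 0, level < 1)
  a <- (1 - level) / 2
  ci <- if (k == 0) c(0, 0) else if (k == n) c(1, 1) else {
    stats::qbeta(c(a, 1 - a), k, n - k)
  }
  structure(list(k = as.integer(k), n = as.integer(n), proportion = k / n,
                 ci_low = ci[1], ci_high = ci[2], level = level),
            class = "proportion_estimate")
}

#' Per-symptom reporting proportions for a cohort
#'
#' @param roster roster data.frame.
#' @param questionnaires questionnaire data.frame.
#' @param window_h reporting window after vaccination in hours (default 72).
#' @return data.frame(symptom, k, n, proportion, ci_low, ci_high).
#' @export
symptom_proportions <- function(roster, questionnaires, window_h = 72) {
  questionnaires$timestamp <- parse_timestamp(questionnaires$timestamp)
  n <- nrow(roster)
  vt <- stats::setNames(parse_timestamp(roster$vaccination_time),
                        roster$participant_id)
  reported <- new.env()
  qs <- questionnaires[questionnaires$participant_id %in% names(vt), ]
  for (i in seq_len(nrow(qs))) {
    pid <- qs$participant_id[i]
    dt <- as.numeric(qs$timestamp[i]) - as.numeric(vt[[pid]])
    if (dt < 0 || dt > window_h * 3600) next
    for (s in split_symptoms(qs$symptoms[i])) {
      if (!s %in% all_symptoms) next
      key <- s
      reported[[key]] <- union(if (is.null(reported[[key]])) character(0)
                               else reported[[key]], pid)
    }
  }
  syms <- sort(ls(reported))
  rows <- lapply(syms, function(s) {
    est <- symptom_proportion(length(reported[[s]]), n)
    data.frame(symptom = s, k = est$k, n = est$n, proportion = est$proportion,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(symptom = character(0), k = integer(0), n = integer(0),
                      proportion = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  }
  do.call(rbind, rows)
}

# round half up to `digits` decimals (reporting convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Recompute a stratified cross-tabulation from published tier counts
#'
#' Expands a table of per-stratum tier counts (e.g. a published cohort
#' description) into pseudo-participant rows and runs [tier_crosstab()] on
#' them, so published percentages can be recomputed through the same code
#' path used for real cohorts.
#'
#' @param counts data.frame(dose, stratum_type, stratum, tier, count); the
#'   copy shipped with the package is at
#'   `system.file("extdata/cohort_tier_counts.csv", package = "vaxwatch")`.
#' @param dose dose to select.
#' @param stratum_type one of `"all"`, `"sex"`, `"age_group"`,
#'   `"underlying_condition"`.
#' @return the [tier_crosstab()] rows for that stratum type.
#' @export
crosstab_from_counts <- function(counts, dose, stratum_type) {
  sub <- counts[counts$dose == dose & counts$stratum_type == stratum_type, ]
  if (!nrow(sub)) stop("no counts for dose ", dose, " / ", stratum_type)
  n <- sum(sub$count)
  tier <- rep(sub$tier, sub$count)
  stratum <- rep(sub$stratum, sub$count)
  roster <- data.frame(participant_id = sprintf("X%06d", seq_len(n)),
                       stringsAsFactors = FALSE)
  if (stratum_type == "sex") roster$sex <- stratum
  if (stratum_type == "age_group") {
    roster$age <- ifelse(stratum == "18-55", 40L, 70L)
  }
  if (stratum_type == "underlying_condition") {
    roster$underlying_condition <- stratum == "yes"
  }
  tiers <- data.frame(participant_id = roster$participant_id, tier = tier,
                      stringsAsFactors = FALSE)
  xt <- tier_crosstab(tiers, roster)
  xt[xt$stratum_type == stratum_type, , drop = FALSE]
}

#' Stratified tier cross-tabulation
#'
#' Counts and percentages of none/mild/severe tiers overall and within the
#' strata sex, age group (18-55 vs > 55) and underlying condition, plus the
#' any-reaction (mild or severe) rate per stratum. Percentages are rounded
#' half-up to one decimal for reporting.
#'
#' @param tiers data.frame(participant_id, tier) (NA tiers dropped).
#' @param roster roster with age, sex, underlying_condition (optional
#'   columns are skipped).
#' @return data.frame(stratum_type, stratum, tier, count, pct,
#'   any_reaction_pct).
#' @export
tier_crosstab <- function(tiers, roster) {
  m <- merge(tiers, roster, by = "participant_id")
  m <- m[!is.na(m$tier), , drop = FALSE]
  strata <- list(all = rep("all", nrow(m)))
  if ("sex" %in% names(m)) strata$sex <- as.character(m$sex)
  if ("age" %in% names(m)) {
    strata$age_group <- ifelse(m$age <= 55, "18-55", ">55")
  }
  if ("underlying_condition" %in% names(m)) {
    strata$underlying_condition <-
      ifelse(as.logical(m$underlying_condition), "yes", "no")
  }
  out <- list()
  for (stype in names(strata)) {
    sval <- strata[[stype]]
    for (sv in sort(unique(sval))) {
      sub <- m$tier[sval == sv]
      tot <- length(sub)
      any_pct <- round_half_up(100 * sum(sub != "none") / tot, 1)
      for (tier in .TIERS) {
        cnt <- sum(sub == tier)
        out[[length(out) + 1L]] <- data.frame(
          stratum_type = stype, stratum = sv, tier = tier, count = cnt,
          pct = round_half_up(100 * cnt / tot, 1),
          any_reaction_pct = any_pct, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
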
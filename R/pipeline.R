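# Pipeline orchestration: validate input CSVs, run
# simulate -> classify -> preprocess -> include -> analyze -> panel as one
# reproducible unit, and a small subcommand CLI.

#' Validate the canonical input CSVs
#'
#' Checks headers, channel and symptom vocabulary membership, timestamp
#' parseability and temperature range before any computation.
#'
#' @param roster_path,wearable_path,questionnaire_path file paths.
#' @return character vector of violations (empty when valid).
#' @export
validate_inputs <- function(roster_path, wearable_path, questionnaire_path) {
  errs <- character(0)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      return(sprintf("%s: missing column(s) %s", what,
                     paste(miss, collapse = ", ")))
    }
    character(0)
  }
  try_ts <- function(x, what) {
    bad <- which(is.na(suppressWarnings(
      as.POSIXct(gsub("T", " ", x), tz = .VW_TZ,
                 format = "%Y-%m-%d %H:%M:%S"))))
    if (length(bad)) sprintf("%s: unparseable timestamp at row %d ('%s')",
                             what, bad[1], x[bad[1]]) else character(0)
  }
  for (p in c(roster_path, wearable_path, questionnaire_path)) {
    if (!file.exists(p)) errs <- c(errs, sprintf("file not found: %s", p))
  }
  if (length(errs)) return(errs)
  roster <- utils::read.csv(roster_path, stringsAsFactors = FALSE)
  errs <- c(errs, need(roster, c("participant_id", "age", "sex",
                                 "underlying_condition", "dose",
                                 "vaccination_time", "true_severity"),
                       "roster"))
  if (!length(errs)) {
    errs <- c(errs, try_ts(roster$vaccination_time, "roster"))
    bad_sex <- which(!roster$sex %in% c("female", "male"))
    if (length(bad_sex)) {
      errs <- c(errs, sprintf("roster: unknown sex at row %d ('%s')",
                              bad_sex[1], roster$sex[bad_sex[1]]))
    }
    if (any(roster$age < 18, na.rm = TRUE)) {
      errs <- c(errs, "roster: age below 18")
    }
  }
  wear <- data.table::fread(wearable_path, nrows = 1e6, data.table = FALSE)
  errs <- c(errs, need(wear, c("participant_id", "channel", "timestamp",
                               "value"), "wearable"))
  if ("channel" %in% names(wear)) {
    bad <- which(!wear$channel %in% .CHANNELS)
    if (length(bad)) {
      errs <- c(errs, sprintf("wearable: unknown channel at row %d ('%s')",
                              bad[1], wear$channel[bad[1]]))
    }
  }
  qs <- utils::read.csv(questionnaire_path, stringsAsFactors = FALSE)
  errs <- c(errs, need(qs, c("participant_id", "timestamp", "symptoms",
                             "temperature_c"), "questionnaire"))
  if ("temperature_c" %in% names(qs)) {
    tv <- suppressWarnings(as.numeric(qs$temperature_c))
    bad <- which(!is.na(tv) & (tv < 34 | tv > 43))
    if (length(bad)) {
      errs <- c(errs, sprintf(
        "questionnaire: temperature out of [34, 43] C at row %d (%s)",
        bad[1], qs$temperature_c[bad[1]]))
    }
  }
  if ("timestamp" %in% names(qs)) {
    errs <- c(errs, try_ts(qs$timestamp, "questionnaire"))
  }
  errs
}

#' Run the full analysis pipeline
#'
#' Either simulates a cohort (when `config` is given) or reads the three
#' canonical CSVs, then tiers the questionnaires, preprocesses the wearable
#' streams, applies inclusion, computes stratified difference statistics for
#' each channel, and fits the four panel regressions (all/asymptomatic x
#' 0-72/24-72 indicator). All stage outputs are written under `out_dir` and
#' a plain-text report is produced.
#'
#' @param roster_path,wearable_path,questionnaire_path input CSVs (ignored
#'   when `config` is given).
#' @param config optional `simulation_config`; the simulated cohort is
#'   written to `out_dir` first and then analysed from those files.
#' @param out_dir output directory.
#' @param channels channels to analyse.
#' @param seed seed forwarded to the simulation when `config` is given.
#' @return invisibly, a list with every stage result plus `report` (the
#'   report lines, also written to `report.txt`).
#' @export
run_pipeline <- function(roster_path = NULL, wearable_path = NULL,
                         questionnaire_path = NULL, config = NULL,
                         out_dir, channels = .CHANNELS, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    sim <- simulate_cohort(config, hourly = FALSE, channels = channels)
    paths <- write_simulation(sim, out_dir)
    roster_path <- paths[1]; wearable_path <- paths[2]
    questionnaire_path <- paths[3]
  }
  errs <- validate_inputs(roster_path, wearable_path, questionnaire_path)
  if (length(errs)) {
    stop("input validation failed:\n  ", paste(errs, collapse = "\n  "))
  }
  roster <- utils::read.csv(roster_path, stringsAsFactors = FALSE)
  wearable <- data.table::fread(wearable_path, data.table = FALSE)
  questionnaires <- utils::read.csv(questionnaire_path,
                                    stringsAsFactors = FALSE)
  questionnaires$symptoms <- as.character(questionnaires$symptoms)
  questionnaires$symptoms[is.na(questionnaires$symptoms)] <- ""

  # classify
  tiers <- tier_cohort(roster, questionnaires)
  utils::write.csv(tiers, file.path(out_dir, "tiers.csv"), row.names = FALSE)
  props <- symptom_proportions(roster, questionnaires)
  utils::write.csv(props, file.path(out_dir, "proportions.csv"),
                   row.names = FALSE)
  xtab <- tier_crosstab(tiers, roster)
  utils::write.csv(xtab, file.path(out_dir, "tier_crosstab.csv"),
                   row.names = FALSE)

  # preprocess
  prep <- preprocess_wearable(wearable, roster)
  tabs <- preprocessed_tables(prep)
  utils::write.csv(tabs$hourly, file.path(out_dir, "hourly.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$diffs, file.path(out_dir, "diffs.csv"),
                   row.names = FALSE)

  # include
  inclusion <- cohort_inclusion(roster, questionnaires, prep)
  utils::write.csv(inclusion, file.path(out_dir, "inclusion.csv"),
                   row.names = FALSE)
  inc_ids <- inclusion$participant_id[inclusion$included]
  if (!length(inc_ids)) {
    stop("inclusion stage: no participants satisfy the inclusion criteria")
  }

  report <- c(sprintf("cohort: %d participants, %d included",
                      nrow(roster), length(inc_ids)), "",
              "tier table (included participants):")
  tt <- table(tiers$tier[tiers$participant_id %in% inc_ids], useNA = "no")
  report <- c(report, sprintf("  %-8s %d", names(tt), as.integer(tt)), "")

  # analyze per channel
  analyses <- list()
  for (ch in channels) {
    keys <- grep(paste0("\\.", ch, "$"), names(prep), value = TRUE)
    diffs <- stack_diffs(lapply(prep[keys], function(r) r$diffs))
    diffs <- diffs[diffs$participant_id %in% inc_ids, , drop = FALSE]
    if (!nrow(diffs)) next
    an <- stratified_differences(diffs, tiers)
    analyses[[ch]] <- an
    curves <- do.call(rbind, lapply(names(an$curves), function(st) {
      cv <- an$curves[[st]]
      if (!nrow(cv)) return(NULL)
      data.frame(stratum = st, channel = ch, hour_offset = cv$hour,
                 mean = cv$mean_diff, ci_low = cv$ci_low,
                 ci_high = cv$ci_high, n = cv$n, stringsAsFactors = FALSE)
    }))
    utils::write.csv(curves, file.path(out_dir,
                                       sprintf("curves_%s.csv", ch)),
                     row.names = FALSE)
    if (nrow(an$tests)) {
      utils::write.csv(an$tests,
                       file.path(out_dir, sprintf("tests_%s.csv", ch)),
                       row.names = FALSE)
    }
    report <- c(report, sprintf("channel %s:", ch))
    for (st in names(an$windows)) {
      w <- an$windows[[st]]
      pkr <- an$peaks[[st]]
      if (is.null(w)) next
      report <- c(report, sprintf(
        "  %-7s 72h mean diff %.2f [%.2f, %.2f] (n=%d); peak %.2f at %dh, return at %sh",
        st, w$mean, w$ci_low, w$ci_high, w$n, pkr$peak_value, pkr$peak_hour,
        ifelse(is.na(pkr$return_hour), "NA", pkr$return_hour)))
    }
    report <- c(report, "")
  }

  # panel regressions
  bf <- bonferroni_threshold(0.05, 6, digits = 3)
  fits <- list()
  for (ch in channels) {
    for (asym in c(FALSE, TRUE)) {
      key <- sprintf("%s_%s", ch, if (asym) "asymptomatic" else "all")
      main <- tryCatch({
        pn <- build_panel(prep, roster, channel = ch, tiers = tiers,
                          asymptomatic_only = asym, included = inc_ids)
        fit_mixed_panel(pn)
      }, error = function(e) e)
      if (inherits(main, "error")) {
        report <- c(report, sprintf("panel %s: failed (%s)", key,
                                    conditionMessage(main)), "")
        next
      }
      pn <- build_panel(prep, roster, channel = ch, tiers = tiers,
                        asymptomatic_only = asym, included = inc_ids)
      sens <- sensitivity_refit(pn)
      fits[[key]] <- list(main = main, sensitivity = sens)
      b1 <- main$coefficients[main$coefficients$term == "post72", ]
      flag <- if (b1$p_one_sided < bf) "significant" else "not significant"
      report <- c(report,
                  format_panel_fit(main, sprintf("panel %s [0-72h]", key)),
                  sprintf("  post-72h indicator one-sided p %.3g -> %s at Bonferroni %.3f",
                          b1$p_one_sided, flag, bf),
                  sprintf("  sensitivity [24-72h] coefficient %.4f",
                          sens$coefficients$estimate[
                            sens$coefficients$term == "post72"]), "")
    }
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(roster = roster, tiers = tiers, proportions = props,
                 crosstab = xtab, inclusion = inclusion, prep = prep,
                 analyses = analyses, fits = fits, report = report))
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `classify`, `preprocess`, `analyze`, `panel`,
#' `run`. Exit codes: 0 success, 1 validation error, 2 computation error.
#' Called from a wrapper script, e.g.
#' `Rscript -e 'vaxwatch::vaxwatch_cli()' run --roster r.csv ...`.
#'
#' @param args character vector of arguments (default the command line).
#' @return integer exit code, invisibly.
#' @export
vaxwatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (!length(i)) return(default)
    if (i[1] + 1 > length(args)) stop("missing value for --", name)
    args[i[1] + 1]
  }
  flag <- function(name) any(args == paste0("--", name))
  if (flag("version")) {
    cat("vaxwatch", as.character(utils::packageVersion("vaxwatch")), "\n")
    return(invisible(0L))
  }
  if (!length(args)) {
    cat("usage: vaxwatch <simulate|classify|preprocess|analyze|panel|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  status <- tryCatch({
    out <- opt("out", "vaxwatch-out")
    seed <- as.integer(opt("seed", "1"))
    switch(cmd,
      simulate = {
        n <- as.integer(opt("n", "50"))
        cfg <- simulation_config(n_participants = n, seed = seed)
        write_simulation(simulate_cohort(cfg, hourly = FALSE), out)
        0L
      },
      classify = {
        roster <- utils::read.csv(opt("roster"), stringsAsFactors = FALSE)
        qs <- utils::read.csv(opt("questionnaires"), stringsAsFactors = FALSE)
        qs$symptoms[is.na(qs$symptoms)] <- ""
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(tier_cohort(roster, qs),
                         file.path(out, "tiers.csv"), row.names = FALSE)
        utils::write.csv(symptom_proportions(roster, qs),
                         file.path(out, "proportions.csv"), row.names = FALSE)
        0L
      },
      preprocess = {
        roster <- utils::read.csv(opt("roster"), stringsAsFactors = FALSE)
        wear <- data.table::fread(opt("wearable"), data.table = FALSE)
        tabs <- preprocessed_tables(preprocess_wearable(wear, roster))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(tabs$hourly, file.path(out, "hourly.csv"),
                         row.names = FALSE)
        utils::write.csv(tabs$diffs, file.path(out, "diffs.csv"),
                         row.names = FALSE)
        0L
      },
      analyze = {
        diffs <- utils::read.csv(opt("diffs"), stringsAsFactors = FALSE)
        tiers <- utils::read.csv(opt("tiers"), stringsAsFactors = FALSE)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        for (ch in unique(diffs$channel)) {
          d <- diffs[diffs$channel == ch,
                     c("participant_id", "hour_offset", "diff")]
          names(d)[2] <- "hour"
          an <- stratified_differences(d, tiers)
          utils::write.csv(an$tests,
                           file.path(out, sprintf("tests_%s.csv", ch)),
                           row.names = FALSE)
        }
        0L
      },
      panel = {
        hourly <- utils::read.csv(opt("hourly"), stringsAsFactors = FALSE)
        roster <- utils::read.csv(opt("roster"), stringsAsFactors = FALSE)
        tiers <- utils::read.csv(opt("tiers"), stringsAsFactors = FALSE)
        ch <- switch(opt("channel", "hr"), hr = "heart_rate",
                     stress = "stress", opt("channel"))
        win <- if (identical(opt("window", "0-72"), "24-72")) c(24, 72)
               else c(0, 72)
        prep <- lapply(split(hourly, list(hourly$participant_id,
                                          hourly$channel), drop = TRUE),
                       function(d) list(interpolated = new_hourly_series(
                         d$hour_offset, d$value, d$status,
                         d$participant_id[1], d$channel[1])))
        names(prep) <- vapply(prep, function(r) {
          s <- r$interpolated
          paste(attr(s, "participant_id"), attr(s, "channel"), sep = ".")
        }, character(1))
        pn <- build_panel(prep, roster, channel = ch, tiers = tiers,
                          asymptomatic_only = flag("asymptomatic-only"),
                          window = win)
        fit <- fit_mixed_panel(pn)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        writeLines(format_panel_fit(fit), file.path(out, "panel_fit.txt"))
        utils::write.csv(fit$coefficients,
                         file.path(out, "panel_coefficients.csv"),
                         row.names = FALSE)
        0L
      },
      run = {
        cfgn <- opt("simulate-n")
        if (!is.null(cfgn)) {
          run_pipeline(config = simulation_config(
            n_participants = as.integer(cfgn), seed = seed), out_dir = out)
        } else {
          run_pipeline(opt("roster"), opt("wearable"),
                       opt("questionnaires"), out_dir = out)
        }
        0L
      },
      { cat("unknown subcommand:", cmd, "\n"); 1L }
    )
  }, error = function(e) {
    msg <- conditionMessage(e)
    cat("error:", msg, "\n")
    if (grepl("validation", msg)) 1L else 2L
  })
  invisible(status)
}
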
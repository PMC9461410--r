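# Mixed-effects panel regression. One row per participant-hour over the
# 168 h before through 168 h after vaccination (at most 336, one lost to
# the lag), built from linearly interpolated but UNSMOOTHED hourly data:
#
#   y_it = b0 + b1 post72_it + b2 y_i,t-1 + b3 age_i + b4 no_condition_i
#          + b5 male_i + u_i + e_it,  u_i ~ N(0, s_u^2), e_it ~ N(0, s_e^2)
#
# fitted by maximum likelihood with participant random intercepts. The
# lagged dependent variable alongside random effects induces Nickell-type
# bias of order 1/T; at T = 336 this is negligible and we follow the
# published design rather than correcting for it.

.PANEL_FIXED <- c("post72", "y_lag", "age", "no_condition", "male")

#' Build the participant-hour panel
#'
#' @param prep preprocessing results from [preprocess_wearable()] (or a list
#'   of `preprocess_series()` results) — the `interpolated` series are used.
#' @param roster roster with age, sex, underlying_condition.
#' @param channel `"heart_rate"` or `"stress"`.
#' @param tiers optional data.frame(participant_id, tier).
#' @param asymptomatic_only keep only tier `"none"` participants (requires
#'   `tiers`).
#' @param included optional character vector of included participant ids.
#' @param window indicator window in hours, default `c(0, 72)`.
#' @return data.frame(participant_id, t, y, y_lag, post72, age,
#'   no_condition, male). The lag is taken within participant and within
#'   contiguous non-missing runs; the first hour of each run is dropped.
#' @export
build_panel <- function(prep, roster, channel = "heart_rate", tiers = NULL,
                        asymptomatic_only = FALSE, included = NULL,
                        window = c(0, 72)) {
  ids <- roster$participant_id
  if (!is.null(included)) ids <- intersect(ids, included)
  if (asymptomatic_only) {
    if (is.null(tiers)) stop("asymptomatic_only requires a tier table")
    ids <- intersect(ids, tiers$participant_id[!is.na(tiers$tier) &
                                                 tiers$tier == "none"])
  }
  rows <- list()
  for (pid in ids) {
    r <- prep[[paste(pid, channel, sep = ".")]]
    if (is.null(r)) next
    p <- roster[roster$participant_id == pid, ]
    if (anyNA(c(p$age, p$sex, p$underlying_condition))) {
      message("build_panel: skipping ", pid, " (missing demographics)")
      next
    }
    s <- window_series(r$interpolated, -168L, 168L)
    ok <- s$status != "missing"
    use <- which(ok & c(FALSE, ok[-length(ok)]))  # previous hour present
    if (!length(use)) next
    rows[[pid]] <- data.frame(
      participant_id = pid, t = s$hour[use], y = s$value[use],
      y_lag = s$value[use - 1L],
      post72 = as.integer(s$hour[use] >= window[1] & s$hour[use] < window[2]),
      age = p$age, no_condition = as.integer(!as.logical(p$underlying_condition)),
      male = as.integer(p$sex == "male"), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("empty panel: no usable participants")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the mixed-effects panel regression
#'
#' Maximum-likelihood fit (lme4) of the panel model with participant random
#' intercepts. Reports coefficients, standard errors, two-sided p-values
#' (t statistics against a t distribution with `n_obs - 6` df), a separate
#' one-sided p-value for the post-vaccination indicator (alternative:
#' coefficient > 0), the variance decomposition, the within/between/overall
#' R-squared, and a Wald F-statistic for all slopes jointly zero.
#'
#' @param panel data.frame from [build_panel()].
#' @param formula_fixed fixed-effects part (default the five regressors).
#' @return list of class `panel_fit` (a RegressionFit): `coefficients`
#'   (data.frame term, estimate, std_error, t, p, p_one_sided), `sigma_u2`,
#'   `sigma_e2`, `pct_variance_random`, `r2_between`, `r2_within`,
#'   `r2_overall`, `f_statistic`, `f_p`, `n_participants`, `n_observations`,
#'   and the underlying `model`.
#' @export
fit_mixed_panel <- function(panel,
                            formula_fixed = y ~ post72 + y_lag + age +
                              no_condition + male) {
  stopifnot(nrow(panel) > 0)
  if (length(unique(panel$participant_id)) < 2L) {
    stop("panel needs at least 2 participants")
  }
  f <- stats::update(formula_fixed, . ~ . + (1 | participant_id))
  fit <- lme4::lmer(f, data = panel, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) {
    stop("mixed-model fit did not converge: ",
         paste(unlist(conv$messages), collapse = "; "))
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  n_obs <- nrow(panel)
  df <- n_obs - length(beta)
  tval <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      std_error = unname(se), t = unname(tval),
                      p = unname(2 * stats::pt(-abs(tval), df)),
                      p_one_sided = unname(stats::pt(tval, df,
                                                     lower.tail = FALSE)),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "participant_id"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  r2 <- r_squared_decomposition(fit, panel)
  # Wald F for all slopes jointly zero
  slopes <- setdiff(names(beta), "(Intercept)")
  bs <- beta[slopes]
  Vs <- V[slopes, slopes, drop = FALSE]
  k <- length(slopes)
  f_stat <- as.numeric(t(bs) %*% solve(Vs, bs)) / k
  structure(list(
    coefficients = coefs, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
    pct_variance_random = 100 * sigma_u2 / (sigma_u2 + sigma_e2),
    r2_between = r2[["r2_between"]], r2_within = r2[["r2_within"]],
    r2_overall = r2[["r2_overall"]],
    f_statistic = f_stat,
    f_p = stats::pf(f_stat, k, n_obs - k - 1, lower.tail = FALSE),
    n_participants = length(unique(panel$participant_id)),
    n_observations = n_obs, model = fit), class = "panel_fit")
}

#' Within/between/overall R-squared decomposition
#'
#' Fitted values use fixed effects only (X beta, excluding the random
#' intercepts). Between: squared correlation of participant means of fitted
#' values and outcomes; within: squared correlation after subtracting
#' participant means; overall: squared correlation of the raw series.
#'
#' @param fit an lme4 fit or `panel_fit`.
#' @param panel the panel the model was fitted on.
#' @return named numeric vector (r2_between, r2_within, r2_overall);
#'   `r2_between` is NA with a single participant.
#' @export
r_squared_decomposition <- function(fit, panel) {
  if (inherits(fit, "panel_fit")) fit <- fit$model
  X <- stats::model.matrix(fit)
  yhat <- as.numeric(X %*% lme4::fixef(fit))
  y <- panel$y
  g <- panel$participant_id
  ym <- tapply(y, g, mean); fm <- tapply(yhat, g, mean)
  between <- if (length(ym) > 1) stats::cor(ym, fm)^2 else NA_real_
  yd <- y - ym[g]; fd <- yhat - fm[g]
  within <- if (stats::sd(yd) > 0 && stats::sd(fd) > 0)
    stats::cor(yd, fd)^2 else NA_real_
  overall <- stats::cor(y, yhat)^2
  c(r2_between = as.numeric(between), r2_within = as.numeric(within),
    r2_overall = overall)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @param digits optional decimals for the reporting convention (0.05 over 6
#'   coefficients prints as 0.008 at `digits = 3`); `NULL` (default) returns
#'   the exact `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 6L, digits = NULL) {
  if (m < 1) stop("m must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  x <- alpha / m
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Sensitivity refit with the 24-72 h indicator
#'
#' Refits the identical model with the post-vaccination indicator set over
#' `window` (default hours 24-72) instead of 0-72, to separate the
#' physiological response from any effect of the vaccination encounter
#' itself (the response is near baseline in the first 12 h, so the late
#' window should carry a larger coefficient).
#'
#' @param panel panel from [build_panel()] (any indicator window).
#' @param window alternative indicator window, default `c(24, 72)`.
#' @return a `panel_fit`.
#' @export
sensitivity_refit <- function(panel, window = c(24, 72)) {
  panel$post72 <- as.integer(panel$t >= window[1] & panel$t < window[2])
  fit_mixed_panel(panel)
}

#' Simulate a panel directly from the regression model
#'
#' Model-based generator for parameter-recovery and type-I-error studies:
#' demographics are drawn as in [generate_cohort()], then y is generated
#' recursively from the panel equation with the given coefficients,
#' random-intercept sd and residual sd, starting each participant at their
#' stationary mean at t = -168 (the lag-less first hour is dropped, as in
#' [build_panel()]).
#'
#' @param n_participants cohort size.
#' @param beta named vector: intercept, post72, y_lag, age, no_condition,
#'   male.
#' @param sigma_u random-intercept sd.
#' @param sigma_e residual sd.
#' @param window indicator window, default `c(0, 72)`.
#' @param t_range panel hour range, default `c(-168, 168)`.
#' @param seed integer seed.
#' @return panel data.frame as from [build_panel()].
#' @export
simulate_panel <- function(n_participants = 200,
                           beta = c(intercept = 30, post72 = 0.7,
                                    y_lag = 0.5, age = -0.15,
                                    no_condition = -1.5, male = -3),
                           sigma_u = 1, sigma_e = 3,
                           window = c(0, 72), t_range = c(-168, 168),
                           seed = 1L) {
  stopifnot(all(c("intercept", "post72", "y_lag", "age", "no_condition",
                  "male") %in% names(beta)))
  tt <- seq(t_range[1], t_range[2] - 1L)
  post <- as.integer(tt >= window[1] & tt < window[2])
  rows <- lapply(seq_len(n_participants), function(i) {
    with_seed(participant_seed(seed, i, 707L), {
      age <- min(max(round(stats::rnorm(1, 50, 15)), 18), 88)
      male <- as.integer(stats::runif(1) < 0.43)
      nocond <- as.integer(stats::runif(1) < 0.65)
      u <- stats::rnorm(1, 0, sigma_u)
      fixed_part <- beta[["intercept"]] + beta[["age"]] * age +
        beta[["no_condition"]] * nocond + beta[["male"]] * male + u
      y <- numeric(length(tt))
      y0 <- fixed_part / (1 - beta[["y_lag"]])     # stationary mean, no post
      e <- stats::rnorm(length(tt), 0, sigma_e)
      prev <- y0
      for (j in seq_along(tt)) {
        y[j] <- fixed_part + beta[["post72"]] * post[j] +
          beta[["y_lag"]] * prev + e[j]
        prev <- y[j]
      }
      data.frame(participant_id = sprintf("S%04d", i), t = tt[-1],
                 y = y[-1], y_lag = y[-length(y)], post72 = post[-1],
                 age = age, no_condition = nocond, male = male,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a panel fit like a results table
#'
#' @param fit a `panel_fit`.
#' @param label table caption.
#' @return character vector of report lines (p-values below 0.001 print as
#'   `<0.001`).
#' @export
format_panel_fit <- function(fit, label = "Mixed effects panel regression") {
  fp <- function(p) if (p < 0.001) "<0.001" else sprintf("%.4f", p)
  co <- fit$coefficients
  pretty <- c("(Intercept)" = "Intercept",
              post72 = "Between 0 and 72 h after vaccination",
              y_lag = "HR or Stress in Previous Hour", age = "Age",
              no_condition = "No Underlying Medical Condition",
              male = "Male Gender")
  lines <- c(sprintf("%s (n = %d participants, %d observations)", label,
                     fit$n_participants, fit$n_observations),
             sprintf("  %-40s %9s, %7s, %s", "Term", "Coef", "StdErr", "p"))
  for (i in seq_len(nrow(co))) {
    nm <- pretty[co$term[i]]
    if (is.na(nm)) nm <- co$term[i]
    lines <- c(lines, sprintf("  %-40s %9.4f, %7.4f, %s", nm,
                              co$estimate[i], co$std_error[i], fp(co$p[i])))
  }
  c(lines,
    sprintf("  F-statistic = %.4g (p-value %s)", fit$f_statistic,
            if (fit$f_p < 1e-4) "<0.0001" else sprintf("%.4f", fit$f_p)),
    sprintf("  R2 Between = %.4f | R2 Within = %.4f | R2 Overall = %.4f",
            fit$r2_between, fit$r2_within, fit$r2_overall),
    sprintf("  %% of Variance due to Random Effects: %.2f%%",
            fit$pct_variance_random))
}
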
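# participant-hour panel and mixed-effects regression

test_that("build_panel drops lag-less hours and masked runs", {
  cfg <- quiet_config()
  p <- fake_participant(severity = "none")
  s <- simulate_hourly(p, "heart_rate", zero_curve(), cfg, gaps = FALSE)
  prep <- list(P1.heart_rate = list(interpolated = interpolate_gaps(s)))
  pn <- build_panel(prep, p, channel = "heart_rate")
  expect_equal(nrow(pn), 335)             # 336 hours minus the first
  expect_equal(range(pn$t), c(-167, 167))
  expect_equal(sum(pn$post72), 72)
  # interior masked run: lose the masked hours plus each restart hour
  v <- s$value
  v[s$hour %in% 10:17] <- NA              # 8-hour gap inside [-168, 168)
  s2 <- new_hourly_series(s$hour, v, participant_id = "P1",
                          channel = "heart_rate", origin = attr(s, "origin"))
  prep2 <- list(P1.heart_rate = list(interpolated = interpolate_gaps(s2)))
  pn2 <- build_panel(prep2, p, channel = "heart_rate")
  # oracle by enumeration: hour t usable iff y(t) and y(t-1) present
  present <- function(t) !(t %in% 10:17) & t >= -168
  usable <- vapply(-167:167, function(t) present(t) && present(t - 1),
                   logical(1))
  expect_equal(sort(pn2$t), (-167:167)[usable])
  expect_false(any(pn2$t %in% 10:18))     # gap hours and the restart hour
  # asymptomatic_only on an all-severe cohort gives an empty panel
  tiers <- data.frame(participant_id = "P1", tier = "severe")
  expect_error(build_panel(prep, p, tiers = tiers, asymptomatic_only = TRUE),
               "empty panel")
})

test_that("fit_mixed_panel agrees with the profiled-likelihood GLS oracle", {
  pn <- simulate_panel(n_participants = 8, sigma_u = 1.2, sigma_e = 2,
                       t_range = c(-20, 20), seed = 5)
  fit <- fit_mixed_panel(pn)
  oracle <- oracle_panel_ml(pn)
  expect_equal(fit$coefficients$estimate, as.numeric(oracle$beta),
               tolerance = 1e-5)
  # lme4 residual variance is ML sigma^2 as well
  expect_equal(fit$sigma_e2, oracle$s2e, tolerance = 1e-4)
  expect_equal(fit$sigma_u2, oracle$s2u, tolerance = 1e-3)
  expect_equal(fit$n_participants, 8)
  expect_error(fit_mixed_panel(pn[pn$participant_id == "S0001", ]),
               "2 participants")
})

test_that("single-replicate parameter recovery at the stated scale", {
  sigma_e <- 3
  sigma_u <- sqrt(0.08 / 0.92) * sigma_e      # 8% random-effect share
  pn <- simulate_panel(n_participants = 200, sigma_u = sigma_u,
                       sigma_e = sigma_e, seed = 1)
  fit <- fit_mixed_panel(pn)
  co <- fit$coefficients
  b1 <- co[co$term == "post72", ]
  expect_lt(abs(b1$estimate - 0.7), 3 * b1$std_error)
  lag <- co[co$term == "y_lag", ]
  expect_lt(abs(lag$estimate - 0.5), 0.02)
  expect_lt(abs(fit$pct_variance_random - 8), 3)
})

test_that("zero random-intercept variance is recovered as ~0%", {
  pn <- simulate_panel(n_participants = 40, sigma_u = 0, sigma_e = 2,
                       t_range = c(-60, 60), seed = 2)
  fit <- fit_mixed_panel(pn)
  expect_lt(fit$pct_variance_random, 1)
})

test_that("r-squared decomposition behaves at the extremes", {
  # perfect linear data, no noise
  pn <- simulate_panel(n_participants = 10, sigma_u = 0, sigma_e = 1e-8,
                       t_range = c(-20, 20), seed = 3)
  fit <- fit_mixed_panel(pn)
  r2 <- r_squared_decomposition(fit, pn)
  expect_true(all(r2 > 0.999))
  # outcome independent of the design
  set.seed(4)
  pn2 <- pn
  pn2$y <- stats::rnorm(nrow(pn2))
  pn2$y_lag <- stats::rnorm(nrow(pn2))
  fit2 <- fit_mixed_panel(pn2)
  r2b <- r_squared_decomposition(fit2, pn2)
  expect_lt(r2b[["r2_overall"]], 0.05)
  # strong between-participant signal, heavy within noise
  set.seed(6)
  ids <- rep(sprintf("Q%02d", 1:12), each = 50)
  age <- rep(stats::runif(12, 20, 80), each = 50)
  y <- 2 * age + stats::rnorm(length(ids), 0, 30)
  pn3 <- data.frame(participant_id = ids, t = rep(1:50, 12), y = y,
                    y_lag = 0, post72 = 0L, age = age,
                    no_condition = rep(c(0L, 1L), 300),
                    male = rep(c(0L, 1L), each = 300))
  fit3 <- fit_mixed_panel(pn3, formula_fixed = y ~ age + no_condition + male)
  r2c <- r_squared_decomposition(fit3, pn3)
  expect_gt(r2c[["r2_between"]], 2 * r2c[["r2_within"]])
})

test_that("bonferroni_threshold reproduces the reporting convention", {
  expect_equal(bonferroni_threshold(0.05, 6, digits = 3), 0.008)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("sensitivity refit with a late-onset response raises the estimate", {
  # truth: effect only between 24 and 72 h
  pn <- simulate_panel(n_participants = 60, beta = c(intercept = 30,
                                                     post72 = 0.7,
                                                     y_lag = 0.5,
                                                     age = -0.15,
                                                     no_condition = -1.5,
                                                     male = -3),
                       sigma_u = 0.9, sigma_e = 3, window = c(24, 72),
                       seed = 7)
  pn$post72 <- as.integer(pn$t >= 0 & pn$t < 72)   # main-fit indicator
  main <- fit_mixed_panel(pn)
  sens <- sensitivity_refit(pn)                    # 24-72 h indicator
  b <- function(f) f$coefficients$estimate[f$coefficients$term == "post72"]
  expect_gt(b(sens), b(main))
  expect_lt(abs(b(sens) - 0.7), 3 * sens$coefficients$std_error[
    sens$coefficients$term == "post72"])
  # null generator: both CIs cover 0
  pn0 <- simulate_panel(n_participants = 40, beta = c(intercept = 30,
                                                      post72 = 0,
                                                      y_lag = 0.5,
                                                      age = -0.15,
                                                      no_condition = -1.5,
                                                      male = -3),
                        sigma_u = 0.9, sigma_e = 3, seed = 8)
  f0 <- fit_mixed_panel(pn0)
  s0 <- sensitivity_refit(pn0)
  covers0 <- function(f) {
    r <- f$coefficients[f$coefficients$term == "post72", ]
    abs(r$estimate) < 1.96 * r$std_error
  }
  expect_true(covers0(f0))
  expect_true(covers0(s0))
})

test_that("panel fits format as a readable report", {
  pn <- simulate_panel(n_participants = 10, t_range = c(-30, 30), seed = 9)
  lines <- format_panel_fit(fit_mixed_panel(pn))
  expect_true(any(grepl("Between 0 and 72 h after vaccination", lines)))
  expect_true(any(grepl("Variance due to Random Effects", lines)))
})
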
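# questionnaire deduplication, tiering, proportions, cross-tabs

test_that("dedupe_daily keeps the latest entry per local day", {
  e <- q_entries(
    q_entry("P1", "2021-08-01 09:00:00", "headache"),
    q_entry("P1", "2021-08-01 21:30:00", "fatigue-free"),
    q_entry("P1", "2021-08-02 10:00:00", "cough"))
  d <- dedupe_daily(e)
  expect_equal(nrow(d), 2)
  expect_equal(format_timestamp(d$timestamp[1]), "2021-08-01T21:30:00")
  # idempotent; identity on one-entry-per-day input
  expect_identical(dedupe_daily(d), d)
  expect_equal(nrow(dedupe_daily(e[0, ])), 0)
  expect_error(dedupe_daily(q_entries(q_entry("P1", "2021-08-01 09:00:00"),
                                      q_entry("P2", "2021-08-01 09:00:00"))),
               "single participant")
})

test_that("dedupe_daily matches a sort-and-take-last oracle on random input", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    ts <- parse_timestamp("2021-08-01 00:00:00") +
      sort(sample(0:(5 * 86400 - 1), n))
    e <- data.frame(participant_id = "P1", timestamp = ts,
                    symptoms = sample(c("", "headache"), n, replace = TRUE),
                    temperature_c = NA_real_, stringsAsFactors = FALSE)
    got <- dedupe_daily(e)
    day <- as.Date(ts, tz = "UTC")
    keep <- vapply(split(seq_len(n), day), function(ix) {
      s <- ix[order(as.numeric(ts[ix]))]
      s[length(s)]
    }, integer(1))
    oracle <- e[sort(unname(keep)), , drop = FALSE]
    rownames(oracle) <- NULL
    expect_identical(got, oracle)
  }
})

test_that("classify_symptom follows the vocabulary and the fever rule", {
  for (s in severe_symptoms) expect_equal(classify_symptom(s), "severe")
  for (s in setdiff(mild_symptoms, "feeling hot")) {
    expect_equal(classify_symptom(s), "mild")
  }
  expect_equal(classify_symptom("feeling hot", 39.2), "severe")
  expect_equal(classify_symptom("feeling hot", 38.0), "mild")
  expect_equal(classify_symptom("feeling hot", NA), "mild")
  expect_equal(classify_symptom("feeling hot"), "mild")
  # exactly 38.9 is not fever ("above 38.9" is strict)
  expect_equal(classify_symptom("feeling hot", 38.9), "mild")
  expect_equal(classify_symptom("headache"), "mild")
  expect_equal(classify_symptom("chills"), "severe")
  expect_error(classify_symptom("sparkling aura"), "sparkling aura")
})

test_that("classify_reaction subtracts baseline and takes the max tier", {
  base <- q_entry("P1", "2021-07-30 20:00:00", "headache")
  # one severe symptom on one day dominates mild symptoms on all days
  post <- q_entries(
    q_entry("P1", "2021-08-01 20:00:00", "muscle pain;chills"),
    q_entry("P1", "2021-08-02 20:00:00", "muscle pain"),
    q_entry("P1", "2021-08-03 20:00:00", "muscle pain"))
  expect_equal(classify_reaction(post, base), "severe")
  # baseline symptom reported post-vaccination is not a side effect
  only_base <- q_entries(q_entry("P1", "2021-08-01 20:00:00", "headache"))
  expect_equal(classify_reaction(only_base, base), "none")
  # free-text symptoms are ignored with a warning
  expect_warning(
    tier <- classify_reaction(
      q_entries(q_entry("P1", "2021-08-01 20:00:00",
                        "muscle pain;weakness;glowing elbows")),
      q_entry("P1", "2021-07-30 20:00:00", "")),
    "glowing elbows")
  expect_equal(tier, "mild")
  expect_error(classify_reaction(post, NULL), "baseline")
  expect_error(classify_reaction(post[0, ], base), "post-vaccination")
})

test_that("classify_reaction agrees with a brute-force oracle and is monotone", {
  set.seed(7)
  empty_base <- q_entry("P1", "2021-07-30 20:00:00", "")
  for (rep in 1:40) {
    syms <- sample(all_symptoms, sample(1:5, 1))
    post <- q_entry("P1", "2021-08-01 20:00:00", paste(syms, collapse = ";"))
    got <- classify_reaction(post, empty_base)
    oracle <- if (any(syms %in% severe_symptoms)) "severe" else "mild"
    expect_equal(got, oracle)
    # monotone: adding a symptom never lowers the tier
    extra <- sample(all_symptoms, 1)
    post2 <- q_entry("P1", "2021-08-01 20:00:00",
                     paste(c(syms, extra), collapse = ";"))
    ranks <- c(none = 1, mild = 2, severe = 3)
    expect_gte(ranks[classify_reaction(post2, empty_base)], ranks[got])
  }
})

test_that("symptom_proportion matches beta quantiles and handles edges", {
  est <- symptom_proportion(50, 100)
  expect_equal(est$proportion, 0.5)
  expect_equal(est$ci_low + est$ci_high, 1, tolerance = 1e-12) # symmetry
  est5 <- symptom_proportion(5, 100)
  expect_equal(est5$ci_low, oracle_beta_quantile(0.025, 5, 95),
               tolerance = 1e-8)
  expect_equal(est5$ci_high, oracle_beta_quantile(0.975, 5, 95),
               tolerance = 1e-8)
  # second-dose any-reaction proportion from the published counts
  expect_equal(round(symptom_proportion(154, 335)$proportion, 3), 0.46)
  expect_error(symptom_proportion(6, 5), "exceed")
  z <- symptom_proportion(0, 20); o <- symptom_proportion(20, 20)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  expect_equal(c(o$ci_low, o$ci_high), c(1, 1))
})

test_that("beta interval coverage is near nominal", {
  set.seed(2026)
  p <- 0.3; n <- 100
  k <- stats::rbinom(2000, n, p)
  covered <- vapply(k, function(ki) {
    est <- symptom_proportion(ki, n)
    est$ci_low <= p && p <= est$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("tier percentages are consistent and sum to 100", {
  tiers <- data.frame(participant_id = sprintf("P%02d", 1:40),
                      tier = rep(c("none", "mild", "severe", "mild"), 10))
  roster <- data.frame(participant_id = sprintf("P%02d", 1:40),
                       age = rep(c(30, 70), 20),
                       sex = rep(c("female", "male"), each = 20),
                       underlying_condition = rep(c(TRUE, FALSE), 20))
  xt <- tier_crosstab(tiers, roster)
  sums <- tapply(xt$pct, paste(xt$stratum_type, xt$stratum), sum)
  expect_true(all(abs(sums - 100) <= 0.2))
  # all in one tier -> 100%
  one <- tier_crosstab(data.frame(participant_id = c("A", "B"),
                                  tier = c("mild", "mild")),
                       data.frame(participant_id = c("A", "B"),
                                  sex = c("female", "male")))
  expect_equal(one$pct[one$stratum_type == "all" & one$tier == "mild"], 100)
})

test_that("published second-dose strata percentages are reproduced", {
  counts <- utils::read.csv(system.file("extdata/cohort_tier_counts.csv",
                                        package = "vaxwatch"))
  sex2 <- crosstab_from_counts(counts, dose = 2, stratum_type = "sex")
  f <- unique(sex2$any_reaction_pct[sex2$stratum == "female"])
  m <- unique(sex2$any_reaction_pct[sex2$stratum == "male"])
  expect_equal(f, 50.5)
  expect_equal(m, 39.7)
  age2 <- crosstab_from_counts(counts, dose = 2, stratum_type = "age_group")
  expect_equal(unique(age2$any_reaction_pct[age2$stratum == "18-55"]), 62.7)
})
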
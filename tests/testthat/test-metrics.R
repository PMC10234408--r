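test_that("strategy summaries reproduce the published derived quantities", {
  cohort <- build_fixture_cohort(seed = 1)
  s9 <- summarize_strategy(cohort, triage_config("combination", 9.0))
  expect_equal(s9$extra_vs_dm, 24)
  expect_equal(s9$missed_vs_full, 17)
  expect_equal(s9$fp_extra_vs_dm, 60)
  expect_equal(s9$ppv, 119 / (119 + 331))
  expect_equal(round_half_up(s9$ppv, 3), 0.264)
  expect_equal(round_half_up(s9$rate_added_per1000, 1), 16.1)
  expect_equal(round_half_up(s9$rate_total_per1000, 1), 8.1)
  expect_equal(round_half_up(s9$pct_increase_vs_dm), 25)
  expect_equal(round_half_up(s9$pct_fp_increase), 22)

  p9 <- summarize_strategy(cohort, triage_config("precedence", 9.0))
  expect_equal(p9$detected, 112)
  expect_equal(p9$fp_total, 301)
  expect_equal(round_half_up(p9$ppv, 3), 0.271)
  expect_equal(round_half_up(p9$rate_added_per1000, 1), 11.4)
  expect_equal(round_half_up(p9$rate_total_per1000, 1), 7.6)

  s75 <- summarize_strategy(cohort, triage_config("combination", 7.5))
  expect_equal(s75$detected, 126)
  expect_equal(s75$missed_vs_full, 10)
  expect_equal(round_half_up(s75$rate_added_per1000, 2), 9.54)
  expect_equal(round_half_up(s75$pct_increase_vs_dm), 33)
  expect_equal(round_half_up(s75$pct_fp_increase), 38)
})

test_that("a strategy compared with itself shows no gain", {
  cohort <- toy_cohort()
  s <- summarize_strategy(cohort, triage_config("dm_only"))
  expect_equal(s$extra_vs_dm, 0)
  expect_equal(s$pct_increase_vs_dm, 0)
  expect_equal(s$fp_extra_vs_dm, 0)
})

test_that("zero denominators surface as NA, never as silent zero", {
  cohort <- toy_cohort()
  s <- summarize_strategy(cohort, triage_config("dm_only"))
  expect_true(is.na(s$rate_added_per1000))  # no DBT exams performed
  all_normal <- toy_cohort()
  all_normal$has_cancer <- FALSE
  all_normal$invasiveness <- NULL
  s2 <- summarize_strategy(all_normal, triage_config("full_both"))
  expect_true(is.na(s2$sensitivity))
})

test_that("Clopper-Pearson interval matches the published whole-cohort row", {
  ci <- clopper_pearson(95, 136, 0.95)
  expect_equal(format_ci(ci), "70% [0.61; 0.77]")
  expect_equal(ci$point, 95 / 136)
})

test_that("Clopper-Pearson boundaries are exact at x = 0 and x = n", {
  ci0 <- clopper_pearson(0, 7)
  expect_identical(ci0$lower, 0)
  expect_lt(ci0$upper, 1)
  cin <- clopper_pearson(7, 7)
  expect_identical(cin$upper, 1)
  expect_gt(cin$lower, 0)
  expect_error(clopper_pearson(3, 0), class = "dbtriage_ci_error")
  expect_error(clopper_pearson(8, 7), class = "dbtriage_ci_error")
})

test_that("Clopper-Pearson equals binomial tail-sum inversion for all n <= 12", {
  for (n in 1:12) {
    for (x in 0:n) {
      ci <- clopper_pearson(x, n, 0.95)
      want <- oracle_cp_tailsum(x, n, 0.95)
      expect_equal(ci$lower, unname(want["lower"]), tolerance = 1e-9,
                   label = sprintf("lower x=%d n=%d", x, n))
      expect_equal(ci$upper, unname(want["upper"]), tolerance = 1e-9,
                   label = sprintf("upper x=%d n=%d", x, n))
      expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
    }
  }
})

test_that("Clopper-Pearson agrees with binom.test and is conservative in coverage", {
  for (case in list(c(95, 136), c(24, 41), c(3, 50))) {
    ci <- clopper_pearson(case[1], case[2])
    bt <- binom.test(case[1], case[2])$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-12)
  }
  set.seed(2024)
  p <- 0.3; n <- 50; reps <- 2000
  xs <- rbinom(reps, n, p)
  covered <- vapply(xs, function(x) {
    ci <- clopper_pearson(x, n)
    ci$lower <= p && p <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("threshold sweep equals pointwise evaluation and hits its limits", {
  cohort <- build_fixture_cohort(seed = 1)
  curve <- sweep_thresholds(cohort, "combination", c(7.5, 9.0))
  expect_equal(curve$detected, c(126, 119))
  lim <- sweep_thresholds(cohort, "combination", 10.0)
  expect_equal(lim$detected, 95)

  synth <- simulate_cohort(sim_params(n_total = 50, prevalence = 0.2,
                                      seed = 31))
  grid <- seq(0.25, 9.75, by = 0.5)
  curve <- sweep_thresholds(synth, "precedence", grid)
  expect_equal(nrow(curve), length(grid))
  expect_true(all(diff(curve$threshold) > 0))
  for (i in seq_along(grid)) {
    direct <- evaluate_cohort(synth, triage_config("precedence", grid[i]))
    expect_equal(curve$detected[i], direct$detected)
    expect_equal(curve$fp_total[i], direct$fp_total)
    expect_equal(curve$n_dbt_exams[i], direct$n_dbt_exams)
  }
  # PPV identity holds on every emitted summary
  has_recall <- curve$detected + curve$fp_total > 0
  expect_equal(curve$ppv[has_recall],
               (curve$detected / (curve$detected + curve$fp_total))[has_recall])
  expect_error(sweep_thresholds(synth, "combination", numeric(0)),
               class = "dbtriage_config_error")
  expect_error(sweep_thresholds(synth, "combination", c(5, 3)),
               class = "dbtriage_config_error")
})

test_that("operating points bound the sweep and match direct arithmetic", {
  cohort <- build_fixture_cohort(seed = 1)
  pts <- operating_points(cohort)
  dm <- pts[pts$workflow == "dm_only", ]
  expect_equal(dm$sensitivity, 95 / 136)
  expect_equal(dm$specificity, (14632 - 271) / 14632)
  expect_equal(pts$sensitivity[pts$workflow == "full_both"], 1)
  # sweep endpoints coincide with the dm_only and full_both points
  ends <- sweep_thresholds(cohort, "combination", c(0, 10))
  expect_equal(ends$sensitivity, c(1, 95 / 136))
  expect_equal(ends$specificity,
               c((14632 - 521) / 14632, (14632 - 271) / 14632))

  all_recall <- toy_cohort()
  all_recall$dm_recall <- TRUE
  pts2 <- operating_points(all_recall)
  expect_equal(pts2$sensitivity[pts2$workflow == "dm_only"], 1)
  expect_equal(pts2$specificity[pts2$workflow == "dm_only"], 0)
  degenerate <- toy_cohort()
  degenerate$has_cancer <- TRUE
  expect_error(operating_points(degenerate), class = "dbtriage_cohort_error")
})

test_that("percent display rounding is half away from zero", {
  expect_equal(round_half_up(58.5), 59)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(16.075, 1), 16.1)
  expect_equal(round_half_up(9.536, 2), 9.54)
})
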
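#' Round half away from zero
#'
#' Commercial rounding used for displayed percentages and rates: halves are
#' rounded away from zero rather than to even, so 58.5 becomes 59.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector; internal computations always keep full precision.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval for a binomial proportion obtained from beta quantiles:
#' lower bound `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). Equivalent to
#' inverting the binomial tail probabilities.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return A `proportion_ci` list: `numerator`, `denominator`, `point`,
#'   `lower`, `upper`, `level`, `method`.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) || n < 1) {
    rlang::abort("clopper_pearson requires scalar x and n with n >= 1",
                 class = "dbtriage_ci_error")
  }
  if (x < 0 || x > n) {
    rlang::abort("x must satisfy 0 <= x <= n", class = "dbtriage_ci_error")
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(numerator = x, denominator = n, point = x / n,
                 lower = lower, upper = upper, level = level,
                 method = "clopper_pearson"),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %d%% [%.2f; %.2f] (%g%% Clopper-Pearson)\n",
              x$numerator, x$denominator, round_half_up(100 * x$point),
              x$lower, x$upper, 100 * x$level))
  invisible(x)
}

#' Format a proportion with its interval the way the study tables print it
#'
#' Point as an integer percent, bounds as 2-decimal proportions.
#'
#' @param ci A `proportion_ci`.
#' @return A string such as `"70% [0.61; 0.77]"`.
#' @export
format_ci <- function(ci) {
  sprintf("%d%% [%.2f; %.2f]", round_half_up(100 * ci$point),
          round_half_up(ci$lower, 2), round_half_up(ci$upper, 2))
}

#' Full outcome summary of a strategy against its baselines
#'
#' Extends the raw counts of [evaluate_cohort()] with the comparative
#' quantities of the study: extra cancers and false positives relative to
#' DM-only reading of the same cohort, cancers missed relative to reading
#' everyone with both modalities, percent increases, positive predictive
#' value, detection rates per 1000 (overall, and per 1000 women with DBT
#' added), sensitivity and specificity. All values carry full precision;
#' rounding happens only in display helpers. Fields with a zero denominator
#' are `NA` (flagged, never silently 0).
#'
#' @param cohort A screening cohort.
#' @param config A [triage_config()].
#' @param baselines Optional list with elements `dm_only` and `full_both`,
#'   the [evaluate_cohort()] counts of those strategies on the same cohort;
#'   computed if omitted.
#' @return An `outcome_summary` list.
#' @export
summarize_strategy <- function(cohort, config, baselines = NULL) {
  counts <- evaluate_cohort(cohort, config)
  if (is.null(baselines)) {
    baselines <- list(
      dm_only = evaluate_cohort(cohort, triage_config("dm_only")),
      full_both = evaluate_cohort(cohort, triage_config("full_both"))
    )
  }
  stopifnot(baselines$dm_only$n_total == counts$n_total,
            baselines$full_both$n_total == counts$n_total)
  ratio <- function(num, den) if (!is.na(den) && den > 0) num / den else NA_real_
  extra <- counts$detected - baselines$dm_only$detected
  fp_extra <- counts$fp_total - baselines$dm_only$fp_total
  n_noncancer <- counts$n_total - counts$n_cancer
  structure(list(
    strategy = counts$strategy,
    workflow = config$workflow,
    threshold = if (is.null(config$threshold)) NA_real_ else config$threshold,
    detected = counts$detected,
    extra_vs_dm = extra,
    pct_increase_vs_dm = 100 * ratio(extra, baselines$dm_only$detected),
    missed_vs_full = baselines$full_both$detected - counts$detected,
    fp_total = counts$fp_total,
    fp_extra_vs_dm = fp_extra,
    pct_fp_increase = 100 * ratio(fp_extra, baselines$dm_only$fp_total),
    ppv = ratio(counts$detected, counts$detected + counts$fp_total),
    n_dbt_exams = counts$n_dbt_exams,
    n_dm_read = counts$n_dm_read,
    rate_added_per1000 = 1000 * ratio(extra, counts$n_dbt_exams),
    rate_total_per1000 = 1000 * ratio(counts$detected, counts$n_total),
    sensitivity = ratio(counts$detected, counts$n_cancer),
    specificity = if (n_noncancer > 0) 1 - counts$fp_total / n_noncancer
                  else NA_real_,
    n_total = counts$n_total,
    n_cancer = counts$n_cancer,
    empty = counts$empty
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Strategy %s on %d women (%d cancers)\n",
              x$strategy, x$n_total, x$n_cancer))
  cat(sprintf("  detected %d (extra vs DM %+d, %s%%), missed vs both %d\n",
              x$detected, x$extra_vs_dm,
              format(round_half_up(x$pct_increase_vs_dm)), x$missed_vs_full))
  cat(sprintf("  false positives %d (extra vs DM %+d, %s%%), PPV %.3f\n",
              x$fp_total, x$fp_extra_vs_dm,
              format(round_half_up(x$pct_fp_increase)), x$ppv))
  cat(sprintf("  DBT exams %d, DM reads %d; rates %.1f added / %.1f total per 1000\n",
              x$n_dbt_exams, x$n_dm_read,
              x$rate_added_per1000, x$rate_total_per1000))
  invisible(x)
}

#' One-row tibble view of an outcome summary
#'
#' @param summary An `outcome_summary`.
#' @return A one-row tibble with every summary field.
#' @export
summary_row <- function(summary) {
  as_tibble(summary[c("strategy", "workflow", "threshold", "detected",
                      "extra_vs_dm", "pct_increase_vs_dm", "missed_vs_full",
                      "fp_total", "fp_extra_vs_dm", "pct_fp_increase", "ppv",
                      "n_dbt_exams", "n_dm_read", "rate_added_per1000",
                      "rate_total_per1000", "sensitivity", "specificity")])
}

#' Sweep a gated workflow across a threshold grid
#'
#' Evaluates `combination` or `precedence` at every threshold of the grid and
#' returns one summary per threshold. At thresholds at or above the maximum
#' score the gated workflows coincide with DM-only; below the minimum score
#' combination coincides with reading both modalities for everyone and
#' precedence with DBT-only.
#'
#' @param cohort A screening cohort.
#' @param workflow `"combination"` or `"precedence"`.
#' @param grid Nonempty increasing numeric vector of thresholds in `[0, 10]`.
#' @return A `sweep_curve` tibble: `threshold` plus all summary columns.
#' @export
sweep_thresholds <- function(cohort, workflow = c("combination", "precedence"),
                             grid) {
  workflow <- match.arg(workflow)
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    rlang::abort("grid must be nonempty and strictly increasing",
                 class = "dbtriage_config_error")
  }
  baselines <- list(
    dm_only = evaluate_cohort(cohort, triage_config("dm_only")),
    full_both = evaluate_cohort(cohort, triage_config("full_both"))
  )
  rows <- lapply(grid, function(t) {
    s <- summarize_strategy(cohort, triage_config(workflow, t), baselines)
    row <- summary_row(s)
    row$threshold <- t
    row
  })
  curve <- do.call(rbind, rows)
  structure(curve, class = c("sweep_curve", class(curve)),
            workflow = workflow)
}

#' Operating points of the three ungated reading strategies
#'
#' Sensitivity/specificity pairs for DM-only, DBT-only and reading both
#' modalities for everyone; the gated sweep curves run between these points.
#'
#' @param cohort A screening cohort with at least one cancer and one
#'   non-cancer.
#' @return A tibble with columns `workflow`, `sensitivity`, `specificity`.
#' @export
operating_points <- function(cohort) {
  n_cancer <- sum(cohort$has_cancer)
  if (n_cancer == 0 || n_cancer == nrow(cohort)) {
    rlang::abort("operating points need at least one cancer and one non-cancer",
                 class = "dbtriage_cohort_error")
  }
  rows <- lapply(c("dm_only", "dbt_only", "full_both"), function(w) {
    s <- summarize_strategy(cohort, triage_config(w))
    tibble(workflow = w, sensitivity = s$sensitivity,
           specificity = s$specificity)
  })
  do.call(rbind, rows)
}

#' Headline strategy table
#'
#' One row per strategy: DM only, the two gated workflows at each requested
#' threshold, reading both modalities for everyone, and DBT only — with
#' detected/extra cancers, false positives, percent increases, PPV, and
#' examination counts.
#'
#' @param cohort A screening cohort.
#' @param thresholds Thresholds for the gated workflows (default 9.0 and 7.5).
#' @return A tibble, one row per strategy.
#' @export
strategy_table <- function(cohort, thresholds = c(9.0, 7.5)) {
  baselines <- list(
    dm_only = evaluate_cohort(cohort, triage_config("dm_only")),
    full_both = evaluate_cohort(cohort, triage_config("full_both"))
  )
  configs <- c(
    list(triage_config("dm_only")),
    unlist(lapply(thresholds, function(t) {
      list(triage_config("combination", t), triage_config("precedence", t))
    }), recursive = FALSE),
    list(triage_config("full_both"), triage_config("dbt_only"))
  )
  rows <- lapply(configs, function(cf) {
    summary_row(summarize_strategy(cohort, cf, baselines))
  })
  do.call(rbind, rows)
}
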
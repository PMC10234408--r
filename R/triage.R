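#' Triage policy configuration
#'
#' Five strategies are supported. `dm_only`: everyone screened and read with
#' DM alone. `dbt_only`: everyone screened and read with DBT alone (no DM
#' performed). `full_both`: everyone receives both examinations, recall is the
#' union of the two arms. `combination`: DBT is added when the AI score
#' strictly exceeds the threshold and the recall decision is the union of the
#' DM and DBT readings; below the threshold DM alone decides. `precedence`:
#' DBT is added when the score strictly exceeds the threshold and then the DBT
#' reading alone decides (the DM examination is still performed but not read);
#' below the threshold DM alone decides.
#'
#' @param workflow One of `"dm_only"`, `"dbt_only"`, `"full_both"`,
#'   `"combination"`, `"precedence"`.
#' @param threshold AI-score threshold in `[0, 10]`; required for (and only
#'   used by) `combination` and `precedence`. Comparison is strict
#'   (`score > threshold`); ties at the threshold do not trigger DBT.
#' @return A `triage_config` object.
#' @export
triage_config <- function(workflow = c("dm_only", "dbt_only", "full_both",
                                       "combination", "precedence"),
                          threshold = NULL) {
  workflow <- match.arg(workflow)
  gated <- workflow %in% c("combination", "precedence")
  if (gated && is.null(threshold)) {
    rlang::abort(paste0("workflow '", workflow, "' requires a threshold"),
                 class = "dbtriage_config_error")
  }
  if (!gated) threshold <- NULL
  if (!is.null(threshold) &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 10)) {
    rlang::abort("threshold must be a number in [0, 10]",
                 class = "dbtriage_config_error")
  }
  structure(list(workflow = workflow, threshold = threshold,
                 comparison = "strict_greater"),
            class = "triage_config")
}

#' @export
print.triage_config <- function(x, ...) {
  cat(sprintf("Triage policy: %s%s\n", x$workflow,
              if (!is.null(x$threshold))
                sprintf(" (DBT if AI score > %s)", format(x$threshold))
              else ""))
  invisible(x)
}

strategy_label <- function(config) {
  if (is.null(config$threshold)) config$workflow
  else sprintf("%s@%s", config$workflow, format(config$threshold))
}

#' Per-woman triage outcomes under a policy
#'
#' Applies the recall logic of the policy to every record and classifies each
#' woman as TP, FP, FN or TN. Also reports whether a DBT examination is
#' performed and whether the DM examination is read under the policy.
#'
#' @param cohort A screening cohort.
#' @param config A [triage_config()].
#' @return A tibble with columns `woman_id`, `dbt_performed`, `dm_read`,
#'   `recalled`, `outcome_class`.
#' @export
triage_outcomes <- function(cohort, config) {
  stopifnot(inherits(config, "triage_config"))
  n <- nrow(cohort)
  above <- if (!is.null(config$threshold)) {
    cohort$ai_score > config$threshold
  } else {
    rep(FALSE, n)
  }
  recalled <- switch(
    config$workflow,
    dm_only = cohort$dm_recall,
    dbt_only = cohort$dbt_recall,
    full_both = cohort$dm_recall | cohort$dbt_recall,
    combination = ifelse(above, cohort$dm_recall | cohort$dbt_recall,
                         cohort$dm_recall),
    precedence = ifelse(above, cohort$dbt_recall, cohort$dm_recall)
  )
  dbt_performed <- switch(
    config$workflow,
    dm_only = rep(FALSE, n),
    dbt_only = rep(TRUE, n),
    full_both = rep(TRUE, n),
    combination = above,
    precedence = above
  )
  dm_read <- switch(
    config$workflow,
    dm_only = rep(TRUE, n),
    dbt_only = rep(FALSE, n),
    full_both = rep(TRUE, n),
    combination = rep(TRUE, n),
    precedence = !above
  )
  outcome_class <- ifelse(cohort$has_cancer,
                          ifelse(recalled, "TP", "FN"),
                          ifelse(recalled, "FP", "TN"))
  tibble(woman_id = cohort$woman_id,
         dbt_performed = as.logical(dbt_performed),
         dm_read = as.logical(dm_read),
         recalled = as.logical(recalled),
         outcome_class = outcome_class)
}

#' Triage outcome for a single screening record
#'
#' Single-record convenience wrapper around [triage_outcomes()].
#'
#' @param record A one-row cohort data frame (or a list with the core fields).
#' @param config A [triage_config()].
#' @return A one-row tibble, see [triage_outcomes()].
#' @export
evaluate_woman <- function(record, config) {
  record <- as_tibble(as.list(record)[c("woman_id", "has_cancer", "dm_recall",
                                        "dbt_recall", "ai_score")])
  triage_outcomes(record, config)
}

#' Aggregate triage outcomes over a cohort
#'
#' Counts detected cancers (true positives), false positives, missed cancers,
#' true negatives, DBT examinations performed and DM examinations read under
#' the policy.
#'
#' @param cohort A screening cohort.
#' @param config A [triage_config()].
#' @return A list of counts with class `outcome_counts`: `detected`,
#'   `fp_total`, `missed`, `tn`, `n_dbt_exams`, `n_dm_read`, `n_total`,
#'   `n_cancer`, `empty`.
#' @export
evaluate_cohort <- function(cohort, config) {
  if (nrow(cohort) == 0) {
    return(structure(list(detected = 0L, fp_total = 0L, missed = 0L, tn = 0L,
                          n_dbt_exams = 0L, n_dm_read = 0L, n_total = 0L,
                          n_cancer = 0L, empty = TRUE,
                          strategy = strategy_label(config)),
                     class = "outcome_counts"))
  }
  out <- triage_outcomes(cohort, config)
  structure(list(
    detected = sum(out$outcome_class == "TP"),
    fp_total = sum(out$outcome_class == "FP"),
    missed = sum(out$outcome_class == "FN"),
    tn = sum(out$outcome_class == "TN"),
    n_dbt_exams = sum(out$dbt_performed),
    n_dm_read = sum(out$dm_read),
    n_total = nrow(cohort),
    n_cancer = sum(cohort$has_cancer),
    empty = FALSE,
    strategy = strategy_label(config)
  ), class = "outcome_counts")
}

#' @export
print.outcome_counts <- function(x, ...) {
  cat(sprintf(
    "%s: %d detected / %d missed cancers, %d false positives; %d DBT exams, %d DM reads (n = %d)\n",
    x$strategy, x$detected, x$missed, x$fp_total, x$n_dbt_exams, x$n_dm_read,
    x$n_total))
  invisible(x)
}
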
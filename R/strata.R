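#' Per-stratum detected / extra / missed cancer breakdown
#'
#' For every level of every characteristic axis present on the cohort's
#' cancers, counts the cancers detected on DM, and per strategy the cancers
#' detected, the extra detections relative to DM-only and the misses relative
#' to reading both modalities for everyone — each with an exact
#' Clopper-Pearson interval on the proportion of the stratum total. Cancers
#' with a missing value on an axis are grouped under an explicit `"missing"`
#' level, so within each axis the level totals sum to the cohort cancer count.
#'
#' @param cohort A screening cohort whose cancer records carry characteristic
#'   columns (see [assign_characteristics()]).
#' @param strategies List of [triage_config()] objects to evaluate.
#' @param level Confidence level for the intervals.
#' @return A long-format tibble: `axis`, `level`, `strategy`, `metric`
#'   (`all`, `dm_detected`, `detected`, `extra`, `missed`), `count`,
#'   `proportion`, `ci_lower`, `ci_upper`. Zero rows (with a warning) when no
#'   characteristic axis is present.
#' @export
characteristics_table <- function(cohort,
                                  strategies = list(
                                    triage_config("combination", 9.0),
                                    triage_config("combination", 7.5)),
                                  level = 0.95) {
  empty <- tibble(axis = character(0), level = character(0),
                  strategy = character(0), metric = character(0),
                  count = integer(0), proportion = numeric(0),
                  ci_lower = numeric(0), ci_upper = numeric(0))
  axes <- intersect(characteristic_axes(), names(cohort))
  cancers <- cohort[cohort$has_cancer, , drop = FALSE]
  if (length(axes) == 0 || nrow(cancers) == 0) {
    warning("cohort carries no cancer characteristics; empty table")
    return(empty)
  }
  dm_detected <- cancers$dm_recall
  full_detected <- cancers$dm_recall | cancers$dbt_recall
  per_strategy <- lapply(strategies, function(cf) {
    out <- triage_outcomes(cancers, cf)
    out$outcome_class == "TP"
  })
  names(per_strategy) <- vapply(strategies, strategy_label, character(1))

  rows <- list()
  emit <- function(axis, lvl, strategy, metric, x, n) {
    ci <- clopper_pearson(x, n, level)
    rows[[length(rows) + 1]] <<- tibble(
      axis = axis, level = lvl, strategy = strategy, metric = metric,
      count = as.integer(x), proportion = ci$point,
      ci_lower = ci$lower, ci_upper = ci$upper)
  }
  for (axis in axes) {
    vals <- as.character(cancers[[axis]])
    vals[is.na(vals) | vals == ""] <- "missing"
    for (lvl in unique(vals)) {
      in_level <- vals == lvl
      n <- sum(in_level)
      emit(axis, lvl, NA_character_, "all", n, n)
      emit(axis, lvl, NA_character_, "dm_detected",
           sum(dm_detected & in_level), n)
      for (snm in names(per_strategy)) {
        det <- per_strategy[[snm]]
        emit(axis, lvl, snm, "detected", sum(det & in_level), n)
        emit(axis, lvl, snm, "extra",
             sum(det & !dm_detected & in_level), n)
        emit(axis, lvl, snm, "missed",
             sum(full_detected & !det & in_level), n)
      }
    }
  }
  do.call(rbind, rows)
}
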
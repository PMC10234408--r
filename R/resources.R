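#' Organ-dose distribution parameters
#'
#' Reference organ doses per examination, in mGy: two-view DM mean 2.69
#' (SD 0.778), one-view DBT mean 2.24 (SD 0.672); a woman examined with both
#' averages 4.91 mGy (SD 1.347). Simulated doses are drawn from normal
#' distributions truncated at zero, independent of the AI score.
#'
#' @param dm_mean_mGy,dm_sd DM exam organ dose mean and SD.
#' @param dbt_mean_mGy,dbt_sd DBT exam organ dose mean and SD.
#' @param both_mean_mGy,both_sd Reference mean and SD for DM + DBT combined.
#' @return A `dose_params` object.
#' @export
dose_params <- function(dm_mean_mGy = 2.69, dm_sd = 0.778,
                        dbt_mean_mGy = 2.24, dbt_sd = 0.672,
                        both_mean_mGy = 4.91, both_sd = 1.347) {
  if (any(c(dm_mean_mGy, dbt_mean_mGy, both_mean_mGy) <= 0) ||
      any(c(dm_sd, dbt_sd, both_sd) < 0)) {
    rlang::abort("dose means must be positive and SDs nonnegative",
                 class = "dbtriage_params_error")
  }
  structure(list(dm_mean_mGy = dm_mean_mGy, dm_sd = dm_sd,
                 dbt_mean_mGy = dbt_mean_mGy, dbt_sd = dbt_sd,
                 both_mean_mGy = both_mean_mGy, both_sd = both_sd,
                 family = "truncnorm0"),
            class = "dose_params")
}

#' Relative reading-time multipliers
#'
#' Reading a one-view DBT examination instead of a two-view DM is taken to
#' cost 1.75 times the DM reading time; reading both together 2.25 times.
#'
#' @param rel_dbt_alone Relative cost of reading DBT instead of DM (>= 1).
#' @param rel_dm_plus_dbt Relative cost of reading DM and DBT together (>= 1).
#' @return A `reading_time_params` object.
#' @export
reading_time_params <- function(rel_dbt_alone = 1.75, rel_dm_plus_dbt = 2.25) {
  if (rel_dbt_alone < 1 || rel_dm_plus_dbt < 1) {
    rlang::abort("reading-time multipliers must be >= 1",
                 class = "dbtriage_params_error")
  }
  structure(list(rel_dbt_alone = rel_dbt_alone,
                 rel_dm_plus_dbt = rel_dm_plus_dbt),
            class = "reading_time_params")
}

#' Population mean organ dose under a strategy
#'
#' Mean (and SD) over all women of the dose actually delivered under the
#' policy: the DM dose accrues for every workflow except DBT-only (under
#' precedence the DM examination is performed even when not read), and the
#' DBT dose accrues whenever a DBT examination is performed.
#'
#' @param cohort A screening cohort with dose columns.
#' @param config A [triage_config()].
#' @return A list with `mean_mGy`, `sd_mGy`, `n`.
#' @export
population_mean_dose <- function(cohort, config) {
  bad <- !is.finite(cohort$dose_dm_mGy) | !is.finite(cohort$dose_dbt_mGy)
  if (any(bad)) {
    rlang::abort(
      paste("missing dose fields on records:",
            paste(utils::head(cohort$woman_id[bad], 10), collapse = ", ")),
      class = "dbtriage_cohort_error")
  }
  out <- triage_outcomes(cohort, config)
  dm_performed <- config$workflow != "dbt_only"
  dose <- cohort$dose_dm_mGy * dm_performed +
    cohort$dose_dbt_mGy * out$dbt_performed
  list(mean_mGy = mean(dose), sd_mGy = stats::sd(dose), n = nrow(cohort))
}

#' Relative change in total screening reading time
#'
#' Percent change versus reading DM for everyone when a fraction of the
#' population is converted to the gated arm of a workflow. For the
#' combination workflow each converted woman costs `rel_dm_plus_dbt` instead
#' of 1, for precedence `rel_dbt_alone` instead of 1; reading both for
#' everyone and DBT-only correspond to a fully converted population, DM-only
#' to none.
#'
#' @param fraction_converted Proportion of women whose examination gains DBT,
#'   in `[0, 1]`. Ignored for the ungated workflows.
#' @param workflow One of the five strategy names.
#' @param params A [reading_time_params()].
#' @return Percent change in total reading time (full precision).
#' @export
reading_time_change <- function(fraction_converted,
                                workflow = c("combination", "precedence",
                                             "dm_only", "dbt_only",
                                             "full_both"),
                                params = reading_time_params()) {
  workflow <- match.arg(workflow)
  if (any(fraction_converted < 0 | fraction_converted > 1)) {
    rlang::abort("fraction_converted must lie in [0, 1]",
                 class = "dbtriage_params_error")
  }
  switch(workflow,
         dm_only = 0 * fraction_converted,
         combination = fraction_converted * (params$rel_dm_plus_dbt - 1) * 100,
         precedence = fraction_converted * (params$rel_dbt_alone - 1) * 100,
         full_both = rep((params$rel_dm_plus_dbt - 1) * 100,
                         length(fraction_converted)),
         dbt_only = rep((params$rel_dbt_alone - 1) * 100,
                        length(fraction_converted)))
}
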
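# Pipeline entry points: each writes delimited/JSON artifacts under an output
# directory and logs seed, parameter digest and package version to stderr so a
# run can be reproduced exactly. Results go to files, logs to stderr, never
# interleaved.

log_run <- function(what, seed, digest) {
  message(sprintf("[dbtriage %s] %s: seed=%s params=%s",
                  as.character(utils::packageVersion("dbtriage")), what,
                  format(seed), digest))
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Build and write the deterministic fixture cohort
#'
#' Writes the cohort table and a constraint-satisfaction report proving that
#' every constraint field re-tallies exactly from the written records.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the dose draws.
#' @param constraints A [fixture_constraints()] object.
#' @param characteristics Assign the published characteristic columns (only
#'   valid with the default constraints).
#' @return Invisibly, a list with the cohort and the report tibble.
#' @export
run_fixture <- function(out_dir, seed = 1L, constraints = trial_constraints(),
                        characteristics = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- build_fixture_cohort(constraints, seed = seed)
  if (characteristics) cohort <- assign_characteristics(cohort)
  log_run("fixture", seed, attr(cohort, "params_digest"))
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  thresholds <- vapply(constraints$blocks, function(b) b$threshold, numeric(1))
  observed <- tally_constraints(cohort, thresholds)
  report <- constraint_report(constraints, observed)
  write_tsv(report, file.path(out_dir, "fixture_report.tsv"))
  if (!all(report$satisfied)) {
    rlang::abort("fixture failed its own constraint re-tally",
                 class = "dbtriage_constraint_error")
  }
  invisible(list(cohort = cohort, report = report))
}

constraint_report <- function(expected, observed) {
  flat <- function(x) {
    base <- unlist(x[c("n_total", "n_cancer", "n_dm_detected", "n_dbt_detected",
                       "n_both_detected", "n_dm_fp", "n_dbt_fp", "n_union_fp")])
    blk <- unlist(lapply(x$blocks, function(b) {
      v <- unlist(b[c("n_above", "n_dbtonly_cancer_above",
                      "n_dmonly_cancer_above", "n_dbtonly_fp_above",
                      "n_dmonly_fp_above")])
      stats::setNames(v, paste0("t", format(b$threshold), ".", names(v)))
    }))
    c(base, blk)
  }
  e <- flat(expected)
  o <- flat(observed)
  tibble(constraint = names(e), expected = unname(e),
         observed = unname(o[names(e)]),
         satisfied = unname(e == o[names(e)]))
}

#' Simulate and write a synthetic cohort
#'
#' @param out_dir Output directory.
#' @param params A [sim_params()] object.
#' @return Invisibly, the cohort.
#' @export
run_simulate <- function(out_dir, params = sim_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(params)
  log_run("simulate", params$seed, attr(cohort, "params_digest"))
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  invisible(cohort)
}

#' Evaluate strategies on a cohort and write the results document
#'
#' Writes a flat strategy table (TSV, one row per strategy) and a structured
#' JSON document with every summary field plus the dose and reading-time
#' resource estimates per strategy.
#'
#' @param cohort A screening cohort.
#' @param out_dir Output directory.
#' @param thresholds Thresholds for the gated workflows.
#' @param reading_params A [reading_time_params()].
#' @return Invisibly, the strategy table.
#' @export
run_evaluate <- function(cohort, out_dir, thresholds = c(9.0, 7.5),
                         reading_params = reading_time_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_run("evaluate", attr(cohort, "seed"), attr(cohort, "params_digest"))
  tab <- strategy_table(cohort, thresholds)
  write_tsv(tab, file.path(out_dir, "strategy_table.tsv"))
  configs <- Map(function(w, t) {
    if (is.na(t)) triage_config(w) else triage_config(w, t)
  }, tab$workflow, tab$threshold)
  docs <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    s <- unclass(summarize_strategy(cohort, cf))
    dose <- population_mean_dose(cohort, cf)
    s$dose_mean_mGy <- dose$mean_mGy
    s$dose_sd_mGy <- dose$sd_mGy
    fraction <- if (cf$workflow %in% c("combination", "precedence")) {
      mean(cohort$ai_score > cf$threshold)
    } else 1
    s$reading_time_change_pct <-
      reading_time_change(fraction, cf$workflow, reading_params)
    s
  })
  names(docs) <- tab$strategy
  jsonlite::write_json(docs, file.path(out_dir, "strategies.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tab)
}

#' Sweep thresholds and write curve tables
#'
#' One row per threshold with the summary metrics (detected, missed, false
#' positives, proportion of women with DBT added, added-DBT detection rate,
#' sensitivity, specificity) for both gated workflows.
#'
#' @param cohort A screening cohort.
#' @param out_dir Output directory.
#' @param grid Increasing threshold grid inside `[0, 10]`.
#' @return Invisibly, a named list of the two sweep tibbles.
#' @export
run_sweep <- function(cohort, out_dir, grid = seq(1, 10, by = 0.5)) {
  if (any(grid < 0 | grid > 10)) {
    rlang::abort("sweep grid must lie inside [0, 10]",
                 class = "dbtriage_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_run("sweep", attr(cohort, "seed"), attr(cohort, "params_digest"))
  curves <- lapply(c(combination = "combination", precedence = "precedence"),
                   function(w) {
    curve <- sweep_thresholds(cohort, w, grid)
    curve$prop_dbt_added <- curve$n_dbt_exams / nrow(cohort)
    write_tsv(curve, file.path(out_dir, paste0("sweep_", w, ".tsv")))
    curve
  })
  invisible(curves)
}

#' Write the per-stratum characteristics table
#'
#' @param cohort A screening cohort with characteristic columns.
#' @param out_dir Output directory.
#' @param strategies Strategies to break down (default: combination at 9.0
#'   and 7.5).
#' @return Invisibly, the long-format table.
#' @export
run_strata <- function(cohort, out_dir,
                       strategies = list(triage_config("combination", 9.0),
                                         triage_config("combination", 7.5))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_run("strata", attr(cohort, "seed"), attr(cohort, "params_digest"))
  tab <- characteristics_table(cohort, strategies)
  write_tsv(tab, file.path(out_dir, "strata.tsv"))
  invisible(tab)
}

#' Full report: fixture (or given cohort), strategies, sweep, strata
#'
#' @param out_dir Output directory.
#' @param cohort Optional cohort; the deterministic fixture is built when
#'   omitted.
#' @param seed Seed used when building the fixture.
#' @return Invisibly, the strategy table.
#' @export
run_report <- function(out_dir, cohort = NULL, seed = 1L) {
  if (is.null(cohort)) {
    cohort <- trial_fixture(seed = seed)
  }
  tab <- run_evaluate(cohort, out_dir)
  run_sweep(cohort, out_dir)
  if (any(characteristic_axes() %in% names(cohort))) {
    run_strata(cohort, out_dir)
  }
  invisible(tab)
}
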
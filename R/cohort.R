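#' @importFrom tibble tibble as_tibble
NULL

characteristic_axes <- function() {
  c("invasiveness", "density", "histology", "histological_grade",
    "nuclear_grade", "size_cat", "node_status", "appearance")
}

cohort_core_columns <- function() {
  c("woman_id", "has_cancer", "dm_recall", "dbt_recall", "ai_score",
    "dose_dm_mGy", "dose_dbt_mGy")
}

#' Construct a screening cohort
#'
#' A screening cohort is a tibble with one row per screened woman: an opaque
#' `woman_id`, cancer status, the recall decision of each double-reading arm,
#' the decimal AI risk score in (0, 10], per-modality organ doses in mGy, and
#' optional cancer-characteristic columns (present only for cancers).
#' Provenance (fixture / simulated / loaded), the seed and a parameter digest
#' are carried as attributes so a run can be reproduced exactly.
#'
#' @param records Data frame with at least the core columns
#'   `woman_id, has_cancer, dm_recall, dbt_recall, ai_score, dose_dm_mGy,
#'   dose_dbt_mGy`.
#' @param provenance One of `"fixture"`, `"simulated"`, `"loaded"`.
#' @param seed Integer seed used to generate the cohort, or `NA`.
#' @param params_digest Short hash of the generating parameters, or `NA`.
#' @return A `screening_cohort` tibble.
#' @export
screening_cohort <- function(records,
                             provenance = c("loaded", "fixture", "simulated"),
                             seed = NA_integer_, params_digest = NA_character_) {
  provenance <- match.arg(provenance)
  records <- as_tibble(records)
  missing_cols <- setdiff(cohort_core_columns(), names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("cohort is missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "dbtriage_cohort_error")
  }
  records$woman_id <- as.character(records$woman_id)
  for (col in c("has_cancer", "dm_recall", "dbt_recall")) {
    records[[col]] <- as.logical(records[[col]])
  }
  structure(
    records,
    class = c("screening_cohort", class(records)),
    provenance = provenance,
    seed = as.integer(seed),
    params_digest = params_digest
  )
}

#' @export
print.screening_cohort <- function(x, ...) {
  cat(sprintf(
    "A screening cohort of %d women (%s%s): %d cancers, %d DM recalls, %d DBT recalls\n",
    nrow(x), attr(x, "provenance"),
    if (!is.na(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else "",
    sum(x$has_cancer), sum(x$dm_recall), sum(x$dbt_recall)))
  NextMethod()
}

#' Validate a screening cohort
#'
#' Report-style check of the per-record invariants: AI scores strictly in
#' (0, 10], nonnegative doses, characteristics only on cancer records,
#' no missing core fields, and unique woman identifiers. Violations are
#' reported, not raised.
#'
#' @param cohort A cohort data frame.
#' @return A tibble with columns `woman_id`, `rule`, `detail`; zero rows iff
#'   the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  violations <- list()
  add <- function(ids, rule, detail) {
    if (length(ids) > 0) {
      violations[[length(violations) + 1]] <<-
        tibble(woman_id = as.character(ids), rule = rule, detail = detail)
    }
  }
  id <- as.character(cohort$woman_id)
  add(id[duplicated(id)], "unique_woman_id", "duplicate identifier")
  bad_score <- !is.finite(cohort$ai_score) |
    cohort$ai_score <= 0 | cohort$ai_score > 10
  add(id[bad_score], "ai_score_in_(0,10]",
      "ai_score must be > 0 and <= 10")
  for (col in c("dose_dm_mGy", "dose_dbt_mGy")) {
    bad <- !is.finite(cohort[[col]]) | cohort[[col]] < 0
    add(id[bad], paste0(col, "_nonnegative"), "dose must be a nonnegative real")
  }
  for (col in c("has_cancer", "dm_recall", "dbt_recall")) {
    add(id[is.na(cohort[[col]])], paste0(col, "_not_missing"),
        "boolean flag missing")
  }
  present_axes <- intersect(characteristic_axes(), names(cohort))
  if (length(present_axes) > 0) {
    has_chr <- Reduce(`|`, lapply(present_axes, function(a) {
      v <- cohort[[a]]
      !is.na(v) & v != ""
    }))
    add(id[has_chr & !cohort$has_cancer], "characteristics_imply_cancer",
        "characteristics present on a non-cancer record")
  }
  if (length(violations) == 0) {
    tibble(woman_id = character(0), rule = character(0), detail = character(0))
  } else {
    do.call(rbind, violations)
  }
}

#' Write a cohort table to delimited text
#'
#' Tab-separated, one row per woman, booleans encoded 0/1, scores with four
#' and doses with six decimals, missing characteristics as empty fields. The
#' fixed formatting makes write-read-write round trips byte-identical.
#'
#' @param cohort A screening cohort.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in c("has_cancer", "dm_recall", "dbt_recall")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$ai_score <- sprintf("%.4f", out$ai_score)
  out$dose_dm_mGy <- sprintf("%.6f", out$dose_dm_mGy)
  out$dose_dbt_mGy <- sprintf("%.6f", out$dose_dbt_mGy)
  for (a in intersect(characteristic_axes(), names(out))) {
    v <- as.character(out[[a]])
    v[is.na(v)] <- ""
    out[[a]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path Input file path.
#' @return A `screening_cohort` with provenance `"loaded"`.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  for (col in c("has_cancer", "dm_recall", "dbt_recall")) {
    raw[[col]] <- raw[[col]] == "1"
  }
  for (col in c("ai_score", "dose_dm_mGy", "dose_dbt_mGy")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  for (a in intersect(characteristic_axes(), names(raw))) {
    raw[[a]][raw[[a]] == ""] <- NA_character_
  }
  screening_cohort(raw, provenance = "loaded")
}

params_digest <- function(x) {
  substr(rlang::hash(x), 1, 12)
}
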
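#' Joint recall-count constraints for a deterministic fixture cohort
#'
#' A `fixture_constraints` object records the printed joint counts that a
#' deterministic screening cohort must reproduce exactly: cohort size, cancer
#' count, per-arm detection marginals and their overlap, per-arm false-positive
#' counts and their union, and one block per AI-score threshold giving the
#' number of women strictly above that threshold together with the above-
#' threshold counts of DBT-only cancers, DM-only cancers, DBT-only false
#' positives and DM-only false positives.
#'
#' Threshold blocks must be supplied at strictly decreasing thresholds and be
#' componentwise monotone: a count above a higher threshold can never exceed
#' the same count above a lower threshold.
#'
#' @param n_total Number of screened women.
#' @param n_cancer Number of women with screen-detectable cancer.
#' @param n_dm_detected Cancers recalled in the DM double-reading arm.
#' @param n_dbt_detected Cancers recalled in the DBT double-reading arm.
#' @param n_both_detected Cancers recalled in both arms.
#' @param n_dm_fp False positives in the DM arm.
#' @param n_dbt_fp False positives in the DBT arm.
#' @param n_union_fp Women recalled in at least one arm without cancer.
#' @param blocks List of per-threshold blocks; each block is a list with
#'   elements `threshold`, `n_above`, `n_dbtonly_cancer_above`,
#'   `n_dmonly_cancer_above`, `n_dbtonly_fp_above`, `n_dmonly_fp_above`.
#' @param band_scores Optional numeric vector of representative AI scores, one
#'   per score band (above the highest threshold, between consecutive
#'   thresholds, and at or below the lowest threshold). Defaults to band
#'   midpoints. Any value inside a band satisfies the counts; fixed
#'   representatives keep the fixture deterministic.
#'
#' @return A validated `fixture_constraints` object.
#' @seealso [trial_constraints()] for the published default values,
#'   [build_fixture_cohort()] for cohort construction,
#'   [tally_constraints()] to re-derive constraints from a cohort.
#' @export
fixture_constraints <- function(n_total, n_cancer,
                                n_dm_detected, n_dbt_detected, n_both_detected,
                                n_dm_fp, n_dbt_fp, n_union_fp,
                                blocks = list(),
                                band_scores = NULL) {
  x <- structure(
    list(
      n_total = as.integer(n_total),
      n_cancer = as.integer(n_cancer),
      n_dm_detected = as.integer(n_dm_detected),
      n_dbt_detected = as.integer(n_dbt_detected),
      n_both_detected = as.integer(n_both_detected),
      n_dm_fp = as.integer(n_dm_fp),
      n_dbt_fp = as.integer(n_dbt_fp),
      n_union_fp = as.integer(n_union_fp),
      blocks = lapply(blocks, function(b) lapply(b, as.numeric)),
      band_scores = band_scores
    ),
    class = "fixture_constraints"
  )
  validate_constraints(x)
  x
}

#' Published joint counts of the paired DM/DBT screening trial
#'
#' Default constraints for the deterministic fixture: 14,768 screened women,
#' 136 cancers (95 DM-detected, 128 DBT-detected, 87 detected in both arms),
#' 271 DM false positives, 404 DBT false positives with a union of 521, and
#' threshold blocks at AI scores 9.0 and 7.5. Above 9.0 there are 1493 women,
#' of whom 24 are DBT-only-detected cancers, 7 DM-only-detected cancers,
#' 60 DBT-only false positives and 30 DM-only false positives; above 7.5 the
#' corresponding counts are 3251, 31, 8, 103 and 52.
#'
#' Representative in-band scores are 9.5, 8.25 and 4.0.
#'
#' @return A `fixture_constraints` object.
#' @export
trial_constraints <- function() {
  fixture_constraints(
    n_total = 14768, n_cancer = 136,
    n_dm_detected = 95, n_dbt_detected = 128, n_both_detected = 87,
    n_dm_fp = 271, n_dbt_fp = 404, n_union_fp = 521,
    blocks = list(
      list(threshold = 9.0, n_above = 1493,
           n_dbtonly_cancer_above = 24, n_dmonly_cancer_above = 7,
           n_dbtonly_fp_above = 60, n_dmonly_fp_above = 30),
      list(threshold = 7.5, n_above = 3251,
           n_dbtonly_cancer_above = 31, n_dmonly_cancer_above = 8,
           n_dbtonly_fp_above = 103, n_dmonly_fp_above = 52)
    ),
    band_scores = c(9.5, 8.25, 4.0)
  )
}

constraint_error <- function(constraint, detail) {
  rlang::abort(
    message = sprintf("inconsistent fixture constraints: %s (%s)",
                      constraint, detail),
    class = "dbtriage_constraint_error",
    constraint = constraint
  )
}

# Derived category totals implied by the marginal counts.
constraint_categories <- function(x) {
  both_fp <- x$n_dm_fp + x$n_dbt_fp - x$n_union_fp
  list(
    cancer_both = x$n_both_detected,
    cancer_dm_only = x$n_dm_detected - x$n_both_detected,
    cancer_dbt_only = x$n_dbt_detected - x$n_both_detected,
    cancer_neither = x$n_cancer - x$n_dm_detected - x$n_dbt_detected +
      x$n_both_detected,
    fp_both = both_fp,
    fp_dm_only = x$n_dm_fp - both_fp,
    fp_dbt_only = x$n_dbt_fp - both_fp,
    normal_norecall = x$n_total - x$n_cancer - x$n_union_fp
  )
}

validate_constraints <- function(x) {
  counts <- unlist(x[c("n_total", "n_cancer", "n_dm_detected", "n_dbt_detected",
                       "n_both_detected", "n_dm_fp", "n_dbt_fp", "n_union_fp")])
  if (any(is.na(counts)) || any(counts < 0)) {
    constraint_error("nonnegative counts", "a marginal count is negative or NA")
  }
  if (x$n_dm_detected + x$n_dbt_detected - x$n_both_detected > x$n_cancer) {
    constraint_error(
      "n_dm_detected + n_dbt_detected - n_both_detected <= n_cancer",
      sprintf("%d + %d - %d > %d", x$n_dm_detected, x$n_dbt_detected,
              x$n_both_detected, x$n_cancer)
    )
  }
  cats <- constraint_categories(x)
  for (nm in names(cats)) {
    if (cats[[nm]] < 0) {
      constraint_error(paste0("derived category ", nm, " nonnegative"),
                       sprintf("%s = %d", nm, cats[[nm]]))
    }
  }
  if (length(x$blocks) > 0) {
    thr <- vapply(x$blocks, function(b) b$threshold, numeric(1))
    if (is.unsorted(rev(thr), strictly = TRUE)) {
      constraint_error("thresholds strictly decreasing",
                       paste(thr, collapse = ", "))
    }
    fields <- c("n_above", "n_dbtonly_cancer_above", "n_dmonly_cancer_above",
                "n_dbtonly_fp_above", "n_dmonly_fp_above")
    for (f in fields) {
      v <- vapply(x$blocks, function(b) b[[f]], numeric(1))
      if (any(v < 0)) constraint_error(paste0(f, " nonnegative"), f)
      if (is.unsorted(v)) {
        constraint_error(
          paste0(f, " componentwise monotone across thresholds"),
          sprintf("%s = [%s] must be non-decreasing as threshold decreases",
                  f, paste(v, collapse = ", "))
        )
      }
    }
    for (b in x$blocks) {
      comp <- b$n_dbtonly_cancer_above + b$n_dmonly_cancer_above +
        b$n_dbtonly_fp_above + b$n_dmonly_fp_above
      if (comp > b$n_above) {
        constraint_error("component counts <= n_above",
                         sprintf("threshold %s: %d > %d", b$threshold,
                                 comp, b$n_above))
      }
    }
    last <- x$blocks[[length(x$blocks)]]
    lims <- c(n_dbtonly_cancer_above = cats$cancer_dbt_only,
              n_dmonly_cancer_above = cats$cancer_dm_only,
              n_dbtonly_fp_above = cats$fp_dbt_only,
              n_dmonly_fp_above = cats$fp_dm_only)
    for (f in names(lims)) {
      if (last[[f]] > lims[[f]]) {
        constraint_error(
          paste0(f, " <= category total"),
          sprintf("%d above lowest threshold exceeds category total %d",
                  last[[f]], lims[[f]])
        )
      }
    }
    if (last$n_above > x$n_total) {
      constraint_error("n_above <= n_total",
                       sprintf("%d > %d", last$n_above, x$n_total))
    }
  }
  if (!is.null(x$band_scores)) {
    k <- length(x$blocks)
    if (length(x$band_scores) != k + 1) {
      constraint_error("band_scores length equals number of bands",
                       sprintf("expected %d, got %d", k + 1,
                               length(x$band_scores)))
    }
  }
  invisible(x)
}

#' @export
print.fixture_constraints <- function(x, ...) {
  cat("Fixture constraints for a screening cohort\n")
  cat(sprintf("  %d women, %d cancers (DM %d / DBT %d / both %d)\n",
              x$n_total, x$n_cancer, x$n_dm_detected, x$n_dbt_detected,
              x$n_both_detected))
  cat(sprintf("  false positives: DM %d / DBT %d / union %d\n",
              x$n_dm_fp, x$n_dbt_fp, x$n_union_fp))
  for (b in x$blocks) {
    cat(sprintf(
      "  score > %-4s: %d women (cancers DBT-only %d, DM-only %d; FPs DBT-only %d, DM-only %d)\n",
      format(b$threshold), b$n_above, b$n_dbtonly_cancer_above,
      b$n_dmonly_cancer_above, b$n_dbtonly_fp_above, b$n_dmonly_fp_above))
  }
  invisible(x)
}

#' Re-tally fixture constraints from a cohort
#'
#' Recomputes, by direct counting over the cohort records, every quantity a
#' [fixture_constraints()] object specifies, at the given thresholds. Used to
#' verify that a constructed cohort reproduces its constraints exactly.
#'
#' @param cohort A screening cohort (see [build_fixture_cohort()]).
#' @param thresholds Numeric vector of AI-score thresholds, strictly
#'   decreasing.
#' @return A `fixture_constraints` object with counts observed in `cohort`.
#' @export
tally_constraints <- function(cohort, thresholds = numeric(0)) {
  stopifnot(is.data.frame(cohort))
  ca <- cohort$has_cancer
  dm <- cohort$dm_recall
  dbt <- cohort$dbt_recall
  blocks <- lapply(thresholds, function(t) {
    above <- cohort$ai_score > t
    list(
      threshold = t,
      n_above = sum(above),
      n_dbtonly_cancer_above = sum(above & ca & dbt & !dm),
      n_dmonly_cancer_above = sum(above & ca & dm & !dbt),
      n_dbtonly_fp_above = sum(above & !ca & dbt & !dm),
      n_dmonly_fp_above = sum(above & !ca & dm & !dbt)
    )
  })
  fixture_constraints(
    n_total = nrow(cohort),
    n_cancer = sum(ca),
    n_dm_detected = sum(ca & dm),
    n_dbt_detected = sum(ca & dbt),
    n_both_detected = sum(ca & dm & dbt),
    n_dm_fp = sum(!ca & dm),
    n_dbt_fp = sum(!ca & dbt),
    n_union_fp = sum(!ca & (dm | dbt)),
    blocks = blocks
  )
}
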
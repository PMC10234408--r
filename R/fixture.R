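# Deterministic fixture cohort reconstructed from printed joint counts.
#
# Women fall into eight recall categories (cancer x {both, DM-only, DBT-only,
# neither} and non-cancer x {both-FP, DM-only-FP, DBT-only-FP, no recall});
# threshold blocks pin how many of each *single-arm* category lie strictly
# above each threshold. Both-arm and no-recall cells are unconstrained by any
# printed count (the combination workflow only adds single-arm events above
# the threshold and precedence cancels both-arm events), so both-arm cells are
# placed below the lowest threshold and no-recall women absorb the remainder
# of each band.

band_counts <- function(total, above) {
  k <- length(above)
  if (k == 0) return(total)
  c(above[1], diff(above), total - above[k])
}

#' Build a deterministic cohort satisfying printed joint counts
#'
#' Constructs a cohort that, when re-tallied, reproduces every count in
#' `constraints` exactly: totals, per-arm cancer-detection and false-positive
#' marginals with their overlaps, and for each threshold block the number of
#' women, DBT-only/DM-only cancers and DBT-only/DM-only false positives
#' strictly above the threshold. AI scores are fixed representative values
#' inside each inter-threshold band; organ doses are drawn from truncated
#' normal distributions, independent of score.
#'
#' @param constraints A [fixture_constraints()] object.
#' @param seed Integer seed for the dose draws.
#' @param dose_params A [dose_params()] object.
#' @return A `screening_cohort` with provenance `"fixture"`.
#' @export
build_fixture_cohort <- function(constraints = trial_constraints(),
                                 seed = 1L,
                                 dose_params = dbtriage::dose_params()) {
  validate_constraints(constraints)
  cats <- constraint_categories(constraints)
  blocks <- constraints$blocks
  k <- length(blocks)
  thresholds <- vapply(blocks, function(b) b$threshold, numeric(1))

  above_of <- function(field) vapply(blocks, function(b) b[[field]], numeric(1))
  constrained <- list(
    cancer_dbt_only = band_counts(cats$cancer_dbt_only,
                                  above_of("n_dbtonly_cancer_above")),
    cancer_dm_only = band_counts(cats$cancer_dm_only,
                                 above_of("n_dmonly_cancer_above")),
    fp_dbt_only = band_counts(cats$fp_dbt_only,
                              above_of("n_dbtonly_fp_above")),
    fp_dm_only = band_counts(cats$fp_dm_only,
                             above_of("n_dmonly_fp_above"))
  )
  bottom_only <- function(total) c(rep(0, k), total)
  unconstrained <- list(
    cancer_both = bottom_only(cats$cancer_both),
    cancer_neither = bottom_only(cats$cancer_neither),
    fp_both = bottom_only(cats$fp_both)
  )
  band_totals <- band_counts(constraints$n_total, above_of("n_above"))
  placed <- Reduce(`+`, c(constrained, unconstrained))
  normals <- band_totals - placed
  if (any(normals < 0)) {
    bad <- which(normals < 0)[1]
    constraint_error(
      "per-band residual of unrecalled women nonnegative",
      sprintf("band %d needs %d recalled/unrecallable women but only %d women",
              bad, placed[bad], band_totals[bad])
    )
  }

  scores <- constraints$band_scores
  if (is.null(scores)) {
    bounds <- c(10, thresholds, 0)
    scores <- (bounds[-1] + bounds[-length(bounds)]) / 2
  }

  # one row block per (category, band), cancers first, in a fixed order
  groups <- list(
    cancer_both = c(TRUE, TRUE, TRUE),
    cancer_dm_only = c(TRUE, TRUE, FALSE),
    cancer_dbt_only = c(TRUE, FALSE, TRUE),
    cancer_neither = c(TRUE, FALSE, FALSE),
    fp_both = c(FALSE, TRUE, TRUE),
    fp_dm_only = c(FALSE, TRUE, FALSE),
    fp_dbt_only = c(FALSE, FALSE, TRUE)
  )
  counts_of <- function(nm) {
    if (nm %in% names(constrained)) constrained[[nm]] else unconstrained[[nm]]
  }
  has_cancer <- logical(0); dm <- logical(0); dbt <- logical(0)
  ai <- numeric(0)
  for (nm in names(groups)) {
    per_band <- counts_of(nm)
    for (i in seq_len(k + 1)) {
      n <- per_band[i]
      if (n == 0) next
      has_cancer <- c(has_cancer, rep(groups[[nm]][1], n))
      dm <- c(dm, rep(groups[[nm]][2], n))
      dbt <- c(dbt, rep(groups[[nm]][3], n))
      ai <- c(ai, rep(scores[i], n))
    }
  }
  for (i in seq_len(k + 1)) {
    n <- normals[i]
    if (n == 0) next
    has_cancer <- c(has_cancer, rep(FALSE, n))
    dm <- c(dm, rep(FALSE, n))
    dbt <- c(dbt, rep(FALSE, n))
    ai <- c(ai, rep(scores[i], n))
  }

  n_total <- constraints$n_total
  if (!is.null(seed)) set.seed(seed)
  records <- tibble(
    woman_id = sprintf("W%0*d", max(5L, nchar(n_total)), seq_len(n_total)),
    has_cancer = has_cancer,
    dm_recall = dm,
    dbt_recall = dbt,
    ai_score = ai,
    dose_dm_mGy = rtruncnorm0(n_total, dose_params$dm_mean_mGy,
                              dose_params$dm_sd),
    dose_dbt_mGy = rtruncnorm0(n_total, dose_params$dbt_mean_mGy,
                               dose_params$dbt_sd)
  )
  screening_cohort(records, provenance = "fixture", seed = seed,
                   params_digest = params_digest(constraints))
}

# Normal truncated at zero via inverse-CDF sampling.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Published per-axis cancer-characteristic marginals
#'
#' Marginal counts of the 136 trial cancers along each characteristic axis
#' (invasiveness, BIRADS density, histological type, histological grade of
#' invasive cancers, nuclear grade of in-situ cancers, pathological size
#' category, axillary node status, radiographic appearance), plus the
#' constraint that pins the invasiveness axis to the published detected /
#' extra / missed columns at thresholds 9.0 and 7.5: of the DBT-only-detected
#' cancers, 1 above 9.0, 2 in (7.5, 9.0] and 1 at or below 7.5 are in situ,
#' and 16 of the both-arm-detected cancers are in situ.
#'
#' @return A named list of per-axis named count vectors plus the in-situ
#'   placement quotas.
#' @export
trial_characteristics <- function() {
  list(
    invasiveness = c(invasive = 116, `in situ` = 20),
    density = c(`1` = 10, `2` = 43, `3` = 63, `4` = 20),
    histology_invasive = c(`invasive ductal` = 74, `invasive lobular` = 24,
                           tubular = 17, `other invasive` = 1),
    histological_grade = c(`1` = 45, `2` = 52, `3` = 17, missing = 2),
    nuclear_grade = c(`1` = 2, `2` = 7, `3` = 11),
    size_cat = c(`<=10` = 49, `11-15` = 44, `16-19` = 14, `>=20` = 27,
                 missing = 2),
    node_status = c(positive = 29, negative = 94, missing = 13),
    appearance = c(`spiculated mass` = 91, `circumscribed mass` = 18,
                   microcalcifications = 22, distortion = 4,
                   `lymph node` = 1),
    insitu_quota = list(
      dbt_only_by_band = c(1, 2, 1),  # bands: >9.0, (7.5, 9.0], <=7.5
      both = 16,
      dm_only = 0
    ),
    band_thresholds = c(9.0, 7.5)
  )
}

seq_fill <- function(n, counts) {
  if (sum(counts) != n) {
    rlang::abort(sprintf(
      "characteristic marginals sum to %d but %d records need a level",
      sum(counts), n), class = "dbtriage_characteristics_error")
  }
  rep(names(counts), counts)
}

#' Assign published cancer characteristics to a fixture cohort
#'
#' Adds the characteristic columns to the cancer records of a fixture cohort
#' so that every axis's published marginal counts are met exactly, and the
#' invasiveness axis additionally reproduces the published detected, extra and
#' missed counts at thresholds 9.0 and 7.5 (in-situ quotas per detection class
#' and score band). Histological type is consistent with invasiveness (ductal
#' carcinoma in situ on exactly the in-situ cancers); grades apply only to
#' their invasiveness class. The joint distribution across axes is not
#' published; remaining levels are assigned deterministically in record order.
#'
#' @param cohort A fixture cohort whose detection-class and band sizes match
#'   the published counts (see [build_fixture_cohort()]).
#' @param spec Characteristic marginals, see [trial_characteristics()].
#' @return The cohort with characteristic columns added (`NA` on non-cancers).
#' @export
assign_characteristics <- function(cohort, spec = trial_characteristics()) {
  ca <- which(cohort$has_cancer)
  n_ca <- length(ca)
  dm <- cohort$dm_recall[ca]
  dbt <- cohort$dbt_recall[ca]
  score <- cohort$ai_score[ca]
  thr <- spec$band_thresholds
  band <- findInterval(-score, -c(Inf, thr))  # 1 = above thr[1], ...

  insitu <- logical(n_ca)
  quota <- spec$insitu_quota
  mark <- function(sel, m) {
    idx <- which(sel)
    if (length(idx) < m) {
      rlang::abort("fixture detection classes too small for in-situ quotas",
                   class = "dbtriage_characteristics_error")
    }
    insitu[idx[seq_len(m)]] <<- TRUE
  }
  for (b in seq_along(quota$dbt_only_by_band)) {
    mark(dbt & !dm & band == b & !insitu, quota$dbt_only_by_band[b])
  }
  mark(dm & dbt & !insitu, quota$both)
  if (quota$dm_only > 0) mark(dm & !dbt & !insitu, quota$dm_only)
  if (sum(insitu) != unname(spec$invasiveness["in situ"])) {
    rlang::abort("in-situ quotas do not sum to the in-situ marginal",
                 class = "dbtriage_characteristics_error")
  }

  chr <- list()
  chr$invasiveness <- ifelse(insitu, "in situ", "invasive")
  chr$density <- seq_fill(n_ca, spec$density)
  chr$histology <- character(n_ca)
  chr$histology[insitu] <- "DCIS"
  chr$histology[!insitu] <- seq_fill(sum(!insitu), spec$histology_invasive)
  chr$histological_grade <- rep(NA_character_, n_ca)
  chr$histological_grade[!insitu] <- seq_fill(sum(!insitu),
                                              spec$histological_grade)
  chr$nuclear_grade <- rep(NA_character_, n_ca)
  chr$nuclear_grade[insitu] <- seq_fill(sum(insitu), spec$nuclear_grade)
  chr$size_cat <- seq_fill(n_ca, spec$size_cat)
  chr$node_status <- seq_fill(n_ca, spec$node_status)
  chr$appearance <- seq_fill(n_ca, spec$appearance)

  for (axis in names(chr)) {
    col <- rep(NA_character_, nrow(cohort))
    col[ca] <- chr[[axis]]
    cohort[[axis]] <- col
  }
  cohort
}

#' Build the published fixture cohort in one call
#'
#' Convenience wrapper: [build_fixture_cohort()] with the published default
#' constraints, with characteristic columns assigned per
#' [assign_characteristics()].
#'
#' @param seed Integer seed for the dose draws.
#' @param characteristics Add the characteristic columns (default `TRUE`).
#' @return A `screening_cohort` of 14,768 women.
#' @export
trial_fixture <- function(seed = 1L, characteristics = TRUE) {
  cohort <- build_fixture_cohort(trial_constraints(), seed = seed)
  if (characteristics) cohort <- assign_characteristics(cohort)
  cohort
}
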
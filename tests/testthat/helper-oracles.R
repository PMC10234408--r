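# Independent oracles and generators used across the test files. These are
# deliberately written as plain, loop-based recomputations that share no code
# with the package internals.

# Brute-force re-tally of every constraint quantity by looping over records.
oracle_tally <- function(cohort, thresholds) {
  n_dm_det <- 0; n_dbt_det <- 0; n_both_det <- 0
  n_dm_fp <- 0; n_dbt_fp <- 0; n_union_fp <- 0; n_cancer <- 0
  blocks <- lapply(thresholds, function(t) {
    list(threshold = t, n_above = 0, n_dbtonly_cancer_above = 0,
         n_dmonly_cancer_above = 0, n_dbtonly_fp_above = 0,
         n_dmonly_fp_above = 0)
  })
  for (i in seq_len(nrow(cohort))) {
    ca <- cohort$has_cancer[i]; dm <- cohort$dm_recall[i]
    dbt <- cohort$dbt_recall[i]; s <- cohort$ai_score[i]
    if (ca) {
      n_cancer <- n_cancer + 1
      if (dm) n_dm_det <- n_dm_det + 1
      if (dbt) n_dbt_det <- n_dbt_det + 1
      if (dm && dbt) n_both_det <- n_both_det + 1
    } else {
      if (dm) n_dm_fp <- n_dm_fp + 1
      if (dbt) n_dbt_fp <- n_dbt_fp + 1
      if (dm || dbt) n_union_fp <- n_union_fp + 1
    }
    for (b in seq_along(blocks)) {
      if (s > blocks[[b]]$threshold) {
        blocks[[b]]$n_above <- blocks[[b]]$n_above + 1
        if (ca && dbt && !dm)
          blocks[[b]]$n_dbtonly_cancer_above <-
            blocks[[b]]$n_dbtonly_cancer_above + 1
        if (ca && dm && !dbt)
          blocks[[b]]$n_dmonly_cancer_above <-
            blocks[[b]]$n_dmonly_cancer_above + 1
        if (!ca && dbt && !dm)
          blocks[[b]]$n_dbtonly_fp_above <- blocks[[b]]$n_dbtonly_fp_above + 1
        if (!ca && dm && !dbt)
          blocks[[b]]$n_dmonly_fp_above <- blocks[[b]]$n_dmonly_fp_above + 1
      }
    }
  }
  list(n_total = nrow(cohort), n_cancer = n_cancer, n_dm_detected = n_dm_det,
       n_dbt_detected = n_dbt_det, n_both_detected = n_both_det,
       n_dm_fp = n_dm_fp, n_dbt_fp = n_dbt_fp, n_union_fp = n_union_fp,
       blocks = blocks)
}

# Random small consistent constraint set, built from an explicit band
# composition so consistency holds by construction. Both-arm and
# never-recalled cells live below the lowest threshold.
random_constraints <- function(seed) {
  set.seed(seed)
  k <- sample(0:3, 1)
  thresholds <- if (k > 0) sort(round(runif(k, 1, 9.5), 2),
                                decreasing = TRUE) else numeric(0)
  nb <- k + 1
  per_band <- function() {
    v <- sample(0:4, nb, replace = TRUE)
    v
  }
  dbtonly_ca <- per_band(); dmonly_ca <- per_band()
  dbtonly_fp <- per_band(); dmonly_fp <- per_band()
  normals <- sample(0:20, nb, replace = TRUE)
  both_ca <- sample(0:5, 1); neither_ca <- sample(0:2, 1)
  both_fp <- sample(0:5, 1)
  band_tot <- dbtonly_ca + dmonly_ca + dbtonly_fp + dmonly_fp + normals
  band_tot[nb] <- band_tot[nb] + both_ca + neither_ca + both_fp
  cum_above <- if (k > 0) cumsum(band_tot)[1:k] else numeric(0)
  blocks <- lapply(seq_len(k), function(i) {
    list(threshold = thresholds[i],
         n_above = cum_above[i],
         n_dbtonly_cancer_above = cumsum(dbtonly_ca)[i],
         n_dmonly_cancer_above = cumsum(dmonly_ca)[i],
         n_dbtonly_fp_above = cumsum(dbtonly_fp)[i],
         n_dmonly_fp_above = cumsum(dmonly_fp)[i])
  })
  fixture_constraints(
    n_total = sum(band_tot),
    n_cancer = sum(dbtonly_ca) + sum(dmonly_ca) + both_ca + neither_ca,
    n_dm_detected = sum(dmonly_ca) + both_ca,
    n_dbt_detected = sum(dbtonly_ca) + both_ca,
    n_both_detected = both_ca,
    n_dm_fp = sum(dmonly_fp) + both_fp,
    n_dbt_fp = sum(dbtonly_fp) + both_fp,
    n_union_fp = sum(dmonly_fp) + sum(dbtonly_fp) + both_fp,
    blocks = blocks
  )
}

# Clopper-Pearson endpoints by direct inversion of the binomial tail sums.
oracle_cp_tailsum <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else {
    uniroot(function(p) sum(dbinom(x:n, n, p)) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    uniroot(function(p) sum(dbinom(0:x, n, p)) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# Small hand-constructable cohort; scores chosen on both sides of 5.0.
toy_cohort <- function() {
  screening_cohort(tibble::tibble(
    woman_id = sprintf("T%02d", 1:10),
    has_cancer = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE),
    dm_recall = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  FALSE, FALSE),
    dbt_recall = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                   FALSE, FALSE),
    ai_score = c(8.2, 6.1, 3.5, 9.4, 7.7, 2.2, 5.0, 9.9, 1.1, 4.8),
    dose_dm_mGy = seq(2.0, 3.8, by = 0.2),
    dose_dbt_mGy = seq(1.8, 3.6, by = 0.2)
  ))
}

# Per-woman recall logic recomputed with explicit if/else, independent of the
# package's vectorized implementation.
oracle_counts <- function(cohort, workflow, threshold = NA) {
  detected <- 0; fp <- 0; fn <- 0; tn <- 0; dbt_exams <- 0; dm_read <- 0
  for (i in seq_len(nrow(cohort))) {
    ca <- cohort$has_cancer[i]; dm <- cohort$dm_recall[i]
    dbt <- cohort$dbt_recall[i]; s <- cohort$ai_score[i]
    above <- !is.na(threshold) && s > threshold
    if (workflow == "dm_only") {
      rec <- dm; dbt_done <- FALSE; dm_rd <- TRUE
    } else if (workflow == "dbt_only") {
      rec <- dbt; dbt_done <- TRUE; dm_rd <- FALSE
    } else if (workflow == "full_both") {
      rec <- dm || dbt; dbt_done <- TRUE; dm_rd <- TRUE
    } else if (workflow == "combination") {
      rec <- if (above) dm || dbt else dm; dbt_done <- above; dm_rd <- TRUE
    } else if (workflow == "precedence") {
      rec <- if (above) dbt else dm; dbt_done <- above; dm_rd <- !above
    }
    if (ca && rec) detected <- detected + 1
    if (ca && !rec) fn <- fn + 1
    if (!ca && rec) fp <- fp + 1
    if (!ca && !rec) tn <- tn + 1
    if (dbt_done) dbt_exams <- dbt_exams + 1
    if (dm_rd) dm_read <- dm_read + 1
  }
  list(detected = detected, fp_total = fp, missed = fn, tn = tn,
       n_dbt_exams = dbt_exams, n_dm_read = dm_read)
}

expect_tally_matches <- function(cohort, constraints) {
  thresholds <- vapply(constraints$blocks, function(b) b$threshold, numeric(1))
  got <- oracle_tally(cohort, thresholds)
  for (f in c("n_total", "n_cancer", "n_dm_detected", "n_dbt_detected",
              "n_both_detected", "n_dm_fp", "n_dbt_fp", "n_union_fp")) {
    expect_equal(got[[f]], constraints[[f]], ignore_attr = TRUE,
                 label = paste("tally of", f))
  }
  for (b in seq_along(constraints$blocks)) {
    for (f in c("n_above", "n_dbtonly_cancer_above", "n_dmonly_cancer_above",
                "n_dbtonly_fp_above", "n_dmonly_fp_above")) {
      expect_equal(got$blocks[[b]][[f]], constraints$blocks[[b]][[f]],
                   ignore_attr = TRUE,
                   label = sprintf("block %d %s", b, f))
    }
  }
}
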
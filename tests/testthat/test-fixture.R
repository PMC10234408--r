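test_that("default fixture reproduces every published joint count", {
  constraints <- trial_constraints()
  cohort <- build_fixture_cohort(constraints, seed = 7)
  expect_tally_matches(cohort, constraints)
  expect_equal(nrow(cohort), 14768)
  expect_equal(sum(cohort$has_cancer), 136)
  expect_equal(sum(cohort$has_cancer & cohort$dm_recall), 95)
  expect_equal(sum(cohort$has_cancer & cohort$dbt_recall), 128)
  expect_equal(sum(!cohort$has_cancer & cohort$dm_recall), 271)
  expect_equal(sum(!cohort$has_cancer & cohort$dbt_recall), 404)
  expect_equal(sum(!cohort$has_cancer &
                     (cohort$dm_recall | cohort$dbt_recall)), 521)
  expect_equal(nrow(validate_cohort(cohort)), 0)
})

test_that("toy constraints re-tally exactly by brute-force count", {
  constraints <- fixture_constraints(
    n_total = 20, n_cancer = 4,
    n_dm_detected = 3, n_dbt_detected = 3, n_both_detected = 2,
    n_dm_fp = 2, n_dbt_fp = 2, n_union_fp = 3,
    blocks = list(list(threshold = 5.0, n_above = 6,
                       n_dbtonly_cancer_above = 1, n_dmonly_cancer_above = 1,
                       n_dbtonly_fp_above = 1, n_dmonly_fp_above = 1))
  )
  cohort <- build_fixture_cohort(constraints, seed = 3)
  expect_tally_matches(cohort, constraints)
})

test_that("all-normal constraints give a cohort with zero signal everywhere", {
  constraints <- fixture_constraints(
    n_total = 50, n_cancer = 0, n_dm_detected = 0, n_dbt_detected = 0,
    n_both_detected = 0, n_dm_fp = 0, n_dbt_fp = 0, n_union_fp = 0,
    blocks = list(list(threshold = 5.0, n_above = 10,
                       n_dbtonly_cancer_above = 0, n_dmonly_cancer_above = 0,
                       n_dbtonly_fp_above = 0, n_dmonly_fp_above = 0))
  )
  cohort <- build_fixture_cohort(constraints, seed = 1)
  for (cf in list(triage_config("dm_only"), triage_config("dbt_only"),
                  triage_config("full_both"), triage_config("combination", 5),
                  triage_config("precedence", 5))) {
    counts <- evaluate_cohort(cohort, cf)
    expect_equal(counts$detected, 0)
    expect_equal(counts$fp_total, 0)
  }
})

test_that("fixture re-tally is idempotent over randomized consistent constraints", {
  for (seed in 1:25) {
    constraints <- random_constraints(seed)
    if (constraints$n_total == 0) next
    cohort <- build_fixture_cohort(constraints, seed = seed)
    expect_tally_matches(cohort, constraints)
    expect_equal(nrow(validate_cohort(cohort)), 0)
  }
})

test_that("same seed gives a byte-identical cohort table", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(build_fixture_cohort(seed = 11), f1)
  write_cohort(build_fixture_cohort(seed = 11), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("inconsistent constraints raise structured errors naming the rule", {
  expect_error(
    fixture_constraints(n_total = 100, n_cancer = 5, n_dm_detected = 4,
                        n_dbt_detected = 4, n_both_detected = 1,
                        n_dm_fp = 0, n_dbt_fp = 0, n_union_fp = 0),
    class = "dbtriage_constraint_error")
  expect_error(
    fixture_constraints(
      n_total = 100, n_cancer = 10, n_dm_detected = 5, n_dbt_detected = 5,
      n_both_detected = 2, n_dm_fp = 5, n_dbt_fp = 5, n_union_fp = 8,
      blocks = list(list(threshold = 5, n_above = 10,
                         n_dbtonly_cancer_above = 4, n_dmonly_cancer_above = 0,
                         n_dbtonly_fp_above = 0, n_dmonly_fp_above = 0))),
    regexp = "category total", class = "dbtriage_constraint_error")
  # block demands more single-arm events above threshold than women above
  expect_error(
    fixture_constraints(
      n_total = 100, n_cancer = 10, n_dm_detected = 5, n_dbt_detected = 5,
      n_both_detected = 2, n_dm_fp = 5, n_dbt_fp = 5, n_union_fp = 8,
      blocks = list(list(threshold = 5, n_above = 2,
                         n_dbtonly_cancer_above = 3, n_dmonly_cancer_above = 2,
                         n_dbtonly_fp_above = 0, n_dmonly_fp_above = 0))),
    regexp = "n_above", class = "dbtriage_constraint_error")
})

test_that("characteristic assignment meets every published axis marginal", {
  cohort <- trial_fixture(seed = 2)
  cancers <- cohort[cohort$has_cancer, ]
  expect_equal(table(cancers$invasiveness)[c("invasive", "in situ")],
               c(invasive = 116, `in situ` = 20), ignore_attr = TRUE)
  expect_equal(as.integer(table(cancers$density)[c("1", "2", "3", "4")]),
               c(10L, 43L, 63L, 20L))
  expect_equal(sort(as.integer(table(cancers$histology))),
               sort(c(74L, 24L, 17L, 20L, 1L)))
  expect_equal(sum(cancers$histology == "DCIS"), 20)
  # nested axes respect invasiveness
  expect_true(all(is.na(cancers$histological_grade[cancers$invasiveness ==
                                                     "in situ"])))
  expect_true(all(is.na(cancers$nuclear_grade[cancers$invasiveness ==
                                                "invasive"])))
  expect_equal(sum(cancers$size_cat == "missing"), 2)
  expect_equal(sum(cancers$node_status == "negative"), 94)
  expect_equal(sum(cancers$appearance == "spiculated mass"), 91)
  # characteristics only on cancers
  expect_true(all(is.na(cohort$invasiveness[!cohort$has_cancer])))
  expect_equal(nrow(validate_cohort(cohort)), 0)
})

test_that("cohort validation reports boundary and consistency violations", {
  cohort <- as.data.frame(toy_cohort())
  cohort$ai_score[1] <- 0
  cohort$invasiveness <- NA_character_
  cohort$invasiveness[5] <- "invasive"  # woman 5 has no cancer
  cohort$woman_id[2] <- cohort$woman_id[3]
  report <- validate_cohort(cohort)
  expect_true("ai_score_in_(0,10]" %in% report$rule)
  expect_true("characteristics_imply_cancer" %in% report$rule)
  expect_true("unique_woman_id" %in% report$rule)
  expect_true(cohort$woman_id[1] %in%
                report$woman_id[report$rule == "ai_score_in_(0,10]"])
})
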
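#' Parameters of the synthetic screening-cohort generator
#'
#' Defaults are calibrated to the trial cohort: prevalence 136/14768, arm
#' sensitivities 95/136 (DM) and 128/136 (DBT) with joint 87/136, arm
#' false-positive rates 271/14632 (DM) and 404/14632 (DBT) with joint
#' 154/14632. Score bins follow the vendor calibration of the AI system:
#' non-cancer scores roughly uniform over the ten integer bins, and most
#' cancer scores in the top bin (default 86% in bin 10, the remainder spread
#' evenly over bins 1 to 9).
#'
#' @param n_total Cohort size.
#' @param prevalence Probability a woman has screen-detectable cancer.
#' @param sens_dm,sens_dbt Marginal probability a cancer is recalled by the
#'   DM / DBT double-reading arm.
#' @param sens_both Joint probability a cancer is recalled by both arms; must
#'   not exceed either marginal and the implied 2x2 cell probabilities must
#'   be nonnegative.
#' @param fp_rate_dm,fp_rate_dbt,fp_rate_both Same three quantities for
#'   recall of non-cancers (false positives).
#' @param cancer_score_weights,normal_score_weights Probabilities of the ten
#'   integer score bins for cancers / non-cancers; each sums to 1. A score is
#'   drawn uniformly inside its bin, so bin k holds scores in (k-1, k].
#' @param score_recall_association Log-odds change in each arm's recall
#'   probability per unit of AI score (0 = recalls independent of score, the
#'   default). When nonzero, per-class intercepts are solved numerically so
#'   the class marginals above are preserved exactly, and the 2x2 joint is
#'   rebuilt at each score from the odds ratio implied by the base joint.
#' @param dose_params A [dose_params()] object.
#' @param seed Integer seed.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(n_total = 14768,
                       prevalence = 136 / 14768,
                       sens_dm = 95 / 136,
                       sens_dbt = 128 / 136,
                       sens_both = 87 / 136,
                       fp_rate_dm = 271 / 14632,
                       fp_rate_dbt = 404 / 14632,
                       fp_rate_both = 154 / 14632,
                       cancer_score_weights = c(rep(0.14 / 9, 9), 0.86),
                       normal_score_weights = rep(0.1, 10),
                       score_recall_association = 0,
                       dose_params = dbtriage::dose_params(),
                       seed = 1L) {
  p <- structure(
    list(n_total = as.integer(n_total), prevalence = prevalence,
         sens_dm = sens_dm, sens_dbt = sens_dbt, sens_both = sens_both,
         fp_rate_dm = fp_rate_dm, fp_rate_dbt = fp_rate_dbt,
         fp_rate_both = fp_rate_both,
         cancer_score_weights = cancer_score_weights,
         normal_score_weights = normal_score_weights,
         score_recall_association = score_recall_association,
         dose_params = dose_params, seed = as.integer(seed)),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

# 2x2 cell probabilities (both, dm-only, dbt-only, neither) from two
# marginals and a joint.
joint_cells <- function(p_dm, p_dbt, p_both, what) {
  cells <- c(both = p_both, dm_only = p_dm - p_both,
             dbt_only = p_dbt - p_both, neither = 1 - p_dm - p_dbt + p_both)
  if (any(cells < -1e-12)) {
    rlang::abort(
      sprintf("infeasible %s joint: cell probabilities (%s) not all nonnegative",
              what, paste(sprintf("%.4g", cells), collapse = ", ")),
      class = "dbtriage_params_error"
    )
  }
  pmax(cells, 0)
}

validate_sim_params <- function(p) {
  probs <- c(p$prevalence, p$sens_dm, p$sens_dbt, p$sens_both,
             p$fp_rate_dm, p$fp_rate_dbt, p$fp_rate_both)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "dbtriage_params_error")
  }
  if (p$sens_both > min(p$sens_dm, p$sens_dbt) + 1e-12) {
    rlang::abort("sens_both exceeds a marginal sensitivity",
                 class = "dbtriage_params_error")
  }
  if (p$fp_rate_both > min(p$fp_rate_dm, p$fp_rate_dbt) + 1e-12) {
    rlang::abort("fp_rate_both exceeds a marginal false-positive rate",
                 class = "dbtriage_params_error")
  }
  joint_cells(p$sens_dm, p$sens_dbt, p$sens_both, "sensitivity")
  joint_cells(p$fp_rate_dm, p$fp_rate_dbt, p$fp_rate_both, "false-positive")
  for (w in list(p$cancer_score_weights, p$normal_score_weights)) {
    if (length(w) != 10 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      rlang::abort("score bin weights must be 10 nonnegative values summing to 1",
                   class = "dbtriage_params_error")
    }
  }
  invisible(p)
}

draw_scores <- function(n, weights) {
  bin <- sample.int(10, n, replace = TRUE, prob = weights)
  bin - stats::runif(n)  # uniform in (bin - 1, bin]
}

# Solve the intercept a so that E[plogis(a + beta * S)] = target, with S
# distributed as the bin-weight mixture (uniform within bin).
solve_tilt_intercept <- function(target, beta, weights) {
  if (target <= 0 || target >= 1) return(stats::qlogis(target))
  grid <- seq(0.005, 9.995, by = 0.01)
  w <- weights[ceiling(grid)]
  w <- w / sum(w)
  f <- function(a) sum(w * stats::plogis(a + beta * grid)) - target
  stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
}

# p_both at score s from tilted marginals p1, p2 and a fixed odds ratio psi.
joint_from_or <- function(p1, p2, psi) {
  if (abs(psi - 1) < 1e-9) return(p1 * p2)
  s <- 1 + (p1 + p2) * (psi - 1)
  p11 <- (s - sqrt(s^2 - 4 * psi * (psi - 1) * p1 * p2)) / (2 * (psi - 1))
  pmin(pmax(p11, pmax(0, p1 + p2 - 1)), pmin(p1, p2))
}

draw_recalls <- function(score, p_arm1, p_arm2, p_joint, beta, weights, what) {
  n <- length(score)
  if (n == 0) {
    return(list(a = logical(0), b = logical(0)))
  }
  if (beta == 0) {
    cells <- joint_cells(p_arm1, p_arm2, p_joint, what)
    pick <- sample.int(4, n, replace = TRUE, prob = cells)
    return(list(a = pick %in% c(1, 2), b = pick %in% c(1, 3)))
  }
  cells0 <- joint_cells(p_arm1, p_arm2, p_joint, what)
  if (any(cells0 == 0)) {
    rlang::abort(
      "score_recall_association requires strictly interior 2x2 cells",
      class = "dbtriage_params_error"
    )
  }
  psi <- (cells0["both"] * cells0["neither"]) /
    (cells0["dm_only"] * cells0["dbt_only"])
  a1 <- solve_tilt_intercept(p_arm1, beta, weights)
  a2 <- solve_tilt_intercept(p_arm2, beta, weights)
  p1 <- stats::plogis(a1 + beta * score)
  p2 <- stats::plogis(a2 + beta * score)
  p11 <- joint_from_or(p1, p2, unname(psi))
  u <- stats::runif(n)
  both <- u < p11
  dm_only <- !both & u < p11 + (p1 - p11)
  dbt_only <- !both & !dm_only & u < p1 + p2 - p11
  list(a = both | dm_only, b = both | dbt_only)
}

#' Simulate a stochastic synthetic screening cohort
#'
#' Each woman is drawn independently: cancer status from the prevalence;
#' the (DM recall, DBT recall) pair from the class-conditional 2x2
#' distribution implied by the marginal and joint recall probabilities; the
#' AI score from the class-conditional bin weights, uniform within the bin;
#' organ doses from truncated normals, independent of everything else.
#' Reproducible: the same parameters and seed give an identical cohort.
#'
#' @param params A [sim_params()] object.
#' @return A `screening_cohort` with provenance `"simulated"`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  validate_sim_params(params)
  n <- params$n_total
  set.seed(params$seed)
  has_cancer <- stats::runif(n) < params$prevalence
  score <- numeric(n)
  score[has_cancer] <- draw_scores(sum(has_cancer),
                                   params$cancer_score_weights)
  score[!has_cancer] <- draw_scores(sum(!has_cancer),
                                    params$normal_score_weights)
  dm <- logical(n); dbt <- logical(n)
  rc <- draw_recalls(score[has_cancer], params$sens_dm, params$sens_dbt,
                     params$sens_both, params$score_recall_association,
                     params$cancer_score_weights, "sensitivity")
  dm[has_cancer] <- rc$a; dbt[has_cancer] <- rc$b
  rn <- draw_recalls(score[!has_cancer], params$fp_rate_dm,
                     params$fp_rate_dbt, params$fp_rate_both,
                     params$score_recall_association,
                     params$normal_score_weights, "false-positive")
  dm[!has_cancer] <- rn$a; dbt[!has_cancer] <- rn$b
  dp <- params$dose_params
  records <- tibble(
    woman_id = sprintf("S%0*d", max(5L, nchar(n)), seq_len(n)),
    has_cancer = has_cancer,
    dm_recall = dm,
    dbt_recall = dbt,
    ai_score = score,
    dose_dm_mGy = rtruncnorm0(n, dp$dm_mean_mGy, dp$dm_sd),
    dose_dbt_mGy = rtruncnorm0(n, dp$dbt_mean_mGy, dp$dbt_sd)
  )
  screening_cohort(records, provenance = "simulated", seed = params$seed,
                   params_digest = params_digest(params))
}
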
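---
title: "Evaluating AI-gated selective addition of DBT to mammography screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating AI-gated selective addition of DBT to mammography screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbtriage)
```

## The question

Digital breast tomosynthesis (DBT) detects more cancers than two-view digital
mammography (DM), but costs more reading time, more equipment time and — when
added on top of DM — more radiation dose. `dbtriage` evaluates a middle road:
screen everyone with DM, score each DM examination with an AI
cancer-detection system that emits a decimal risk score in (0, 10]
(decile-calibrated so that each integer bin holds roughly 10% of a screening
population, with the large majority of cancers in bin 10), and add a one-view
DBT examination only when the score strictly exceeds a threshold `t`.

Two reading workflows are compared for the gated women:

* **combination** — the DBT double reading is combined with the DM double
  reading; a woman is recalled if either arm recalls her
  (`recall = dm | dbt` above `t`, `dm` below);
* **precedence** — only the DBT double reading is used when DBT was
  performed (`recall = dbt` above `t`, `dm` below). The DM examination is
  still *performed* (its dose accrues) but is not read.

Three ungated strategies bracket these: `dm_only`, `dbt_only` (no DM
performed at all) and `full_both` (everyone read with both, recall is the
union). Ties at the threshold never trigger DBT: the comparison is strictly
`score > t`.

Because the underlying trial read the two arms separately, the union of two
independent double readings is exactly what a combination workflow would have
produced; no reader behaviour is re-modelled. How radiologists would read DM
and DBT *together*, or with AI results visible, is unknowable from these data
and out of scope.

## The deterministic fixture cohort

No per-woman data are public, but every headline quantity of the evaluation
is a pure function of published joint counts: 14,768 screened women; 136
cancers of which 95 were DM-detected, 128 DBT-detected and 87 detected by
both arms (hence 8 DM-only, 41 DBT-only, 0 missed by both); 271 DM false
positives, 404 DBT false positives, 521 in union (hence 154 in both arms);
and, per threshold, the number of women strictly above (1493 above 9.0, 3251
above 7.5) together with the above-threshold counts of the four *single-arm*
recall categories (at 9.0: 24 DBT-only cancers, 7 DM-only cancers, 60
DBT-only FPs, 30 DM-only FPs; at 7.5: 31, 8, 103, 52).

`build_fixture_cohort()` materialises a cohort that reproduces all of these
counts exactly when re-tallied. The thresholds partition (0, 10] into bands;
each recall category is allocated to bands by successive differences of its
above-threshold counts, and all remaining women in a band are unrecalled
normals. Two cells are unconstrained by any printed count: the 87
both-detected cancers and the 154 both-arm false positives. The combination
workflow only *adds* single-arm events above the threshold, and precedence
*cancels* both-arm events (recalled either way), so no reported number
depends on where these cells sit; they are placed below the lowest threshold.

Within a band, any score satisfies the counts, so fixed representatives keep
the fixture deterministic: 9.5, 8.25 and 4.0 for the default bands (general
constraint sets default to band midpoints). Organ doses are drawn from
zero-truncated normal distributions, independent of score, so the only
randomness in the fixture is the dose column; every count is seed-invariant.

Feasibility is validated before construction (monotone block counts, category
totals, nonnegative per-band residuals), and a violated constraint is named
in a structured error. `run_fixture()` additionally writes a re-tally report
proving each constraint is satisfied by the written table.

### Cancer characteristics

The published per-axis marginals of the 136 cancers (invasiveness 116/20,
BIRADS density 10/43/63/20, histological type, grades, size, node status,
radiographic appearance) are assigned by `assign_characteristics()`. The
invasiveness axis is additionally pinned to the published detected / extra /
missed columns at both thresholds, which determines how many in-situ cancers
sit in each DBT-only band (1 above 9.0, 2 in (7.5, 9.0], 1 below) and among
the both-detected cancers (16). Nested axes are respected — ductal carcinoma
in situ coincides with the in-situ cancers, histological grade applies to
invasive and nuclear grade to in-situ cancers only. The joint distribution
across axes is not published; remaining levels are filled deterministically
in record order, so per-axis totals are exact while cross-axis joints (and
the per-level detected splits of axes other than invasiveness) are a
documented best effort.

## The synthetic-cohort generator

`simulate_cohort()` draws each woman independently: cancer status at
prevalence 136/14768; for cancers the (DM recall, DBT recall) pair from the
2×2 distribution implied by marginal sensitivities 95/136 and 128/136 with
joint 87/136; for non-cancers from false-positive rates 271/14632 and
404/14632 with joint 154/14632; the AI score from class-conditional integer
bin weights, uniform within the bin. Non-cancer weights default to the
vendor's decile calibration (0.1 per bin); cancer weights default to 0.86 in
bin 10 — consistent with the calibration statement that more than 85% of
cancers score 10 — with the remainder spread evenly over bins 1–9, a choice
made once as a plausible screening-population shape since the full cancer
score histogram is not published.

By default recalls are independent of the score given the class. The
`score_recall_association` parameter (log-odds per score unit) tilts each
arm's recall probability in the score while preserving the class marginals
exactly — the intercept is solved numerically against the score mixture and
the 2×2 joint is rebuilt at each score from the base odds ratio. This is the
minimal mechanism that makes "high-scoring cancers are the DBT-detectable
ones" expressible; the paired trial publishes no estimate of it, which is
why independence is the default.

What the generator does *not* emulate: interval cancers and next-round
detections (the ground truth is screen detection by either arm), per-lesion
structure, reader identity and consensus dynamics, density–score or
dose–score correlation, and any drift of the score calibration across
populations. Tests passing on simulated cohorts therefore validate the
accounting machinery under the stated statistical structure, not the
transportability of the published effect sizes to other screening programs.

## Outcome metrics and intervals

`summarize_strategy()` reports, per strategy: detected cancers, extras versus
DM-only on the same cohort, misses versus `full_both`, false positives and
extras, PPV = detected / (detected + FP), examination counts, detection rates
per 1000 (overall, and extra detections per 1000 women given DBT), and
sensitivity/specificity. All fields carry full precision; zero denominators
yield `NA`, never a silent 0. Display mirrors the source tables:
per-1000 rates to one decimal (9.54 keeps two), percent increases computed on
unrounded counts and rounded half-away-from-zero to integers
(`round_half_up()`), interval points as integer percents with 2-decimal
bounds (`format_ci()`).

Proportion intervals are exact Clopper–Pearson, computed from beta quantiles
(`qbeta(α/2, x, n−x+1)`, `qbeta(1−α/2, x+1, n−x)`), with the boundary
conventions lower = 0 at x = 0 and upper = 1 at x = n. Tests verify
equivalence with direct binomial tail-sum inversion for every `x` at
`n ≤ 12` (tolerance 1e-9) and conservative ≥95% empirical coverage over
2,000 simulated binomials at `p = 0.3, n = 50`.

## Resource models

**Dose.** `population_mean_dose()` averages the dose actually delivered:
the DM dose accrues for every workflow except `dbt_only` (under precedence
the DM exam is performed even when unread), the DBT dose whenever DBT is
performed. Defaults: DM 2.69 mGy (SD 0.778), DBT 2.24 mGy (SD 0.672),
both 4.91 mGy (SD 1.347), zero-truncated normal. With score-independent
doses the expectation is `2.69 + f · 2.24` where `f` is the fraction given
DBT — 2.92 mGy at `t = 9.0` and 3.18 at `t = 7.5` on the fixture. The source
reports 2.89 and 3.14 on the real data, implying a mild negative score–dose
correlation it does not quantify; the independence values are the model's
output and the published ones are deliberately not reproduction targets.

**Reading time.** `reading_time_change()` uses two multipliers relative to a
DM reading: 1.75 for reading DBT instead of DM, 2.25 for reading both. A
fraction `f` of converted examinations changes total reading time by
`f·125%` (combination) or `f·75%` (precedence): 27.5% and 16.5% at
`t = 7.5` (the source prints the rounded 27% and 16%), 12.6% and 7.6% at
`t = 9.0`. The source prints 11% and 6% at 9.0, which is inconsistent with
its own multipliers and the 1493 count; the arithmetic values are returned
and the mismatch is simply documented. The same applies to the source
abstract's 25 extra cancers / 1797 gated women / 14 per 1000 / 58 extra FPs,
which conflict with its own detailed table (24 / 1493 / 16.1 / 60); the
fixture follows the detailed table. One further cosmetic mismatch: the
detailed table prints PPV 0.251 for combination at 7.5 while
126/(126+374) = 0.252; the computed value is reported.

## Numerical and design choices

* Strict threshold comparison everywhere; a tie keeps the woman on DM alone.
* Percent rounding half-away-from-zero (so 58.5% prints 59%); `round()`'s
  round-to-even would disagree on exact halves.
* Fixture identifiers are zero-padded and rows written with fixed decimal
  formats, so write–read–write round trips are byte-identical and a seed
  fully determines the file.
* `sweep_thresholds()` recomputes each point by full evaluation rather than
  incremental updates; the cohort sizes involved make O(grid × n) trivial.
* Degenerate inputs: empty cohorts produce flagged all-zero summaries;
  cohorts without cancers refuse operating points; missing dose fields name
  the offending records.

Test problem sizes were chosen to keep the full suite fast while leaving
Monte-Carlo error far below the tested tolerances: calibration at n = 10^5
(3 standard errors), 200 replicate cohorts at the study size for the
binomial-mean check, 2,000 replicates for interval coverage.

## Limitations

The fixture reproduces printed counts, not the trial's data: within a score
band the joint distribution of score with everything else is degenerate by
construction, so only quantities determined by the published counts are
meaningful on it (this is exactly the set of quantities the evaluation
reports). Cross-axis characteristic joints are under-determined. The
simulator's independence defaults are assumptions, not estimates. Interval
cancers are excluded by design, so "sensitivity" here means sensitivity
against screen-detectable disease. Reading-time and dose models are
two-parameter approximations intended for policy-level comparison, not
workload scheduling.
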
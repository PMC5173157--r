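#' Delineation-time analysis and acceptance decision engine
#'
#' The workflow-time side of the validation: per-patient timing records
#' (first-operation time T1, independent-check time T2, total TT = T1 + T2,
#' all minutes), group summaries, the total-time saving estimators, the
#' paired Student's t-test, and the multi-criterion acceptance rule with a
#' mandatory time-saving criterion.
#'
#' @name qa-engine
NULL

#' Build a table of per-patient timing records
#'
#' @param patient_id character vector.
#' @param group workflow group per record: `"A"` (manual) or `"B"`
#'   (automatic).
#' @param t1_min first-operation time (manual contouring, or auto-delineation
#'   including atlas choice and propagation), minutes, >= 0.
#' @param t2_min independent-check time, minutes, >= 0.
#' @return data.frame with class `timing_records`; `tt_min` is derived as
#'   `t1_min + t2_min`.
#' @export
timing_records <- function(patient_id, group, t1_min, t2_min) {
  group <- as.character(group)
  if (!all(group %in% c("A", "B"))) stop("group must be 'A' (manual) or 'B' (automatic)")
  if (any(t1_min < 0) || any(t2_min < 0)) stop("times must be non-negative")
  out <- data.frame(patient_id = as.character(patient_id), group = group,
                    t1_min = as.numeric(t1_min), t2_min = as.numeric(t2_min),
                    stringsAsFactors = FALSE)
  out$tt_min <- out$t1_min + out$t2_min
  class(out) <- c("timing_records", "data.frame")
  out
}

#' Mean and SD of T1, T2 and TT for one workflow group
#'
#' @param records `timing_records` rows, all from one group.
#' @return list with per-column `mean` and `sd` (sample SD, n - 1; 0 with
#'   `sd_defined = FALSE` for a single record) plus `n` and `group`.
#' @export
group_time_summary <- function(records) {
  if (!nrow(records)) stop("empty timing group")
  if (length(unique(records$group)) != 1L) {
    stop("group_time_summary expects records from a single group")
  }
  n <- nrow(records)
  sd_defined <- n >= 2L
  cols <- c("t1_min", "t2_min", "tt_min")
  list(group = records$group[1L], n = n, sd_defined = sd_defined,
       mean = vapply(records[cols], mean, numeric(1)),
       sd = if (sd_defined) vapply(records[cols], stats::sd, numeric(1))
            else stats::setNames(rep(0, 3L), cols))
}

#' Total-time saving from group mean times (ratio of means)
#'
#' `100 * (tt_manual - tt_auto) / tt_manual` percent; negative if the
#' automatic workflow is slower.
#'
#' @param tt_manual_mean,tt_auto_mean group mean total times, minutes.
#' @return percent saving.
#' @export
time_saving_pct <- function(tt_manual_mean, tt_auto_mean) {
  if (!is.finite(tt_manual_mean) || tt_manual_mean <= 0) {
    stop("manual-group mean total time must be positive")
  }
  100 * (tt_manual_mean - tt_auto_mean) / tt_manual_mean
}

#' Per-patient total-time savings (mean-of-ratios estimator)
#'
#' Matches the two groups by patient and returns each patient's percent
#' saving plus their mean; offered alongside [time_saving_pct()] because the
#' two estimators differ whenever times vary across patients.
#'
#' @param records_a,records_b `timing_records` for the manual (A) and
#'   automatic (B) workflow; every patient must appear in both.
#' @return list with `per_patient` (data.frame patient_id, saving_pct) and
#'   `mean_saving_pct`.
#' @export
per_patient_saving <- function(records_a, records_b) {
  ids_a <- records_a$patient_id
  ids_b <- records_b$patient_id
  missing_b <- setdiff(ids_a, ids_b)
  missing_a <- setdiff(ids_b, ids_a)
  if (length(missing_a) || length(missing_b)) {
    stop("unmatched patients between groups: ",
         paste(sort(unique(c(missing_a, missing_b))), collapse = ", "))
  }
  if (!length(ids_a)) stop("unmatched patients between groups: empty intersection")
  tt_a <- records_a$tt_min[order(ids_a)]
  tt_b <- records_b$tt_min[order(ids_b)]
  if (any(tt_a <= 0)) stop("per-patient manual total times must be positive")
  s <- 100 * (tt_a - tt_b) / tt_a
  list(per_patient = data.frame(patient_id = sort(ids_a), saving_pct = s,
                                stringsAsFactors = FALSE),
       mean_saving_pct = mean(s))
}

#' Paired Student's t-test on per-patient total-time differences
#'
#' Classical paired t statistic with n - 1 degrees of freedom, two-sided
#' p-value and 95% CI of the mean difference (via [stats::t.test()]).
#'
#' @param diffs per-patient TT differences (manual minus automatic), minutes.
#' @return list with `mean_diff_min`, `t_statistic`, `df`, `p_value`, `ci95`.
#' @export
paired_t_test <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L) stop("paired t-test needs n >= 2 differences")
  if (stats::sd(diffs) == 0) {
    stop("degenerate paired t-test: differences have zero variance")
  }
  tt <- stats::t.test(diffs)
  list(mean_diff_min = unname(tt$estimate),
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       ci95 = as.numeric(tt$conf.int))
}

#' Acceptance thresholds for introducing auto-segmentation
#'
#' Defaults are the clinical-introduction thresholds: MDSC >= 0.75,
#' MSHD <= 1 mm, total-time saving >= 50%, with at least 2 of the 3 criteria
#' met of which the time saving is mandatory. All comparisons are inclusive.
#'
#' @param dsc_min minimum acceptable cohort MDSC.
#' @param mshd_max_mm maximum acceptable cohort mean MSHD, mm.
#' @param tt_saving_min_pct minimum acceptable total-time saving, percent.
#' @param required_met how many criteria must hold (<= 3).
#' @param mandatory which criterion must always be among those met
#'   (`"tt_saving"`, or `NA` for none).
#' @return a `qa_criteria` list.
#' @export
qa_criteria <- function(dsc_min = 0.75, mshd_max_mm = 1.0,
                        tt_saving_min_pct = 50, required_met = 2L,
                        mandatory = "tt_saving") {
  stopifnot(dsc_min > 0, mshd_max_mm > 0, required_met <= 3L)
  structure(list(dsc_min = dsc_min, mshd_max_mm = mshd_max_mm,
                 tt_saving_min_pct = tt_saving_min_pct,
                 required_met = as.integer(required_met),
                 mandatory = mandatory),
            class = "qa_criteria")
}

#' Evaluate the acceptance criteria on observed cohort values
#'
#' Inclusive comparisons: MDSC >= `dsc_min`, MSHD <= `mshd_max_mm`, saving >=
#' `tt_saving_min_pct`. Accepted iff at least `required_met` criteria hold
#' and the mandatory criterion (time saving) is among them.
#'
#' @param mdsc observed cohort median DSC (or a `cohort_overlap_summary`).
#' @param mshd_mean_mm observed cohort mean MSHD, mm (ignored when `mdsc` is
#'   a summary object).
#' @param tt_saving_pct observed total-time saving, percent.
#' @param criteria a [qa_criteria()] object.
#' @return a `qa_decision`: list with `observed`, `met` (named logicals),
#'   `n_met`, `mandatory_met`, `accepted`.
#' @export
evaluate_acceptance <- function(mdsc, mshd_mean_mm = NULL, tt_saving_pct,
                                criteria = qa_criteria()) {
  if (inherits(mdsc, "cohort_overlap_summary")) {
    mshd_mean_mm <- mdsc$mshd_mean_mm
    mdsc <- mdsc$mdsc
  }
  obs <- c(mdsc = mdsc, mshd_mean_mm = mshd_mean_mm,
           tt_saving_pct = tt_saving_pct)
  if (!all(is.finite(obs))) stop("observed (MDSC, MSHD, saving) must be finite")
  met <- c(mdsc = unname(obs["mdsc"] >= criteria$dsc_min),
           mshd = unname(obs["mshd_mean_mm"] <= criteria$mshd_max_mm),
           tt_saving = unname(obs["tt_saving_pct"] >= criteria$tt_saving_min_pct))
  mandatory_met <- if (is.na(criteria$mandatory)) TRUE else met[[criteria$mandatory]]
  structure(list(observed = obs, met = met, n_met = sum(met),
                 mandatory_met = mandatory_met,
                 accepted = sum(met) >= criteria$required_met && mandatory_met,
                 criteria = criteria),
            class = "qa_decision")
}

#' @export
print.qa_decision <- function(x, ...) {
  cat(sprintf(
    "<qa_decision> MDSC %.3f [%s]  MSHD %.2f mm [%s]  TT saving %.1f%% [%s]\n  %d/3 met, mandatory %s -> %s\n",
    x$observed["mdsc"], if (x$met["mdsc"]) "met" else "not met",
    x$observed["mshd_mean_mm"], if (x$met["mshd"]) "met" else "not met",
    x$observed["tt_saving_pct"], if (x$met["tt_saving"]) "met" else "not met",
    x$n_met, if (x$mandatory_met) "met" else "NOT met",
    if (x$accepted) "ACCEPTED" else "REJECTED"))
  invisible(x)
}

#' Re-summarise a cohort after removing its worst patients
#'
#' Ranks patients by combined poorness (rank by ascending DSC plus rank by
#' descending MSHD, ties broken by patient id), removes the `k_worst` worst,
#' and re-summarises. Mirrors the qualitative exclusion of outlier anatomies
#' (e.g. pelvic bowel loops, large uterine fibroma) in a reproducible rule.
#'
#' @param results list of `overlap_result` (or an [overlap_table()]).
#' @param k_worst number of patients to drop (0 <= k < n).
#' @return list with `summary` (a `cohort_overlap_summary`), `removed_ids`,
#'   `kept` (the reduced table).
#' @export
outlier_sensitivity <- function(results, k_worst) {
  tab <- if (is.data.frame(results)) results else overlap_table(results)
  n <- nrow(tab)
  if (k_worst >= n) stop("k_worst must be smaller than the cohort size")
  ord_id <- order(tab$patient_id)
  tab <- tab[ord_id, , drop = FALSE]
  r_dsc <- rank(tab$dsc, ties.method = "first")        # worst dsc -> rank 1
  r_mshd <- rank(-tab$mshd_mm, ties.method = "first")  # worst mshd -> rank 1
  score <- r_dsc + r_mshd
  worst <- order(score, tab$patient_id)[seq_len(k_worst)]
  removed <- tab$patient_id[worst]
  kept <- if (k_worst > 0L) tab[-worst, , drop = FALSE] else tab
  list(summary = summarise_cohort(kept),
       removed_ids = sort(removed),
       kept = kept)
}

#' Compare overlap and independent-check time across slice-thickness subgroups
#'
#' Splits patients by slice thickness, summarises the overlap metrics per
#' subgroup, and compares the independent-check time T2 across the two
#' subgroups with an unpaired Student's t-test (different patients per
#' thickness cohort). With fewer than 2 subgroups, or a subgroup of fewer
#' than 2 patients, summaries are still emitted and the test is skipped with
#' a flag.
#'
#' @param results list of `overlap_result` or an [overlap_table()] (must
#'   carry `slice_thickness_mm`).
#' @param timings `timing_records` for the patients being compared (one
#'   group's records).
#' @return list with `subgroups` (named list of `cohort_overlap_summary`),
#'   `t2_test` (list or NULL), `test_skipped`, `skip_reason`.
#' @export
subgroup_compare <- function(results, timings) {
  tab <- if (is.data.frame(results)) results else overlap_table(results)
  sub <- split(tab, tab$slice_thickness_mm)
  summaries <- lapply(sub, summarise_cohort)
  names(summaries) <- paste0(names(sub), "mm")
  skipped <- FALSE; reason <- NULL; test <- NULL
  if (length(sub) != 2L) {
    skipped <- TRUE
    reason <- "need exactly 2 thickness subgroups for the T2 comparison"
  } else {
    t2 <- lapply(sub, function(s) {
      timings$t2_min[match(s$patient_id, timings$patient_id)]
    })
    if (anyNA(unlist(t2))) {
      skipped <- TRUE
      reason <- "timing records missing for some patients"
    } else if (any(vapply(t2, length, integer(1)) < 2L)) {
      skipped <- TRUE
      reason <- "a subgroup has fewer than 2 patients"
    } else {
      # sub is split() output, ordered by ascending thickness: [[1]] thinner
      tt <- stats::t.test(t2[[1L]], t2[[2L]], var.equal = TRUE)
      test <- list(thinner_mm = as.numeric(names(sub)[1L]),
                   thicker_mm = as.numeric(names(sub)[2L]),
                   mean_diff_min = unname(tt$estimate[1L] - tt$estimate[2L]),
                   t_statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
    }
  }
  list(subgroups = summaries, t2_test = test,
       test_skipped = skipped, skip_reason = reason)
}
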
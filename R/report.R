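#' Study evaluation pipeline and reporting
#'
#' Drives the full evaluation over a cohort (synthetic or ingested): per
#' patient overlap of the manual (group A) and automatic (group B)
#' delineations against the reference, cohort summaries, the time analysis
#' with both saving estimators and the paired t-test, the acceptance
#' decision, the outlier sensitivity analysis and the slice-thickness
#' subgroup comparison. The report mirrors the two blocks of the study's
#' summary table (overlapping analysis / time analysis) plus a decision
#' block.
#'
#' @name qa-report
NULL

#' Evaluate a cohort end to end
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param criteria acceptance thresholds ([qa_criteria()]).
#' @param step_mm Hausdorff boundary resampling step, mm.
#' @param unmatched_policy MSHD handling of reference slices without a test
#'   contour (`"exclude"` or `"penalise"`).
#' @param saving_estimator which total-time-saving estimator feeds the
#'   decision: `"ratio_of_means"` (group-mean based, default) or
#'   `"per_patient"`; both are always reported.
#' @param outlier_k patients removed in the sensitivity analysis.
#' @return a `qa_report` list (tables, summaries, time analysis, decision,
#'   sensitivity, subgroup analysis, flags).
#' @export
evaluate_cohort <- function(cohort, criteria = qa_criteria(), step_mm = 0.1,
                            unmatched_policy = c("exclude", "penalise"),
                            saving_estimator = c("ratio_of_means", "per_patient"),
                            outlier_k = 2L) {
  unmatched_policy <- match.arg(unmatched_policy)
  saving_estimator <- match.arg(saving_estimator)
  ids <- names(cohort$delineations)
  run_group <- function(role) {
    res <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      trip <- cohort$delineations[[ids[k]]]
      res[[k]] <- compare_delineations(trip$reference, trip[[role]],
                                       unmatched_policy = unmatched_policy,
                                       step_mm = step_mm)
    }
    res
  }
  results_manual <- run_group("manual")
  results_auto <- run_group("auto")
  summary_a <- summarise_cohort(results_manual)
  summary_b <- summarise_cohort(results_auto)

  tim <- cohort$timings
  missing_timing <- setdiff(ids, tim$patient_id)
  tim <- tim[tim$patient_id %in% ids, , drop = FALSE]
  rec_a <- tim[tim$group == "A", , drop = FALSE]
  rec_b <- tim[tim$group == "B", , drop = FALSE]
  ts_a <- group_time_summary(rec_a)
  ts_b <- group_time_summary(rec_b)
  saving_rom <- time_saving_pct(ts_a$mean[["tt_min"]], ts_b$mean[["tt_min"]])
  pps <- per_patient_saving(rec_a, rec_b)
  common <- intersect(rec_a$patient_id, rec_b$patient_id)
  diffs <- rec_a$tt_min[match(common, rec_a$patient_id)] -
    rec_b$tt_min[match(common, rec_b$patient_id)]
  ttest <- paired_t_test(diffs)

  saving_used <- if (saving_estimator == "ratio_of_means") saving_rom
                 else pps$mean_saving_pct
  decision <- evaluate_acceptance(summary_b, tt_saving_pct = saving_used,
                                  criteria = criteria)
  sens <- outlier_sensitivity(results_auto, outlier_k)
  subgrp <- subgroup_compare(results_auto, rec_b)

  structure(list(
    table_manual = overlap_table(results_manual),
    table_auto = overlap_table(results_auto),
    summary_manual = summary_a,
    summary_auto = summary_b,
    time = list(group_a = ts_a, group_b = ts_b,
                saving_ratio_of_means_pct = saving_rom,
                saving_per_patient_mean_pct = pps$mean_saving_pct,
                saving_estimator_used = saving_estimator,
                paired_t = ttest),
    decision = decision,
    sensitivity = sens,
    subgroup = subgrp,
    flags = list(patients_missing_timing = missing_timing),
    parameters = list(step_mm = step_mm, unmatched_policy = unmatched_policy,
                      outlier_k = as.integer(outlier_k))),
    class = "qa_report")
}

summary_block <- function(s) {
  list(mdsc = s$mdsc, dsc_sd = s$dsc_sd, mshd_mean_mm = s$mshd_mean_mm,
       mshd_sd_mm = s$mshd_sd_mm, n_patients = s$n_patients)
}
time_block <- function(ts) {
  list(n = ts$n,
       t1 = list(mean = unname(ts$mean[["t1_min"]]), sd = unname(ts$sd[["t1_min"]])),
       t2 = list(mean = unname(ts$mean[["t2_min"]]), sd = unname(ts$sd[["t2_min"]])),
       tt = list(mean = unname(ts$mean[["tt_min"]]), sd = unname(ts$sd[["tt_min"]])))
}

#' Report as a plain list (JSON-ready)
#'
#' @param report a `qa_report`.
#' @return nested list mirroring the overlap / time / decision blocks.
#' @export
report_as_list <- function(report) {
  d <- report$decision
  list(
    overlapping_analysis = list(
      group_a = summary_block(report$summary_manual),
      group_b = summary_block(report$summary_auto)),
    time_analysis = list(
      group_a = time_block(report$time$group_a),
      group_b = time_block(report$time$group_b),
      saving_ratio_of_means_pct = report$time$saving_ratio_of_means_pct,
      saving_per_patient_mean_pct = report$time$saving_per_patient_mean_pct,
      saving_estimator_used = report$time$saving_estimator_used,
      paired_t = report$time$paired_t),
    decision = list(
      observed = as.list(d$observed),
      thresholds = list(dsc_min = d$criteria$dsc_min,
                        mshd_max_mm = d$criteria$mshd_max_mm,
                        tt_saving_min_pct = d$criteria$tt_saving_min_pct),
      met = as.list(d$met),
      n_met = d$n_met,
      mandatory_met = d$mandatory_met,
      accepted = d$accepted),
    sensitivity = list(
      removed_ids = report$sensitivity$removed_ids,
      summary = summary_block(report$sensitivity$summary)),
    subgroup = list(
      summaries = lapply(report$subgroup$subgroups, summary_block),
      t2_test = report$subgroup$t2_test,
      test_skipped = report$subgroup$test_skipped),
    flags = report$flags,
    parameters = report$parameters)
}

#' Write a QA report to disk (JSON + markdown + per-patient CSVs)
#'
#' @param report a `qa_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_qa_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(report_as_list(report), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE),
             file.path(dir, "qa_report.json"))
  writeLines(report_markdown(report), file.path(dir, "qa_report.md"))
  utils::write.csv(report$table_manual,
                   file.path(dir, "overlap_group_a.csv"), row.names = FALSE)
  utils::write.csv(report$table_auto,
                   file.path(dir, "overlap_group_b.csv"), row.names = FALSE)
  invisible(dir)
}

#' Render a QA report as markdown
#'
#' @param report a `qa_report`.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  sa <- report$summary_manual; sb <- report$summary_auto
  ta <- report$time$group_a; tb <- report$time$group_b
  d <- report$decision
  fmt <- function(m, s) sprintf("%.2f (±%.2f)", m, s)
  lines <- c(
    "# Delineation QA report",
    "",
    "## OVERLAPPING ANALYSIS",
    "",
    "| | Group A (manual) | Group B (automatic) |",
    "|---|---|---|",
    sprintf("| MDSC ± 1SD | %s | %s |", fmt(sa$mdsc, sa$dsc_sd), fmt(sb$mdsc, sb$dsc_sd)),
    sprintf("| MSHD (mm) ± 1SD | %s | %s |",
            fmt(sa$mshd_mean_mm, sa$mshd_sd_mm), fmt(sb$mshd_mean_mm, sb$mshd_sd_mm)),
    "",
    "## TIME ANALYSIS",
    "",
    "| | Group A (manual) | Group B (automatic) |",
    "|---|---|---|",
    sprintf("| T1 (min) | %s | %s |", fmt(ta$mean[["t1_min"]], ta$sd[["t1_min"]]),
            fmt(tb$mean[["t1_min"]], tb$sd[["t1_min"]])),
    sprintf("| T2 (min) | %s | %s |", fmt(ta$mean[["t2_min"]], ta$sd[["t2_min"]]),
            fmt(tb$mean[["t2_min"]], tb$sd[["t2_min"]])),
    sprintf("| TT (min) | %s | %s |", fmt(ta$mean[["tt_min"]], ta$sd[["tt_min"]]),
            fmt(tb$mean[["tt_min"]], tb$sd[["tt_min"]])),
    "",
    sprintf("TT saving: %.2f%% (ratio of means), %.2f%% (mean of per-patient savings).",
            report$time$saving_ratio_of_means_pct,
            report$time$saving_per_patient_mean_pct),
    sprintf("Paired t-test on TT differences: t = %.2f (df %d), p = %.3g, mean diff %.2f min (95%% CI %.2f to %.2f).",
            report$time$paired_t$t_statistic, report$time$paired_t$df,
            report$time$paired_t$p_value, report$time$paired_t$mean_diff_min,
            report$time$paired_t$ci95[1L], report$time$paired_t$ci95[2L]),
    "",
    "## DECISION",
    "",
    sprintf("- MDSC %.3f vs >= %.2f: %s", d$observed[["mdsc"]],
            d$criteria$dsc_min, ifelse(d$met[["mdsc"]], "met", "not met")),
    sprintf("- MSHD %.2f mm vs <= %.2f mm: %s", d$observed[["mshd_mean_mm"]],
            d$criteria$mshd_max_mm, ifelse(d$met[["mshd"]], "met", "not met")),
    sprintf("- TT saving %.1f%% vs >= %.0f%%: %s (mandatory)",
            d$observed[["tt_saving_pct"]], d$criteria$tt_saving_min_pct,
            ifelse(d$met[["tt_saving"]], "met", "not met")),
    sprintf("- %d/3 criteria met, mandatory criterion %s: **%s**", d$n_met,
            ifelse(d$mandatory_met, "met", "NOT met"),
            ifelse(d$accepted, "ACCEPTED", "REJECTED")),
    "",
    "## SENSITIVITY (worst patients removed)",
    "",
    sprintf("Removed: %s. MDSC %.2f (±%.2f), MSHD %.2f mm (±%.2f).",
            paste(report$sensitivity$removed_ids, collapse = ", "),
            report$sensitivity$summary$mdsc, report$sensitivity$summary$dsc_sd,
            report$sensitivity$summary$mshd_mean_mm,
            report$sensitivity$summary$mshd_sd_mm))
  sub <- report$subgroup
  lines <- c(lines, "", "## SLICE-THICKNESS SUBGROUPS", "")
  for (nm in names(sub$subgroups)) {
    s <- sub$subgroups[[nm]]
    lines <- c(lines, sprintf("- %s: n = %d, MDSC %.2f, MSHD %.2f mm",
                              nm, s$n_patients, s$mdsc, s$mshd_mean_mm))
  }
  if (!sub$test_skipped) {
    lines <- c(lines, sprintf(
      "- T2 thinner minus thicker: %.2f min (t = %.2f, p = %.3g, unpaired)",
      sub$t2_test$mean_diff_min, sub$t2_test$t_statistic, sub$t2_test$p_value))
  } else {
    lines <- c(lines, sprintf("- T2 subgroup test skipped: %s", sub$skip_reason))
  }
  lines
}

#' @export
print.qa_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Validate a report JSON against the shipped schema
#'
#' Structural check of required properties and primitive types against the
#' JSON-schema file installed with the package
#' (`inst/schema/qa_report.schema.json`).
#'
#' @param json path to a report JSON, or the parsed list.
#' @param schema_path schema file; default the installed schema.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report_json <- function(json,
                                 schema_path = system.file(
                                   "schema", "qa_report.schema.json",
                                   package = "ctvqa")) {
  obj <- if (is.character(json)) jsonlite::fromJSON(json, simplifyVector = FALSE)
         else json
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  resolve_ref <- function(sch) {
    ref <- sch[["$ref"]]
    if (is.null(ref)) return(sch)
    parts <- strsplit(sub("^#/", "", ref), "/")[[1L]]
    node <- schema
    for (p in parts) node <- node[[p]]
    node
  }
  check <- function(node, sch, where) {
    sch <- resolve_ref(sch)
    type <- sch$type
    if (identical(type, "object")) {
      if (!is.list(node)) stop("expected object at ", where)
      for (req in sch$required) {
        if (is.null(node[[req]])) stop("missing required property '", req, "' at ", where)
      }
      for (nm in names(sch$properties)) {
        if (!is.null(node[[nm]])) {
          check(node[[nm]], sch$properties[[nm]], paste0(where, ".", nm))
        }
      }
    } else if (identical(type, "number")) {
      if (!is.numeric(node) && !is.null(node)) stop("expected number at ", where)
    } else if (identical(type, "integer")) {
      if (!is.numeric(node)) stop("expected integer at ", where)
    } else if (identical(type, "boolean")) {
      if (!is.logical(node)) stop("expected boolean at ", where)
    } else if (identical(type, "string")) {
      if (!is.character(node)) stop("expected string at ", where)
    } else if (identical(type, "array")) {
      if (!is.list(node) && !is.atomic(node)) stop("expected array at ", where)
    }
    invisible(TRUE)
  }
  check(obj, schema, "$")
  invisible(TRUE)
}

#' Run the full synthetic study: simulate, write, evaluate, report
#'
#' Deterministic end to end: two runs with the same configuration and seed
#' produce byte-identical datasets and reports.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory; dataset under `dataset/`, report files at
#'   the top level.
#' @param seed overrides `config$seed` when given.
#' @param ... passed to [evaluate_cohort()].
#' @return the `qa_report`, invisibly.
#' @export
run_study <- function(config = synthetic_config(), out_dir, seed = NULL, ...) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  write_cohort(cohort, file.path(out_dir, "dataset"))
  report <- evaluate_cohort(cohort, ...)
  write_qa_report(report, out_dir)
  invisible(report)
}
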
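test_that("timing records derive TT and group summaries match hand arithmetic", {
  r <- timing_records(c("p1", "p2"), c("A", "A"), c(10, 16), c(8, 12))
  expect_equal(r$tt_min, c(18, 28))
  s <- group_time_summary(r)
  expect_equal(unname(s$mean), c(13, 10, 23))
  expect_equal(unname(s$sd), c(sd(c(10, 16)), sd(c(8, 12)), sd(c(18, 28))))
  # identical records -> SD 0
  s0 <- group_time_summary(timing_records(c("a", "b"), c("B", "B"),
                                          c(1.12, 1.12), c(9.72, 9.72)))
  expect_equal(unname(s0$sd), c(0, 0, 0))
  # single record: SD flagged undefined
  s1 <- group_time_summary(timing_records("a", "A", 13.12, 10.20))
  expect_false(s1$sd_defined)
  expect_equal(unname(s1$mean[["t1_min"]]), 13.12)
  expect_error(group_time_summary(r[0, ]), "empty")
  expect_error(timing_records("a", "C", 1, 1))
  expect_error(timing_records("a", "A", -1, 1))
})

test_that("time-saving estimators match hand arithmetic and identities", {
  expect_equal(time_saving_pct(20, 10), 50)
  expect_equal(time_saving_pct(7, 7), 0)
  expect_lt(time_saving_pct(10, 12), 0)
  expect_error(time_saving_pct(0, 5), "positive")
  # algebraic identity: saving + 100 b/a = 100
  set.seed(2)
  for (i in 1:20) {
    a <- stats::runif(1, 5, 40); b <- stats::runif(1, 1, 40)
    expect_equal(time_saving_pct(a, b) + 100 * b / a, 100, tolerance = 1e-12)
  }

  ra <- timing_records(c("p1", "p2"), c("A", "A"), c(15, 8), c(5, 2))
  rb <- timing_records(c("p2", "p1"), c("B", "B"), c(4, 5), c(5, 5))
  pp <- per_patient_saving(ra, rb)
  expect_equal(pp$per_patient$saving_pct, c(50, 10))  # (20,10) and (10,9)
  expect_equal(pp$mean_saving_pct, 30)
  rb_bad <- timing_records("p3", "B", 1, 1)
  expect_error(per_patient_saving(ra, rb_bad), "p1")
})

test_that("paired t-test reproduces the textbook closed form", {
  r <- paired_t_test(c(2.1, 1.9, 2.0, 2.2, 1.8))
  expect_equal(r$mean_diff_min, 2.0)
  expect_equal(r$t_statistic, 2.0 / (sd(c(2.1, 1.9, 2.0, 2.2, 1.8)) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(r$t_statistic, 28.2843, tolerance = 1e-4)
  expect_lt(r$p_value, 1e-5)
  expect_lte(r$ci95[1], r$mean_diff_min)
  expect_gte(r$ci95[2], r$mean_diff_min)

  sym <- paired_t_test(c(1, -1, 1, -1))
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)

  expect_error(paired_t_test(rep(2, 5)), "zero variance")
  expect_error(paired_t_test(3), "n >= 2")
})

test_that("acceptance engine applies inclusive thresholds and the mandatory rule", {
  # all three criteria pass
  d3 <- evaluate_acceptance(0.84, 0.87, 55.5)
  expect_equal(d3$n_met, 3L)
  expect_true(d3$accepted)
  # two met without the mandatory time saving -> rejected
  dr <- evaluate_acceptance(0.80, 0.90, 40.0)
  expect_equal(dr$n_met, 2L)
  expect_false(dr$met[["tt_saving"]])
  expect_false(dr$accepted)
  # exact boundary values are inclusive
  db <- evaluate_acceptance(0.75, 1.00, 50.0)
  expect_equal(db$n_met, 3L)
  expect_true(db$accepted)
  expect_error(evaluate_acceptance(NA, 1, 50), "finite")
})

test_that("acceptance is monotone: improving any observed value never revokes it", {
  set.seed(31)
  for (i in 1:50) {
    mdsc <- stats::runif(1, 0.5, 1)
    mshd <- stats::runif(1, 0.2, 3)
    sav <- stats::runif(1, 20, 70)
    base <- evaluate_acceptance(mdsc, mshd, sav)
    bumped <- evaluate_acceptance(min(mdsc + stats::runif(1, 0, 0.2), 1),
                                  mshd * stats::runif(1, 0.5, 1),
                                  sav + stats::runif(1, 0, 20))
    if (base$accepted) expect_true(bumped$accepted)
  }
})

test_that("outlier sensitivity removes the worst-ranked patients", {
  mk <- function(id, dsc, mshd) {
    structure(list(patient_id = id, dsc = dsc, slice_hd_mm = numeric(0),
                   mshd_mm = mshd, n_reference_slices = 1L,
                   n_unmatched_slices = 0L, slice_thickness_mm = 5),
              class = "overlap_result")
  }
  res <- list(mk("a", 1, 0.5), mk("b", 1, 0.5), mk("c", 0.2, 6))
  s <- outlier_sensitivity(res, 1)
  expect_equal(s$removed_ids, "c")
  expect_equal(s$summary$n_patients, 2L)
  # k = 0 leaves the summary unchanged
  s0 <- outlier_sensitivity(res, 0)
  expect_equal(s0$summary$mdsc, summarise_cohort(res)$mdsc)
  expect_error(outlier_sensitivity(res, 3), "smaller")
})

test_that("subgroup comparison summarises per thickness and tests T2", {
  mk <- function(id, dsc, mshd, thick) {
    structure(list(patient_id = id, dsc = dsc, slice_hd_mm = numeric(0),
                   mshd_mm = mshd, n_reference_slices = 1L,
                   n_unmatched_slices = 0L, slice_thickness_mm = thick),
              class = "overlap_result")
  }
  res <- c(lapply(1:4, function(i) mk(paste0("t", i), 0.8, 1, 5)),
           lapply(1:4, function(i) mk(paste0("u", i), 0.8, 1, 2.5)))
  tim <- timing_records(c(paste0("t", 1:4), paste0("u", 1:4)), rep("B", 8),
                        rep(1, 8), c(8, 9, 10, 11, 12, 13, 14, 15))
  sg <- subgroup_compare(res, tim)
  expect_named(sg$subgroups, c("2.5mm", "5mm"))
  expect_false(sg$test_skipped)
  # thinner group reviewed longer: positive difference
  expect_equal(sg$t2_test$mean_diff_min, mean(12:15) - mean(8:11))
  expect_equal(sg$t2_test$thinner_mm, 2.5)
  # single thickness: summaries only, test skipped with a reason
  sg1 <- subgroup_compare(res[1:4], tim[1:4, ])
  expect_true(sg1$test_skipped)
  expect_length(sg1$subgroups, 1L)
})

test_that("thin-slice IC-time effect is detectable at study scale, null is calibrated", {
  # power check: 2 min shift at n = 15 + 15 patients, across seeded replicates
  tm <- time_model(ic_thickness_effect_min = 2)
  hits <- 0L
  for (s in 1:10) {
    rec <- simulate_times(tm, sprintf("p%02d", 1:30), "B",
                          c(rep(5, 15), rep(2.5, 15)), seed = 1000 + s)
    thin <- c(rep(FALSE, 15), rep(TRUE, 15))
    tt <- stats::t.test(rec$t2_min[thin], rec$t2_min[!thin], var.equal = TRUE)
    if (unname(tt$estimate[1] - tt$estimate[2]) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 8L)  # shift direction recovered in most replicates
  # type-I calibration: no effect -> p roughly uniform (mean near 0.5)
  tm0 <- time_model(ic_thickness_effect_min = 0)
  ps <- vapply(1:20, function(s) {
    rec <- simulate_times(tm0, sprintf("p%02d", 1:30), "B",
                          c(rep(5, 15), rep(2.5, 15)), seed = 2000 + s)
    thin <- c(rep(FALSE, 15), rep(TRUE, 15))
    stats::t.test(rec$t2_min[thin], rec$t2_min[!thin], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
})
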
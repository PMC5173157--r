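test_that("reference generation: circles are exact, grids correct, seeds reproducible", {
  shp <- shape_params(n_slices = 10, slice_thickness_mm = 5, base_radius_mm = 20,
                      taper = 0, fourier_amps = numeric(0), centre_drift_mm = 0)
  ref <- generate_reference(shp, 42)
  radii <- sqrt(rowSums(ref$contours[[1]]$vertices^2))
  expect_lt(max(abs(radii - 20)), 1e-9)
  expect_equal(diff(range(delineation_z(ref))), 45)  # 10 slices at 5 mm
  expect_equal(length(ref$contours), 10L)
  # determinism: identical vertex lists for the same seed
  ref2 <- generate_reference(shp, 42)
  expect_identical(lapply(ref$contours, `[[`, "vertices"),
                   lapply(ref2$contours, `[[`, "vertices"))
  ref3 <- generate_reference(shape_params(n_slices = 10), 43)
  expect_false(identical(ref3$contours[[1]]$vertices, ref$contours[[1]]$vertices))
  # generation refuses shapes that would self-intersect
  expect_error(shape_params(fourier_amps = c(0.4, 0.3)), "sum")
})

test_that("perturbation is the identity at zero parameters and exact for pure bias", {
  shp <- shape_params(n_slices = 6, slice_thickness_mm = 5, base_radius_mm = 20,
                      taper = 0, fourier_amps = numeric(0), centre_drift_mm = 0)
  ref <- generate_reference(shp, 7)
  same <- perturb(ref, perturb_model(), 1)
  expect_identical(lapply(same$contours, `[[`, "vertices"),
                   lapply(ref$contours, `[[`, "vertices"))
  # pure 2 mm radial bias on a cylinder: analytic DSC and MSHD per slice
  out <- perturb(ref, perturb_model(radial_bias_mm = 2), 1)
  expect_equal(patient_mshd(ref, out)$mshd_mm, 2.0, tolerance = 1e-6)
  expect_equal(patient_dsc(ref, out), 2 * 20^2 / (20^2 + 22^2), tolerance = 1e-6)
  # truncation bookkeeping flows through to unmatched slices
  tr <- perturb(ref, perturb_model(extent_shift = list(prob = 1, max_slices = 2)), 5)
  lost <- 6L - length(tr$contours)
  expect_gte(lost, 1L)
  expect_equal(patient_mshd(ref, tr)$n_unmatched_slices, lost)
  # collapse guard
  expect_error(perturb(ref, perturb_model(radial_bias_mm = -25), 1), "collapses")
})

test_that("correlated noise field has the requested pointwise spread", {
  shp <- shape_params(n_slices = 4, slice_thickness_mm = 5, base_radius_mm = 25,
                      taper = 0, fourier_amps = numeric(0), centre_drift_mm = 0)
  ref <- generate_reference(shp, 3)
  # displacement of each vertex is radial with SD ~ sigma: estimate over seeds
  sig <- 1.5
  disp <- unlist(lapply(1:40, function(s) {
    p <- perturb(ref, perturb_model(radial_sigma_mm = sig, angular_corr = 0.8,
                                    axial_corr = 0.5), s)
    unlist(lapply(seq_along(p$contours), function(i) {
      sqrt(rowSums((p$contours[[i]]$vertices - ref$contours[[i]]$vertices)^2))
    }))
  }))
  expect_equal(sqrt(mean(disp^2)), sig, tolerance = 0.1)
})

test_that("cohort generation lays out the study and labels its outliers", {
  cfg <- synthetic_config(seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$profiles), 44L)
  expect_equal(sum(coh$profiles$role == "atlas"), 14L)
  expect_equal(sum(coh$profiles$role == "test"), 30L)
  expect_equal(sum(coh$profiles$slice_thickness_mm == 5), 29L)
  expect_equal(sum(coh$profiles$slice_thickness_mm == 2.5), 15L)
  expect_length(coh$delineations, 30L)
  expect_named(coh$delineations[[1]], c("reference", "manual", "auto"))
  expect_equal(nrow(coh$timings), 60L)
  expect_length(coh$provenance$outlier_ids, 2L)
  expect_true(all(coh$provenance$outlier_ids %in%
                    coh$profiles$patient_id[coh$profiles$role == "test"]))
  # BMI fields are internally consistent (validated constructor)
  expect_s3_class(coh$profiles, "patient_profiles")
  expect_error(synthetic_config(n_patients = 10, n_atlas = 12,
                                thickness_pattern = rep(5, 10)))
  expect_error(synthetic_config(thickness_pattern = rep(5, 3)))
})

test_that("injected outlier anatomies are the ones the sensitivity rule removes", {
  cfg <- synthetic_config(n_patients = 10, n_atlas = 2,
                          thickness_pattern = c(rep(5, 6), rep(2.5, 4)),
                          axial_extent_mm = 30, outlier_count = 2L, seed = 4)
  coh <- generate_cohort(cfg)
  res <- lapply(names(coh$delineations), function(pid) {
    trip <- coh$delineations[[pid]]
    compare_delineations(trip$reference, trip$auto)
  })
  sens <- outlier_sensitivity(res, 2)
  expect_setequal(sens$removed_ids, coh$provenance$outlier_ids)
  # removing them improves both cohort metrics
  full <- summarise_cohort(res)
  expect_gte(sens$summary$mdsc, full$mdsc)
  expect_lte(sens$summary$mshd_mean_mm, full$mshd_mean_mm)
})

test_that("expert-vs-auto calibration orders the groups on both metrics", {
  # group A (bias 0.5, sigma 1) vs group B (bias 1, sigma 2) across replicates
  hits_dsc <- 0L; hits_mshd <- 0L
  reps <- 10L
  for (s in seq_len(reps)) {
    shp <- shape_params(n_slices = 5, slice_thickness_mm = 5)
    seeds <- ctvqa:::derive_seeds(3000 + s, 24)
    res <- lapply(1:8, function(k) {
      ref <- generate_reference(shp, seeds[3 * k - 2])
      a <- perturb(ref, perturb_model(radial_bias_mm = 0.5, radial_sigma_mm = 1),
                   seeds[3 * k - 1])
      b <- perturb(ref, perturb_model(radial_bias_mm = 1, radial_sigma_mm = 2),
                   seeds[3 * k])
      c(dsc_a = patient_dsc(ref, a), dsc_b = patient_dsc(ref, b),
        hd_a = patient_mshd(ref, a)$mshd_mm, hd_b = patient_mshd(ref, b)$mshd_mm)
    })
    m <- colMeans(do.call(rbind, res))
    if (stats::median(vapply(res, `[[`, numeric(1), "dsc_a")) >
        stats::median(vapply(res, `[[`, numeric(1), "dsc_b"))) hits_dsc <- hits_dsc + 1L
    if (m[["hd_a"]] < m[["hd_b"]]) hits_mshd <- hits_mshd + 1L
  }
  expect_gte(hits_dsc, ceiling(0.95 * reps))
  expect_gte(hits_mshd, ceiling(0.95 * reps))
})

test_that("timing simulator is seed-stable and respects lognormal moment matching", {
  tm <- time_model()
  r1 <- simulate_times(tm, sprintf("p%d", 1:5), "A", 5, seed = 9)
  r2 <- simulate_times(tm, sprintf("p%d", 1:5), "A", 5, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$t1_min > 0))
  expect_equal(r1$tt_min, r1$t1_min + r1$t2_min)
  # analytic moment matching of the lognormal parameters
  p <- ctvqa:::lnorm_params(13.12, 4.84)
  expect_equal(exp(p$meanlog + p$sdlog^2 / 2), 13.12, tolerance = 1e-12)
  expect_equal(sqrt((exp(p$sdlog^2) - 1)) * 13.12, 4.84, tolerance = 1e-9)
  # single draw works; invalid targets refused
  expect_equal(nrow(simulate_times(tm, "p1", "B", 5, seed = 1)), 1L)
  expect_error(time_model(manual_t1 = c(10, 0)), "positive")
})

test_that("cohort artifacts are pure functions of config and seed", {
  cfg <- synthetic_config(n_patients = 8, n_atlas = 3,
                          thickness_pattern = c(rep(5, 6), rep(2.5, 2)),
                          axial_extent_mm = 20, outlier_count = 1L, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$timings, c2$timings)
  expect_identical(c1$provenance, c2$provenance)
  expect_identical(lapply(c1$delineations, function(t) lapply(t$auto$contours, `[[`, "vertices")),
                   lapply(c2$delineations, function(t) lapply(t$auto$contours, `[[`, "vertices")))
})
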
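test_that("patient DSC hits its anchors: identity, disjoint, concentric discs", {
  d1 <- cylinder_delineation("p", 10, 3, 5)
  expect_equal(patient_dsc(d1, d1), 1.0)

  far <- structure_delineation("p", "CTV", 5, lapply(0:2, function(i) {
    circle_contour(10, centre = c(50, 0), z = i * 5)
  }))
  expect_equal(patient_dsc(d1, far), 0.0)

  # concentric discs r = 10, 11: DSC = 2 r^2 / (r^2 + (r+d)^2) = 200/221
  d2 <- cylinder_delineation("p", 11, 3, 5)
  expect_equal(patient_dsc(d1, d2), 200 / 221, tolerance = 1e-3)
  # ... and the polygonal value is exact because similar polygons scale areas
  expect_equal(patient_dsc(d1, d2), 2 * 100 / (100 + 121), tolerance = 1e-9)

  # cross-check against the raster oracle on one slice
  raster <- oracle_raster_intersection(d1$contours[[1]]$vertices,
                                       d2$contours[[1]]$vertices, pixel = 0.05)
  a1 <- slice_region_area(d1$contours[1])
  a2 <- slice_region_area(d2$contours[1])
  expect_equal(patient_dsc(d1, d2), 2 * raster / (a1 + a2), tolerance = 1e-3)
})

test_that("DSC is symmetric, bounded, and 1 only for coincident regions", {
  set.seed(13)
  shp <- shape_params(n_slices = 4, slice_thickness_mm = 5)
  ref <- generate_reference(shp, 99)
  tst <- perturb(ref, perturb_model(radial_bias_mm = 0.5, radial_sigma_mm = 1), 3)
  expect_equal(patient_dsc(ref, tst), patient_dsc(tst, ref), tolerance = 1e-12)
  d <- patient_dsc(ref, tst)
  expect_gte(d, 0); expect_lt(d, 1)
  expect_equal(patient_dsc(ref, ref), 1.0)
})

test_that("slicewise symmetric Hausdorff matches analytic anchors", {
  c10 <- circle_contour(10)
  expect_equal(slice_symmetric_hausdorff(list(c10), list(c10)), 0.0)
  # concentric circles: uniform radial offset
  for (delta in c(0.5, 2)) {
    expect_equal(slice_symmetric_hausdorff(list(c10), list(circle_contour(10 + delta))),
                 delta, tolerance = 1e-3)
  }
  # translated unit square: 3-4-5 corner displacement, brute-force checked
  a <- clean_contour(square_verts())
  b <- clean_contour(square_verts(dx = 3, dy = 4))
  expect_equal(slice_symmetric_hausdorff(list(a), list(b)), 5.0, tolerance = 1e-6)
  expect_equal(oracle_hausdorff(a$vertices, b$vertices, step = 0.02), 5.0,
               tolerance = 0.02)
  expect_error(slice_symmetric_hausdorff(list(), list(c10)), "unmatched")
})

test_that("MSHD averages matched slices and books unmatched ones per policy", {
  ref <- cylinder_delineation("p", 10, 10, 5)
  expect_equal(patient_mshd(ref, ref)$mshd_mm, 0.0)
  expect_equal(patient_mshd(ref, ref)$n_unmatched_slices, 0L)

  # uniform 2 mm expansion on every slice
  grown <- cylinder_delineation("p", 12, 10, 5)
  m <- patient_mshd(ref, grown)
  expect_equal(m$mshd_mm, 2.0, tolerance = 1e-3)
  expect_equal(m$slice_hd_mm,
               setNames(rep(2, 10), format(seq(0, 45, by = 5), trim = TRUE)),
               tolerance = 1e-3)

  # test missing the 2 caudal slices, others identical
  trunc <- structure_delineation("p", "CTV", 5, ref$contours[3:10])
  ex <- patient_mshd(ref, trunc, "exclude")
  expect_equal(ex$mshd_mm, 0.0)
  expect_equal(ex$n_unmatched_slices, 2L)
  expect_equal(ex$n_reference_slices, 10L)
  # penalise: unmatched slices enter at thickness * slice gap (5, 10 mm)
  pen <- patient_mshd(ref, trunc, "penalise")
  expect_equal(pen$mshd_mm, (0 * 8 + 5 + 10) / 10)

  # no matched slice at all -> undefined MSHD
  shifted <- structure_delineation("p", "CTV", 5, lapply(ref$contours[1:3], function(ct) {
    ctvqa:::new_planar_contour(ct$vertices, ct$z_mm + 2.5)
  }))
  expect_error(patient_mshd(ref, shifted), "undefined MSHD")
})

test_that("DSC and MSHD are invariant under a common rigid transform", {
  set.seed(5)
  shp <- shape_params(n_slices = 3, slice_thickness_mm = 5)
  ref <- generate_reference(shp, 21)
  tst <- perturb(ref, perturb_model(radial_bias_mm = 1, radial_sigma_mm = 1), 4)
  move <- function(sd, ang, shift) {
    structure_delineation(sd$patient_id, sd$label, sd$slice_thickness_mm,
                          lapply(sd$contours, function(ct) {
                            ctvqa:::new_planar_contour(
                              rigid_transform(ct$vertices, ang, shift), ct$z_mm)
                          }))
  }
  d0 <- patient_dsc(ref, tst)
  h0 <- patient_mshd(ref, tst)$mshd_mm
  refm <- move(ref, 0.6, c(30, -12))
  tstm <- move(tst, 0.6, c(30, -12))
  expect_equal(patient_dsc(refm, tstm), d0, tolerance = 1e-6)
  expect_equal(patient_mshd(refm, tstm)$mshd_mm, h0, tolerance = 1e-6)
})

test_that("cohort summary uses median DSC and n-1 SDs", {
  mk <- function(id, dsc, mshd) {
    structure(list(patient_id = id, dsc = dsc, slice_hd_mm = numeric(0),
                   mshd_mm = mshd, n_reference_slices = 1L,
                   n_unmatched_slices = 0L, slice_thickness_mm = 5),
              class = "overlap_result")
  }
  s3 <- summarise_cohort(list(mk("a", 0.7, 1), mk("b", 0.75, 2), mk("c", 0.8, 3)))
  expect_equal(s3$mdsc, 0.75)
  expect_equal(s3$dsc_sd, sd(c(0.7, 0.75, 0.8)))
  expect_equal(s3$mshd_mean_mm, 2)
  # even n: midpoint convention
  s2 <- summarise_cohort(list(mk("a", 0.7, 1), mk("b", 0.8, 2)))
  expect_equal(s2$mdsc, 0.75)
  # degenerate cohort: SD reported 0 and flagged
  s1 <- summarise_cohort(list(mk("a", 0.9, 1)))
  expect_equal(s1$mdsc, 0.9)
  expect_equal(s1$dsc_sd, 0)
  expect_false(s1$sd_defined)
})
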
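test_that("clean_contour normalises orientation, deduplicates and rejects degenerates", {
  sq <- square_verts()
  cc <- clean_contour(sq[4:1, ])  # clockwise input
  expect_gt(ctvqa:::shoelace_area(cc$vertices), 0)
  expect_equal(sort(apply(cc$vertices, 1, paste, collapse = ",")),
               sort(apply(sq, 1, paste, collapse = ",")))

  tri <- rbind(c(0, 0), c(0, 0), c(2, 0), c(0, 2))
  expect_equal(nrow(clean_contour(tri)$vertices), 3L)
  # duplicated closing vertex is also dropped
  expect_equal(nrow(clean_contour(rbind(sq, sq[1, ]))$vertices), 4L)

  expect_error(clean_contour(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(clean_contour(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  # bowtie with unequal lobes: nonzero area but crossing edges
  expect_error(clean_contour(cbind(c(0, 4, 4, 0), c(0, 4, 0, 2))),
               "self-intersecting")
})

test_that("slice areas match closed forms and union semantics", {
  a <- clean_contour(square_verts())
  expect_equal(slice_region_area(list(a)), 1.0)
  b3 <- clean_contour(square_verts(dx = 3))
  expect_equal(slice_region_area(list(a, b3)), 2.0)
  expect_equal(slice_region_area(list(a, a)), 1.0)
  # partial overlap: union = 2 - overlap
  bh <- clean_contour(square_verts(dx = 0.5))
  expect_equal(slice_region_area(list(a, bh)), 1.5)
})

test_that("intersection areas match closed forms", {
  a <- clean_contour(square_verts())
  expect_equal(slice_intersection_area(list(a), list(a)), 1.0)
  expect_equal(slice_intersection_area(list(a), list(clean_contour(square_verts(dx = 3)))), 0.0)
  expect_equal(slice_intersection_area(list(a), list(clean_contour(square_verts(dx = 0.5)))), 0.5)
  # externally touching squares share a zero-area boundary
  expect_equal(slice_intersection_area(list(a), list(clean_contour(square_verts(dx = 1)))), 0.0)
  # nested regions: intersection equals the inner area
  big <- clean_contour(square_verts(4, -1.5, -1.5))
  expect_equal(slice_intersection_area(list(a), list(big)), 1.0)
})

test_that("area and intersection are invariant under rigid transforms and symmetric", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_star_polygon()
    ang <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(2, 0, 20)
    pt <- clean_contour(rigid_transform(p$vertices, ang, shift))
    expect_equal(slice_region_area(list(pt)), slice_region_area(list(p)),
                 tolerance = 1e-9)
    q <- random_star_polygon()
    ab <- slice_intersection_area(list(p), list(q))
    ba <- slice_intersection_area(list(q), list(p))
    expect_identical(ab, ba)
    expect_lte(ab, min(slice_region_area(list(p)), slice_region_area(list(q))) + 1e-12)
  }
})

test_that("exact intersection agrees with the raster oracle on random polygons", {
  set.seed(7)
  for (i in 1:3) {
    p <- random_star_polygon(r0 = 3)
    q <- random_star_polygon(r0 = 3)
    q$vertices <- sweep(q$vertices, 2L, c(1.0, 0.5), "+")
    exact <- slice_intersection_area(list(p), list(q))
    raster <- oracle_raster_intersection(p$vertices, q$vertices, pixel = 0.05)
    expect_equal(exact, raster, tolerance = 0.02)
  }
})

test_that("resample_boundary honours the step and stays on the boundary", {
  sq4 <- clean_contour(square_verts(4))
  expect_equal(nrow(resample_boundary(list(sq4), 1)), 16L)
  # step beyond every edge length: original vertices only
  expect_equal(nrow(resample_boundary(list(sq4), 100)), 4L)
  circ <- circle_contour(5, n = 360)
  pts <- resample_boundary(list(circ), 0.1)
  gaps <- sqrt(rowSums((pts[c(2:nrow(pts), 1L), ] - pts)^2))
  expect_lte(max(gaps), 0.1 + 1e-12)
  expect_lt(max(ctvqa:::dist_to_boundary(pts, list(circ))), 1e-9)
  expect_error(resample_boundary(list(sq4), 0))
})

test_that("delineations validate slice grids and snap-match slices", {
  c1 <- clean_contour(square_verts(), z_mm = 0)
  c2 <- clean_contour(square_verts(), z_mm = 5)
  sd <- structure_delineation("p1", "CTV", 5, list(c2, c1))
  expect_equal(delineation_z(sd), c(0, 5))  # sorted ascending
  expect_length(contours_at(sd, 5.005), 1L)  # within 0.01 mm snap
  expect_length(contours_at(sd, 5.5), 0L)
  bad <- clean_contour(square_verts(), z_mm = 7.3)
  expect_error(structure_delineation("p1", "CTV", 5, list(c1, c2, bad)),
               "common grid")
})
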
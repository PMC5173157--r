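#' Exact planar polygon geometry
#'
#' Area, boolean-overlap and boundary primitives used by the overlap metrics.
#' Areas and intersections are computed exactly from the polygon geometry
#' (shoelace formula plus a Green's-theorem boundary integral over the pieces
#' of each boundary lying inside the other region), never by rasterisation,
#' so raster resolution is not a hidden parameter of the Dice coefficient.
#'
#' A "region" below is a list of `planar_contour`s (or bare vertex matrices)
#' sharing one slice, interpreted as the union of their interiors; polygons
#' within one slice are assumed to have disjoint interiors (holes are not
#' modelled).
#'
#' @name polygon-geometry
NULL

# signed shoelace area; positive for counter-clockwise vertex order
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  0.5 * sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])
}

# vertex matrices from a region (list of planar_contour or matrices)
region_vertices <- function(region) {
  if (inherits(region, "planar_contour")) region <- list(region)
  lapply(region, function(p) if (inherits(p, "planar_contour")) p$vertices else as.matrix(p))
}

# edge start/end matrices for one polygon
polygon_edges <- function(v) {
  n <- nrow(v)
  list(S = v, E = v[c(2:n, 1L), , drop = FALSE])
}

region_edges <- function(region) {
  vs <- region_vertices(region)
  eds <- lapply(vs, polygon_edges)
  list(S = do.call(rbind, lapply(eds, `[[`, "S")),
       E = do.call(rbind, lapply(eds, `[[`, "E")))
}

# distances from each point (m x 2) to each segment (S, E: n x 2) -> m x n;
# flat-vector arithmetic (column-major, point index fastest) keeps this fast
# min distance from each point to a region's boundary (C++ kernel)
dist_to_boundary <- function(P, region) {
  ed <- region_edges(region)
  sqrt(min_sqdist_to_segments_cpp(P, ed$S, ed$E))
}

# even-odd inside test for points vs one polygon (no boundary handling)
points_in_polygon <- function(P, v) {
  points_in_polygon_cpp(P, v)
}

# classify points against a region: 0 outside, 1 strictly inside, 2 on boundary
classify_points <- function(P, region, tol = 1e-9) {
  out <- integer(nrow(P))
  on_bd <- dist_to_boundary(P, region) <= tol
  inside <- rep(FALSE, nrow(P))
  for (v in region_vertices(region)) {
    inside <- inside | points_in_polygon(P, v)
  }
  out[inside] <- 1L
  out[on_bd] <- 2L
  out
}

# self-intersection test for one polygon (non-adjacent edge pairs)
is_simple_polygon <- function(v, tol = 1e-9) {
  n <- nrow(v)
  if (n < 4L) return(TRUE)  # a triangle with nonzero area is simple
  ed <- polygon_edges(v)
  cr <- segment_crossings(ed$S, ed$E, ed$S, ed$E, param_tol = 0)
  if (!length(cr$i)) return(TRUE)
  adjacent <- cr$i == cr$j | abs(cr$i - cr$j) == 1L | abs(cr$i - cr$j) == n - 1L
  t <- cr$t[!adjacent]; u <- cr$u[!adjacent]; col <- cr$collinear[!adjacent]
  if (!length(t)) return(TRUE)
  # a genuine crossing has a parameter strictly interior, or the edges
  # overlap collinearly
  eps <- 1e-9
  proper <- (t > eps & t < 1 - eps) | (!is.na(u) & u > eps & u < 1 - eps) | col
  !any(proper)
}

# All crossings between edge set 1 (S1,E1: n1 x 2) and edge set 2 (n2 x 2).
# Returns edge indices i (set 1), j (set 2), parameter t along edge i, u
# along edge j, and a collinear flag. For collinear overlapping pairs, the
# projections of edge j's endpoints onto edge i are emitted (u is NA).
segment_crossings <- function(S1, E1, S2, E2, param_tol = 1e-12) {
  segment_crossings_cpp(S1, E1, S2, E2, param_tol)
}

# Green's-theorem integral of x dy - y dx over the pieces of region A's
# boundary lying inside region `against`; on-boundary pieces get weight 1/2
# (coincident arcs traversed the same way then sum to 1; externally touching
# arcs cancel). Returns the signed area contribution.
half_boundary_integral <- function(A, against, tol = 1e-9) {
  edA <- region_edges(A)
  edB <- region_edges(against)
  cr <- segment_crossings(edA$S, edA$E, edB$S, edB$E)
  n1 <- nrow(edA$S)
  crossed <- sort(unique(cr$i))
  plain <- setdiff(seq_len(n1), crossed)
  # edges without crossings are single sub-segments; subdivide the rest
  seg_i <- plain
  seg_a <- rep.int(0, length(plain))
  seg_b <- rep.int(1, length(plain))
  for (e in crossed) {
    ts <- sort(unique(c(0, 1, cr$t[cr$i == e])))
    ts <- ts[c(TRUE, diff(ts) > 1e-12)]
    if (length(ts) < 2L) next
    k <- length(ts) - 1L
    seg_i <- c(seg_i, rep.int(e, k))
    seg_a <- c(seg_a, ts[-length(ts)])
    seg_b <- c(seg_b, ts[-1L])
  }
  dx <- edA$E[seg_i, 1L] - edA$S[seg_i, 1L]
  dy <- edA$E[seg_i, 2L] - edA$S[seg_i, 2L]
  mx <- edA$S[seg_i, 1L] + 0.5 * (seg_a + seg_b) * dx
  my <- edA$S[seg_i, 2L] + 0.5 * (seg_a + seg_b) * dy
  cls <- classify_points(cbind(mx, my), against, tol = tol)
  w <- c(0, 1, 0.5)[cls + 1L]
  ax <- edA$S[seg_i, 1L] + seg_a * dx; ay <- edA$S[seg_i, 2L] + seg_a * dy
  bx <- edA$S[seg_i, 1L] + seg_b * dx; by <- edA$S[seg_i, 2L] + seg_b * dy
  0.5 * sum(w * (ax * by - bx * ay))
}

#' Area of the union region on one slice
#'
#' Exact area (mm^2) of the union of the polygon interiors, from polygon
#' geometry (shoelace plus boundary-piece weighting for coincident edges).
#'
#' @param contours_on_slice list of `planar_contour` (or vertex matrices)
#'   sharing one z.
#' @return area in mm^2.
#' @export
slice_region_area <- function(contours_on_slice) {
  vs <- region_vertices(contours_on_slice)
  if (!length(vs)) return(0)
  if (length(vs) == 1L) return(abs(shoelace_area(vs[[1L]])))
  total <- 0
  for (i in seq_along(vs)) {
    others <- vs[-i]
    edA <- polygon_edges(vs[[i]])
    edB <- region_edges(others)
    cr <- segment_crossings(edA$S, edA$E, edB$S, edB$E)
    n1 <- nrow(edA$S)
    for (e in seq_len(n1)) {
      ts <- sort(unique(c(0, 1, cr$t[cr$i == e])))
      ts <- ts[c(TRUE, diff(ts) > 1e-12)]
      p1 <- edA$S[e, ]; p2 <- edA$E[e, ]
      for (k in seq_len(length(ts) - 1L)) {
        a <- p1 + ts[k] * (p2 - p1)
        b <- p1 + ts[k + 1L] * (p2 - p1)
        mid <- matrix(0.5 * (a + b), 1L, 2L)
        cls <- classify_points(mid, others)
        w <- if (cls == 1L) 0 else if (cls == 2L) 0.5 else 1
        total <- total + w * 0.5 * (a[1L] * b[2L] - b[1L] * a[2L])
      }
    }
  }
  abs(total)
}

#' Intersection area of two union regions on one slice
#'
#' Exact area (mm^2) of the intersection of the two regions; the |A n B| term
#' of the Dice coefficient. Symmetric in its arguments by construction.
#'
#' @param a,b lists of `planar_contour` (or vertex matrices) on the same z.
#' @return area in mm^2, within `[0, min(area(a), area(b))]`.
#' @export
slice_intersection_area <- function(a, b) {
  ia <- half_boundary_integral(a, b) + half_boundary_integral(b, a)
  max(ia, 0)
}

#' Resample a slice boundary at a fixed arc-length step
#'
#' Places points along each polygon's perimeter at intervals no larger than
#' `step_mm`; original vertices are always retained, so the sampled set lies
#' exactly on the boundary and never under-represents corners.
#'
#' @param contours_on_slice list of `planar_contour` (or vertex matrices).
#' @param step_mm maximum arc-length spacing, mm (> 0).
#' @return two-column matrix of boundary points.
#' @export
resample_boundary <- function(contours_on_slice, step_mm) {
  stopifnot(is.numeric(step_mm), step_mm > 0)
  vs <- region_vertices(contours_on_slice)
  pts <- lapply(vs, function(v) {
    ed <- polygon_edges(v)
    len <- sqrt(rowSums((ed$E - ed$S)^2))
    nsub <- pmax(1L, ceiling(len / step_mm))
    idx <- rep.int(seq_len(nrow(v)), nsub)
    tt <- (sequence(nsub) - 1L) / rep.int(nsub, nsub)
    cbind(ed$S[idx, 1L] + tt * (ed$E[idx, 1L] - ed$S[idx, 1L]),
          ed$S[idx, 2L] + tt * (ed$E[idx, 2L] - ed$S[idx, 2L]))
  })
  do.call(rbind, pts)
}
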
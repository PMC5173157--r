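#' Planar contour and structure delineation data model
#'
#' A `planar_contour` is one simple closed polygon on an axial CT slice,
#' stored as an ordered vertex matrix in patient-space millimetres
#' (closure implicit: the last vertex connects back to the first). A
#' `structure_delineation` is a stack of such contours grouped by slice
#' position, with slice-thickness metadata — the in-memory form of one
#' delineated structure (typically a rectal CTV).
#'
#' Coordinates are millimetres throughout; no pixel-index coordinates appear
#' in the public data model. Orientation is normalised counter-clockwise on
#' ingest. Multiple polygons on one slice are treated as a union region;
#' holes are not modelled.
#'
#' @name contour-model
NULL

#' Clean and validate a raw contour
#'
#' Removes consecutive duplicate vertices (including a duplicated closing
#' vertex), verifies the polygon is simple and non-degenerate, and normalises
#' orientation to counter-clockwise. Collinear runs are preserved: the shape
#' is never simplified.
#'
#' @param raw_vertices two-column matrix (or coercible) of (x, y) vertices, mm.
#' @param z_mm axial slice position in mm.
#' @param dedup_tol consecutive vertices closer than this (mm) are merged.
#' @param check_simple verify no self-intersection (O(n^2); generators whose
#'   output is star-shaped by construction may skip it).
#' @return a `planar_contour`: list with `z_mm` and `vertices` (n x 2, CCW).
#' @export
clean_contour <- function(raw_vertices, z_mm = 0, dedup_tol = 1e-9,
                          check_simple = TRUE) {
  v <- as.matrix(raw_vertices)
  if (!is.numeric(v) || ncol(v) != 2L || anyNA(v)) {
    stop("contour vertices must be a numeric n x 2 matrix without NAs")
  }
  # drop consecutive duplicates, then a duplicated closing vertex
  if (nrow(v) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(v))) > dedup_tol)
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) > 1L && sum(abs(v[1L, ] - v[nrow(v), ])) <= dedup_tol) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 3L) {
    stop("degenerate contour: fewer than 3 distinct vertices")
  }
  a <- shoelace_area(v)
  if (abs(a) <= 1e-12) {
    stop("degenerate contour: zero area")
  }
  if (a < 0) v <- v[nrow(v):1L, , drop = FALSE]
  if (check_simple && !is_simple_polygon(v)) {
    stop("contour polygon is self-intersecting after cleaning")
  }
  new_planar_contour(v, z_mm)
}

# internal constructor: trusts its input (used by generators whose polygons
# are simple by construction)
new_planar_contour <- function(vertices, z_mm) {
  structure(list(z_mm = as.numeric(z_mm),
                 vertices = unname(as.matrix(vertices))),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> z = %.3f mm, %d vertices, area %.2f mm^2\n",
              x$z_mm, nrow(x$vertices), shoelace_area(x$vertices)))
  invisible(x)
}

#' Assemble a structure delineation from planar contours
#'
#' @param patient_id patient identifier.
#' @param label structure name, e.g. `"CTV"`.
#' @param slice_thickness_mm positive slice thickness, mm.
#' @param contours list of [clean_contour()] results (one or more per slice).
#' @param grid_tol tolerance (mm) for the common-z-grid invariant.
#' @return a `structure_delineation` with contours sorted by ascending z.
#' @export
structure_delineation <- function(patient_id, label, slice_thickness_mm,
                                  contours, grid_tol = 1e-6) {
  stopifnot(is.numeric(slice_thickness_mm), slice_thickness_mm > 0)
  if (!length(contours)) stop("a structure_delineation needs >= 1 contour")
  ok <- vapply(contours, inherits, logical(1), "planar_contour")
  if (!all(ok)) stop("all contours must be planar_contour objects")
  z <- vapply(contours, function(ct) ct$z_mm, numeric(1))
  contours <- contours[order(z)]
  z <- sort(z)
  zu <- unique(z)
  if (length(zu) > 1L) {
    d <- diff(zu)
    step <- min(d)
    if (any(abs(d / step - round(d / step)) * step > grid_tol)) {
      stop("slice z positions do not lie on a common grid (tolerance 1e-6 mm)")
    }
  }
  structure(list(patient_id = as.character(patient_id),
                 label = as.character(label),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 contours = contours),
            class = "structure_delineation")
}

#' @export
print.structure_delineation <- function(x, ...) {
  z <- delineation_z(x)
  cat(sprintf(
    "<structure_delineation> %s / %s: %d contour(s) on %d slice(s), dz = %g mm, z in [%.2f, %.2f] mm\n",
    x$patient_id, x$label, length(x$contours), length(unique(z)),
    x$slice_thickness_mm, min(z), max(z)))
  invisible(x)
}

#' Slice positions of a delineation
#'
#' @param sd a `structure_delineation`.
#' @return numeric vector of z positions, one per contour (ascending).
#' @export
delineation_z <- function(sd) {
  vapply(sd$contours, function(ct) ct$z_mm, numeric(1))
}

#' Contours of a delineation on one slice
#'
#' Slice lookup snaps to the common grid: z values within `tol` are the same
#' slice (both delineations in a comparison derive from the same planning CT).
#'
#' @param sd a `structure_delineation`.
#' @param z_mm slice position, mm.
#' @param tol match tolerance, mm (default 0.01).
#' @return list of `planar_contour` (possibly empty).
#' @export
contours_at <- function(sd, z_mm, tol = 0.01) {
  z <- delineation_z(sd)
  sd$contours[abs(z - z_mm) <= tol]
}
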
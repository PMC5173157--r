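# Fixture shapes and independent pure-R oracles. Everything here is written
# against the geometry definitions directly (no package internals), so the
# package's C++/boundary-integral paths are cross-checked by a separate route.

square_verts <- function(side = 1, dx = 0, dy = 0) {
  cbind(c(0, side, side, 0) + dx, c(0, 0, side, side) + dy)
}

circle_contour <- function(r, n = 360, centre = c(0, 0), z = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  clean_contour(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)), z)
}

# random smooth star-shaped polygon (guaranteed simple)
random_star_polygon <- function(r0 = 3, n = 90, z = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- rep(r0, n)
  for (k in 1:5) {
    r <- r + r0 * stats::runif(1, 0, 0.06) * cos(k * th + stats::runif(1, 0, 2 * pi))
  }
  clean_contour(cbind(r * cos(th), r * sin(th)), z)
}

rigid_transform <- function(v, angle = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  sweep(v %*% t(R), 2L, shift, "+")
}

# dense boundary sampling by arc length (oracle's own resampler)
oracle_resample <- function(v, step) {
  n <- nrow(v)
  out <- vector("list", n)
  for (e in seq_len(n)) {
    p <- v[e, ]
    q <- v[if (e == n) 1L else e + 1L, ]
    L <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(L / step))
    tt <- (seq_len(k) - 1L) / k
    out[[e]] <- cbind(p[1L] + tt * (q[1L] - p[1L]), p[2L] + tt * (q[2L] - p[2L]))
  }
  do.call(rbind, out)
}

# brute-force symmetric Hausdorff: max-min over densely sampled point pairs
oracle_hausdorff <- function(va, vb, step = 0.02) {
  A <- oracle_resample(va, step)
  B <- oracle_resample(vb, step)
  directed <- function(P, Q) {
    max(vapply(seq_len(nrow(P)), function(i) {
      sqrt(min((Q[, 1L] - P[i, 1L])^2 + (Q[, 2L] - P[i, 2L])^2))
    }, numeric(1)))
  }
  max(directed(A, B), directed(B, A))
}

# even-odd point-in-polygon, plain R
oracle_pip <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 2L]; yj <- v[j, 2L]
    str <- (yi > py) != (yj > py)
    if (any(str)) {
      xint <- v[i, 1L] + (py[str] - yi) * (v[j, 1L] - v[i, 1L]) / (yj - yi)
      flip <- which(str)[px[str] < xint]
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# rasterised intersection area over a pixel grid (the GridSpec oracle)
oracle_raster_intersection <- function(va, vb, pixel = 0.05, margin = 1) {
  xs <- range(c(va[, 1L], vb[, 1L])) + c(-margin, margin)
  ys <- range(c(va[, 2L], vb[, 2L])) + c(-margin, margin)
  gx <- seq(xs[1L] + pixel / 2, xs[2L], by = pixel)
  gy <- seq(ys[1L] + pixel / 2, ys[2L], by = pixel)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  ina <- oracle_pip(px, py, va)
  inb <- oracle_pip(px, py, vb)
  sum(ina & inb) * pixel^2
}

# stacked-circle delineation for metric closed forms
cylinder_delineation <- function(patient_id, r, n_slices, dz, n = 360,
                                 label = "CTV") {
  contours <- lapply(seq_len(n_slices) - 1L, function(i) {
    circle_contour(r, n = n, z = i * dz)
  })
  structure_delineation(patient_id, label, dz, contours)
}
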
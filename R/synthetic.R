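#' Synthetic delineation cohort generator
#'
#' Seeded generator of the whole study's inputs: reference CTV-like shapes
#' (stacked star-shaped polygons with a tapered axial radius profile, Fourier
#' boundary irregularity and a drifting in-slice centre), "expert manual" and
#' "auto-segmented" perturbations of them (systematic radial bias plus a
#' boundary-correlated Gaussian field, optional cranio-caudal truncation and
#' localized outlier bumps), patient profiles, and lognormal delineation-time
#' logs. Every artifact is a pure function of configuration plus seed.
#'
#' @name synthetic-cohort
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Shape parameters for a synthetic reference CTV
#'
#' The reference is one closed polygon per slice,
#' `r(theta, z) = R(z) * (1 + sum_k a_k cos(k theta + phi_k))`, sampled at
#' `n_vertices` angles, with `R(z)` a smoothly tapered axial profile and the
#' slice centre following a smooth drift path. Phases and drift direction are
#' drawn from the generation seed.
#'
#' @param n_slices number of axial slices.
#' @param slice_thickness_mm slice spacing, mm.
#' @param base_radius_mm mid-structure radius, mm.
#' @param taper fractional radius reduction at the cranial/caudal ends
#'   (`R(end) = (1 - taper) * base_radius_mm`), in `[0, 0.9]`.
#' @param fourier_amps relative amplitudes of boundary harmonics k = 2, 3, ...
#'   (`sum < 0.5` keeps the polygon star-shaped and simple).
#' @param centre_drift_mm peak in-slice centre excursion, mm.
#' @param n_vertices vertices per polygon (>= 180 recommended).
#' @return a `shape_params` list.
#' @export
shape_params <- function(n_slices = 21, slice_thickness_mm = 5,
                         base_radius_mm = 25, taper = 0.35,
                         fourier_amps = c(0.05, 0.03, 0.015),
                         centre_drift_mm = 4, n_vertices = 180L) {
  stopifnot(n_slices >= 1, slice_thickness_mm > 0, base_radius_mm > 0,
            taper >= 0, taper <= 0.9, all(fourier_amps >= 0),
            sum(fourier_amps) < 0.5, centre_drift_mm >= 0, n_vertices >= 3L)
  structure(list(n_slices = as.integer(n_slices),
                 slice_thickness_mm = slice_thickness_mm,
                 base_radius_mm = base_radius_mm, taper = taper,
                 fourier_amps = fourier_amps,
                 centre_drift_mm = centre_drift_mm,
                 n_vertices = as.integer(n_vertices)),
            class = "shape_params")
}

#' Generate a synthetic reference delineation
#'
#' @param shape a [shape_params()] object.
#' @param seed integer seed; the output is a pure function of shape + seed.
#' @param patient_id,label identifiers for the resulting delineation.
#' @return a `structure_delineation` (one polygon per slice, z starting at 0).
#' @export
generate_reference <- function(shape, seed, patient_id = "SYN", label = "CTV") {
  with_seed(seed, {
    ns <- shape$n_slices
    dz <- shape$slice_thickness_mm
    z <- (seq_len(ns) - 1L) * dz
    u <- if (ns > 1L) 2 * (z - mean(z)) / (max(z) - min(z)) else 0 * z  # [-1, 1]
    Rz <- shape$base_radius_mm * (1 - shape$taper * u^2)
    theta <- 2 * pi * (seq_len(shape$n_vertices) - 1L) / shape$n_vertices
    amps <- shape$fourier_amps
    phases <- stats::runif(length(amps), 0, 2 * pi)
    drift_phase <- stats::runif(2L, 0, 2 * pi)
    modulation <- rep(1, length(theta))
    for (k in seq_along(amps)) {
      modulation <- modulation + amps[k] * cos((k + 1L) * theta + phases[k])
    }
    contours <- vector("list", ns)
    for (i in seq_len(ns)) {
      r <- Rz[i] * modulation
      if (any(r <= 0)) {
        stop(sprintf("shape parameters yield a non-simple polygon on slice %d (non-positive radius)", i))
      }
      cx <- shape$centre_drift_mm * 0.5 * sin(pi * u[i] + drift_phase[1L])
      cy <- shape$centre_drift_mm * 0.5 * sin(pi * u[i] + drift_phase[2L])
      v <- cbind(cx + r * cos(theta), cy + r * sin(theta))
      contours[[i]] <- new_planar_contour(v, z[i])
    }
    structure_delineation(patient_id, label, dz, contours)
  })
}

#' Boundary perturbation model
#'
#' Radial displacement applied to every boundary vertex:
#' `bias + f(theta, z)` where `f` is a zero-mean Gaussian field with pointwise
#' SD `radial_sigma_mm`, synthesised spectrally on the boundary angle
#' (harmonic variances decay as `(1 - angular_corr)^k`, so 1 = a single
#' uniform shift per slice, near 0 = rough jitter) and carried across slices
#' by an AR(1) process with coefficient `axial_corr`. Optionally truncates
#' end slices (cranio-caudal extent disagreement) and adds a localized
#' outward bump (the "irregular anatomy" failure mode).
#'
#' @param radial_bias_mm systematic over-contouring (+) / under-contouring
#'   (-), mm.
#' @param radial_sigma_mm pointwise SD of the random boundary field, mm
#'   (>= 0).
#' @param angular_corr smoothness of the field along the boundary, in
#'   `(0, 1]`.
#' @param axial_corr smoothness of the field across slices, in `(0, 1]`.
#' @param extent_shift list `(prob, max_slices)`: with probability `prob`,
#'   1..`max_slices` caudal slices are dropped.
#' @param outlier `NULL`, or list `(amplitude_mm, angular_width, span_mm)`
#'   describing a Gaussian-profile outward bump on the central slices;
#'   `span_mm` is the axial extent of the bump in mm, so the emulated
#'   anatomy has the same physical size at any slice thickness.
#' @return a `perturb_model` list.
#' @export
perturb_model <- function(radial_bias_mm = 0, radial_sigma_mm = 0,
                          angular_corr = 0.85, axial_corr = 0.7,
                          extent_shift = list(prob = 0, max_slices = 0),
                          outlier = NULL) {
  stopifnot(radial_sigma_mm >= 0,
            angular_corr > 0, angular_corr <= 1,
            axial_corr > 0, axial_corr <= 1,
            extent_shift$prob >= 0, extent_shift$prob <= 1)
  if (!is.null(outlier)) stopifnot(outlier$amplitude_mm >= 0)
  structure(list(radial_bias_mm = radial_bias_mm,
                 radial_sigma_mm = radial_sigma_mm,
                 angular_corr = angular_corr, axial_corr = axial_corr,
                 extent_shift = extent_shift, outlier = outlier),
            class = "perturb_model")
}

# correlated radial noise field evaluated at each slice's vertex angles;
# returns a list of numeric vectors (one per slice)
radial_noise_field <- function(thetas_by_slice, sigma, angular_corr, axial_corr) {
  ns <- length(thetas_by_slice)
  if (sigma <= 0) return(lapply(thetas_by_slice, function(th) 0 * th))
  kmax <- 15L
  lambda <- 1 - angular_corr
  w2 <- lambda^(0:kmax)          # harmonic variances, k = 0 .. kmax
  s <- sigma * sqrt(w2 / sum(w2))  # pointwise SD sums to sigma^2
  # AR(1) coefficient streams across slices, unit marginal variance
  draw_ar1 <- function() {
    x <- numeric(ns)
    x[1L] <- stats::rnorm(1L)
    if (ns > 1L) {
      innov <- stats::rnorm(ns - 1L)
      for (i in 2:ns) x[i] <- axial_corr * x[i - 1L] + sqrt(1 - axial_corr^2) * innov[i - 1L]
    }
    x
  }
  a <- vapply(0:kmax, function(k) draw_ar1(), numeric(ns))  # ns x (kmax+1)
  b <- vapply(0:kmax, function(k) draw_ar1(), numeric(ns))
  lapply(seq_len(ns), function(i) {
    th <- thetas_by_slice[[i]]
    f <- rep(a[i, 1L] * s[1L], length(th))  # k = 0: uniform shift
    for (k in 1:kmax) {
      f <- f + s[k + 1L] * (a[i, k + 1L] * cos(k * th) + b[i, k + 1L] * sin(k * th))
    }
    f
  })
}

#' Perturb a reference delineation
#'
#' Applies a [perturb_model()] to every boundary vertex of `reference`,
#' displacing it radially about its slice centroid. With zero bias, zero
#' sigma and no truncation/bump the output is identical to the input.
#'
#' @param reference a `structure_delineation`.
#' @param model a [perturb_model()].
#' @param seed integer seed.
#' @param patient_id identifier for the perturbed delineation (defaults to
#'   the reference's).
#' @param min_radius_mm slices whose perturbed boundary would collapse below
#'   this radius raise an error.
#' @return a `structure_delineation`.
#' @export
perturb <- function(reference, model, seed, patient_id = reference$patient_id,
                    min_radius_mm = 0.5) {
  with_seed(seed, {
    contours <- reference$contours
    ns <- length(contours)
    geo <- lapply(contours, function(ct) {
      v <- ct$vertices
      c0 <- colMeans(v)
      d <- sweep(v, 2L, c0)
      r <- sqrt(rowSums(d^2))
      list(centre = c0, r = r, theta = atan2(d[, 2L], d[, 1L]), v = v)
    })
    noise <- radial_noise_field(lapply(geo, `[[`, "theta"),
                                model$radial_sigma_mm,
                                model$angular_corr, model$axial_corr)
    # outlier bump: seeded angular position, central axial window
    bump <- vector("list", ns)
    if (!is.null(model$outlier) && model$outlier$amplitude_mm > 0) {
      th0 <- stats::runif(1L, 0, 2 * pi)
      span <- min(max(1L, round(model$outlier$span_mm /
                                  reference$slice_thickness_mm)), ns)
      first <- max(1L, floor((ns - span) / 2) + 1L)
      idx <- first:(first + span - 1L)
      for (j in seq_along(idx)) {
        axw <- sin(pi * (j - 0.5) / span)^2
        i <- idx[j]
        dth <- (geo[[i]]$theta - th0 + pi) %% (2 * pi) - pi
        bump[[i]] <- model$outlier$amplitude_mm * axw *
          exp(-0.5 * (dth / model$outlier$angular_width)^2)
      }
    }
    # cranio-caudal truncation of caudal slices
    drop_n <- 0L
    if (model$extent_shift$prob > 0 && model$extent_shift$max_slices > 0) {
      if (stats::runif(1L) < model$extent_shift$prob) {
        drop_n <- sample.int(model$extent_shift$max_slices, 1L)
      }
    }
    keep <- if (drop_n > 0L) (drop_n + 1L):ns else seq_len(ns)
    out <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      g <- geo[[i]]
      disp <- model$radial_bias_mm + noise[[i]]
      if (!is.null(bump[[i]])) disp <- disp + bump[[i]]
      newr <- g$r + disp
      if (any(newr < min_radius_mm)) {
        stop(sprintf("perturbation collapses slice %d below the minimum radius", i))
      }
      unit <- cbind(cos(g$theta), sin(g$theta))
      v <- g$v + disp * unit
      out[[j]] <- new_planar_contour(v, contours[[i]]$z_mm)
    }
    structure_delineation(patient_id, reference$label,
                          reference$slice_thickness_mm, out)
  })
}

#' Delineation-time model (lognormal, moment matched)
#'
#' Each workflow group and time column gets a lognormal whose parameters are
#' solved analytically from a target mean and SD (minutes), so the implied
#' moments reproduce the targets exactly. Times are positive and
#' right-skewed, which matches the large SD-to-mean ratios of observed
#' independent-check times. T2 for thin-slice (2.5 mm) patients is shifted
#' additively by `ic_thickness_effect_min` before matching: reviewing twice
#' as many slices lengthens the independent check.
#'
#' @param manual_t1,manual_t2 target `c(mean, sd)` for the manual workflow
#'   (group A) first-delineation and independent-check times.
#' @param auto_t1,auto_t2 same for the automatic workflow (group B; T1 is
#'   atlas choice + propagation).
#' @param ic_thickness_effect_min additive T2 mean shift for thin-slice
#'   patients, minutes.
#' @param thin_thickness_mm slice thickness at or below which the shift
#'   applies, mm.
#' @return a `time_model` list.
#' @export
time_model <- function(manual_t1 = c(13.12, 4.84), manual_t2 = c(10.20, 5.15),
                       auto_t1 = c(1.12, 0.44), auto_t2 = c(9.72, 8.67),
                       ic_thickness_effect_min = 2, thin_thickness_mm = 2.5) {
  tgt <- list(A = list(t1 = manual_t1, t2 = manual_t2),
              B = list(t1 = auto_t1, t2 = auto_t2))
  for (g in tgt) for (cc in g) {
    if (length(cc) != 2L || any(!is.finite(cc)) || cc[1L] <= 0 || cc[2L] <= 0) {
      stop("each timing target must be c(mean, sd) with positive values")
    }
  }
  structure(c(tgt, list(ic_thickness_effect_min = ic_thickness_effect_min,
                        thin_thickness_mm = thin_thickness_mm)),
            class = "time_model")
}

lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate per-patient timing records
#'
#' Lognormal draws with analytic moment matching to the model's target
#' mean/SD per column; thin-slice patients get the additive T2 shift.
#'
#' @param model a [time_model()].
#' @param patient_id patient identifiers (length n).
#' @param group `"A"` or `"B"` for all records.
#' @param slice_thickness_mm per-patient thickness (scalar or length n).
#' @param seed integer seed.
#' @return [timing_records()] of length n.
#' @export
simulate_times <- function(model, patient_id, group, slice_thickness_mm, seed) {
  n <- length(patient_id)
  stopifnot(n >= 1L, group %in% c("A", "B"))
  thick <- rep_len(slice_thickness_mm, n)
  with_seed(seed, {
    tg <- model[[group]]
    p1 <- lnorm_params(tg$t1[1L], tg$t1[2L])
    t1 <- stats::rlnorm(n, p1$meanlog, p1$sdlog)
    thin <- thick <= model$thin_thickness_mm
    t2 <- numeric(n)
    p2 <- lnorm_params(tg$t2[1L], tg$t2[2L])
    t2[!thin] <- stats::rlnorm(sum(!thin), p2$meanlog, p2$sdlog)
    if (any(thin)) {
      p2s <- lnorm_params(tg$t2[1L] + model$ic_thickness_effect_min, tg$t2[2L])
      t2[thin] <- stats::rlnorm(sum(thin), p2s$meanlog, p2s$sdlog)
    }
    timing_records(patient_id, rep(group, n), t1, t2)
  })
}

#' Full synthetic-study configuration
#'
#' Defaults lay out the validation study: 44 patients, the first 14 as atlas
#' library and the remaining 30 as test patients, the first 29 scanned at
#' 5 mm slice thickness and the last 15 at 2.5 mm; each test patient gets a
#' reference ("master contour"), one expert-manual perturbation (group A)
#' and one auto-segmentation perturbation (group B, larger bias and variance)
#' of it, with a configurable number of group-B outlier anatomies; timing
#' logs follow the time model.
#'
#' @param n_patients,n_atlas cohort layout; patients beyond `n_atlas` are
#'   test patients.
#' @param thickness_pattern per-patient slice thickness, mm (length
#'   `n_patients`).
#' @param axial_extent_mm cranio-caudal CTV extent; slices per patient =
#'   `round(extent / thickness) + 1`.
#' @param shape base [shape_params()] (its `n_slices`/`slice_thickness_mm`
#'   are overridden per patient).
#' @param perturb_manual,perturb_auto [perturb_model()]s for groups A and B.
#' @param outlier_count how many test patients carry the outlier bump in
#'   their group-B delineation.
#' @param outlier_bump bump geometry passed into the auto model for those
#'   patients.
#' @param times a [time_model()].
#' @param seed master seed; every sub-stream seed derives from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 44L, n_atlas = 14L,
                             thickness_pattern = c(rep(5, 29), rep(2.5, 15)),
                             axial_extent_mm = 100,
                             shape = shape_params(),
                             perturb_manual = perturb_model(
                               radial_bias_mm = 0.5, radial_sigma_mm = 1.0),
                             perturb_auto = perturb_model(
                               radial_bias_mm = 1.0, radial_sigma_mm = 2.0,
                               extent_shift = list(prob = 0.2, max_slices = 2)),
                             outlier_count = 2L,
                             outlier_bump = list(amplitude_mm = 25,
                                                 angular_width = 0.9,
                                                 span_mm = 45),
                             times = time_model(),
                             seed = 1L) {
  if (length(thickness_pattern) != n_patients) {
    stop("thickness_pattern must have one entry per patient")
  }
  if (n_atlas >= n_patients) stop("need at least one test patient")
  if (outlier_count > n_patients - n_atlas) {
    stop("more outliers requested than test patients")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_atlas = as.integer(n_atlas),
                 thickness_pattern = thickness_pattern,
                 axial_extent_mm = axial_extent_mm,
                 shape = shape, perturb_manual = perturb_manual,
                 perturb_auto = perturb_auto,
                 outlier_count = as.integer(outlier_count),
                 outlier_bump = outlier_bump,
                 times = times, seed = as.integer(seed)),
            class = "synthetic_config")
}

# plausible adult anthropometric profiles; these feed atlas ranking only
simulate_profiles <- function(config, seed) {
  n <- config$n_patients
  with_seed(seed, {
    sex <- c(sample(c(rep("F", 8L), rep("M", 6L)))[seq_len(min(14L, n))],
             sample(c("F", "M"), max(0L, n - 14L), replace = TRUE))
    age <- round(stats::runif(n, 45, 82))
    height <- round(stats::rnorm(n, ifelse(sex == "M", 175, 163), 7))
    bmi <- round(stats::runif(n, 20, 34), 1)
    weight <- round(bmi * (height / 100)^2, 1)
    fertility <- ifelse(sex == "M", "na",
                        ifelse(age >= 52, "post-menopausal", "fertile"))
    df <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      role = c(rep("atlas", config$n_atlas),
               rep("test", n - config$n_atlas)),
      stage = sample(c("II", "III"), n, replace = TRUE, prob = c(0.4, 0.6)),
      tumor_localization = sample(c("low", "mid"), n, replace = TRUE),
      sex = sex, age = age, weight = weight, height = height,
      bmi = round(weight / (height / 100)^2, 1),
      fertility_state = fertility,
      sacro_coccygeal_mm = round(stats::runif(n, 95, 140), 1),
      inter_iliac_mm = round(stats::runif(n, 230, 300), 1),
      slice_thickness_mm = config$thickness_pattern,
      stringsAsFactors = FALSE)
    patient_profiles(df)
  })
}

#' Generate the full synthetic study
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort`: list with `profiles`, `delineations` (per
#'   test patient: `reference`, `manual`, `auto`), `timings`
#'   ([timing_records()] for groups A and B), and `provenance` (master seed,
#'   config hash, outlier patient ids).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  test_idx <- (config$n_atlas + 1L):n
  seeds <- derive_seeds(config$seed, 4L + 3L * length(test_idx))
  profiles <- simulate_profiles(config, seeds[1L])
  outlier_ids <- with_seed(seeds[2L], {
    sample(profiles$patient_id[test_idx], config$outlier_count)
  })
  delineations <- vector("list", length(test_idx))
  names(delineations) <- profiles$patient_id[test_idx]
  for (j in seq_along(test_idx)) {
    i <- test_idx[j]
    pid <- profiles$patient_id[i]
    thick <- config$thickness_pattern[i]
    shp <- config$shape
    shp$slice_thickness_mm <- thick
    shp$n_slices <- as.integer(round(config$axial_extent_mm / thick) + 1L)
    s0 <- seeds[4L + 3L * (j - 1L) + 1L]
    s1 <- seeds[4L + 3L * (j - 1L) + 2L]
    s2 <- seeds[4L + 3L * (j - 1L) + 3L]
    ref <- generate_reference(shp, s0, patient_id = pid)
    auto_model <- config$perturb_auto
    if (pid %in% outlier_ids) auto_model$outlier <- config$outlier_bump
    delineations[[pid]] <- list(
      reference = ref,
      manual = perturb(ref, config$perturb_manual, s1),
      auto = perturb(ref, auto_model, s2))
  }
  test_ids <- profiles$patient_id[test_idx]
  test_thick <- config$thickness_pattern[test_idx]
  timings <- rbind(
    simulate_times(config$times, test_ids, "A", test_thick, seeds[3L]),
    simulate_times(config$times, test_ids, "B", test_thick, seeds[4L]))
  class(timings) <- c("timing_records", "data.frame")
  structure(list(profiles = profiles, delineations = delineations,
                 timings = timings,
                 provenance = list(seed = config$seed,
                                   config_hash = config_hash(config),
                                   outlier_ids = sort(outlier_ids))),
            class = "synthetic_cohort")
}

# md5 of the serialised configuration (text form, so it is stable across
# sessions)
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(config, digits = 15L), f)
  unname(tools::md5sum(f))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d profiles (%d atlas / %d test), %d delineation triplets, %d timing records\n",
    nrow(x$profiles), sum(x$profiles$role == "atlas"),
    sum(x$profiles$role == "test"), length(x$delineations), nrow(x$timings)))
  if (length(x$provenance$outlier_ids)) {
    cat("  outliers:", paste(x$provenance$outlier_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
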
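#' Canonical contour JSON exchange format
#'
#' One delineation per file:
#' `{"patient_id", "label", "slice_thickness_mm",
#'   "slices": [{"z_mm", "polygons": [[[x,y], ...], ...]}]}`.
#' All numbers are patient-space millimetres. Polygons are cleaned on ingest
#' (duplicate removal, orientation normalisation, simplicity check).
#'
#' @name contour-json
NULL

#' @rdname contour-json
#' @param sd a `structure_delineation`.
#' @param path output file.
#' @export
write_delineation_json <- function(sd, path) {
  z <- delineation_z(sd)
  zu <- sort(unique(z))
  slices <- lapply(zu, function(zz) {
    polys <- lapply(contours_at(sd, zz), function(ct) ct$vertices)
    list(z_mm = zz, polygons = polys)
  })
  obj <- list(patient_id = sd$patient_id, label = sd$label,
              slice_thickness_mm = sd$slice_thickness_mm, slices = slices)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname contour-json
#' @param clean run [clean_contour()] validation on every polygon (recommended
#'   for third-party files).
#' @export
read_delineation_json <- function(path, clean = TRUE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("patient_id", "label", "slice_thickness_mm", "slices")
  if (!all(need %in% names(obj))) {
    stop("contour JSON lacks fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  }
  contours <- list()
  for (sl in obj$slices) {
    z <- as.numeric(sl$z_mm)
    for (poly in sl$polygons) {
      v <- do.call(rbind, lapply(poly, function(p) as.numeric(unlist(p))))
      ct <- if (clean) clean_contour(v, z) else new_planar_contour(v, z)
      contours[[length(contours) + 1L]] <- ct
    }
  }
  structure_delineation(obj$patient_id, obj$label,
                        as.numeric(obj$slice_thickness_mm), contours)
}

#' Write a synthetic cohort to a dataset directory
#'
#' Layout: `contours/<id>_<role>.json` (canonical contour JSON),
#' `profiles.csv`, `timings.csv`, `provenance.json`. Runs with the same
#' cohort object produce byte-identical files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  cdir <- file.path(dir, "contours")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$delineations)) {
    trip <- cohort$delineations[[pid]]
    for (role in names(trip)) {
      write_delineation_json(trip[[role]],
                             file.path(cdir, sprintf("%s_%s.json", pid, role)))
    }
  }
  utils::write.csv(as.data.frame(cohort$profiles),
                   file.path(dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$timings)[
    c("patient_id", "group", "t1_min", "t2_min")],
    file.path(dir, "timings.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(cohort$provenance, auto_unbox = TRUE, digits = NA),
             file.path(dir, "provenance.json"))
  invisible(dir)
}

#' Read a cohort dataset directory
#'
#' Accepts directories written by [write_cohort()] or user-assembled ones
#' with the same layout; `provenance.json` is optional.
#'
#' @param dir dataset directory.
#' @param clean validate polygons on ingest.
#' @return a `synthetic_cohort`-shaped list.
#' @export
read_cohort <- function(dir, clean = TRUE) {
  prof <- utils::read.csv(file.path(dir, "profiles.csv"),
                          stringsAsFactors = FALSE)
  prof <- patient_profiles(prof)
  tim <- utils::read.csv(file.path(dir, "timings.csv"), stringsAsFactors = FALSE)
  tim <- timing_records(tim$patient_id, tim$group, tim$t1_min, tim$t2_min)
  files <- list.files(file.path(dir, "contours"), pattern = "\\.json$",
                      full.names = TRUE)
  parts <- regmatches(basename(files),
                      regexec("^(.*)_(reference|manual|auto)\\.json$",
                              basename(files)))
  delineations <- list()
  for (k in seq_along(files)) {
    if (length(parts[[k]]) != 3L) next
    pid <- parts[[k]][2L]; role <- parts[[k]][3L]
    if (is.null(delineations[[pid]])) delineations[[pid]] <- list()
    delineations[[pid]][[role]] <- read_delineation_json(files[k], clean = clean)
  }
  canonical <- c("reference", "manual", "auto")
  delineations <- lapply(delineations, function(trip) {
    trip[c(intersect(canonical, names(trip)),
           setdiff(names(trip), canonical))]
  })
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path)) {
    jsonlite::fromJSON(prov_path, simplifyVector = TRUE)
  } else NULL
  structure(list(profiles = prof, delineations = delineations,
                 timings = tim, provenance = prov),
            class = "synthetic_cohort")
}
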
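#' Atlas-patient matching by clinical and anthropometric profile
#'
#' Ranks atlas-library patients as candidate best-fitting matches for a test
#' patient using the selection parameters of the delineation workflow: stage,
#' tumor localization, sex, age, weight, height, BMI, fertility state, plus
#' the sacro-coccygeal and inter-iliac distances. Only the selection step is
#' modelled; contour propagation is out of scope.
#'
#' @name atlas-select
NULL

.profile_numeric <- c("age", "weight", "height", "bmi",
                      "sacro_coccygeal_mm", "inter_iliac_mm")
.profile_categorical <- c("tumor_localization", "sex", "fertility_state")
.profile_ordinal <- "stage"
.profile_fields <- c(.profile_ordinal, .profile_numeric, .profile_categorical)
.stage_levels <- c("I", "II", "III", "IV")

#' Build a table of patient profiles
#'
#' @param df data.frame with columns `patient_id`, `role` ("atlas" or
#'   "test"), `stage` (ordinal, levels I < II < III < IV), `tumor_localization`
#'   ("low"/"mid"), `sex`, `age` (years), `weight` (kg), `height` (cm), `bmi`
#'   (kg/m^2, checked against weight/height within 2% when all three are
#'   present), `fertility_state`, `sacro_coccygeal_mm`, `inter_iliac_mm`,
#'   `slice_thickness_mm`. Missing values are allowed and skipped in
#'   distances.
#' @return the validated data.frame with class `patient_profiles`.
#' @export
patient_profiles <- function(df) {
  need <- c("patient_id", "role", .profile_fields, "slice_thickness_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("profile table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(df$role %in% c("atlas", "test"))) stop("role must be 'atlas' or 'test'")
  for (f in .profile_numeric) {
    bad <- !is.na(df[[f]]) & df[[f]] <= 0
    if (any(bad)) stop("non-positive values in numeric profile field ", f)
  }
  full <- !is.na(df$bmi) & !is.na(df$weight) & !is.na(df$height)
  if (any(full)) {
    implied <- df$weight[full] / (df$height[full] / 100)^2
    if (any(abs(df$bmi[full] - implied) / implied > 0.02)) {
      stop("bmi inconsistent with weight/height (tolerance 2%)")
    }
  }
  df$patient_id <- as.character(df$patient_id)
  class(df) <- c("patient_profiles", "data.frame")
  df
}

#' Field ranges of a profile cohort (for range-normalised distances)
#'
#' @param profiles a [patient_profiles()] table.
#' @return named list of `c(min, max)` per numeric field, computed over
#'   non-missing values.
#' @export
profile_ranges <- function(profiles) {
  out <- lapply(.profile_numeric, function(f) {
    v <- profiles[[f]]
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_) else range(v)
  })
  names(out) <- .profile_numeric
  out
}

#' Gower-style mixed distance between two patient profiles
#'
#' Numeric fields contribute absolute difference divided by the cohort range;
#' categorical fields contribute 0/1 mismatch; stage is ordinal (scaled rank
#' difference over levels I-IV). The result is the weighted mean over fields
#' non-missing in both profiles (weights renormalised), so it lies in
#' `[0, 1]`, is symmetric, and is 0 iff all compared fields agree.
#'
#' @param a,b one-row `patient_profiles` entries (or lists with the profile
#'   fields).
#' @param ranges cohort numeric ranges from [profile_ranges()].
#' @param weights named per-field weights; default uniform over all fields.
#' @return distance in `[0, 1]`.
#' @export
profile_distance <- function(a, b, ranges, weights = NULL) {
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(.profile_fields)), .profile_fields)
  }
  get1 <- function(p, f) {
    v <- if (is.data.frame(p)) p[[f]][1L] else p[[f]]
    if (is.null(v)) NA else v
  }
  num <- 0; den <- 0
  for (f in .profile_fields) {
    va <- get1(a, f); vb <- get1(b, f)
    if (is.na(va) || is.na(vb)) next
    w <- if (f %in% names(weights)) weights[[f]] else 0
    if (is.na(w)) w <- 0
    d <- if (f %in% .profile_categorical) {
      as.numeric(as.character(va) != as.character(vb))
    } else if (f == .profile_ordinal) {
      ra <- match(as.character(va), .stage_levels)
      rb <- match(as.character(vb), .stage_levels)
      if (is.na(ra) || is.na(rb)) next
      abs(ra - rb) / (length(.stage_levels) - 1L)
    } else {
      rg <- ranges[[f]]
      if (anyNA(rg)) next
      span <- rg[2L] - rg[1L]
      if (span <= 0) 0 else min(abs(va - vb) / span, 1)
    }
    num <- num + w * d
    den <- den + w
  }
  if (den <= 0) stop("profiles share no comparable fields with positive weight")
  num / den
}

#' Rank an atlas library against a test patient
#'
#' Candidates are ordered by ascending [profile_distance()]; ties are broken
#' deterministically by patient id.
#'
#' @param test one-row profile of the test patient.
#' @param library `patient_profiles` rows with role `"atlas"`.
#' @param ranges cohort ranges; default computed from test + library so the
#'   normalisation reflects the cohort at hand.
#' @param weights per-field weights (see [profile_distance()]).
#' @return data.frame: test_id, atlas_id, distance, rank.
#' @export
rank_atlas <- function(test, library, ranges = NULL, weights = NULL) {
  if (!nrow(library)) stop("atlas library is empty")
  if (!all(library$role == "atlas")) stop("library rows must have role 'atlas'")
  if (is.null(ranges)) {
    pool <- rbind(as.data.frame(test)[names(as.data.frame(library))],
                  as.data.frame(library))
    ranges <- profile_ranges(pool)
  }
  d <- vapply(seq_len(nrow(library)), function(i) {
    profile_distance(test, library[i, , drop = FALSE], ranges, weights)
  }, numeric(1))
  ord <- order(d, library$patient_id)
  data.frame(test_id = if (is.data.frame(test)) test$patient_id[1L] else test$patient_id,
             atlas_id = library$patient_id[ord],
             distance = d[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
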
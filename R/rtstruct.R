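#' Minimal DICOM RT-STRUCT reader
#'
#' Reads planar contours of one ROI from a DICOM structure-set file into a
#' `structure_delineation`. Only what structure-set geometry needs is
#' implemented: explicit-VR little-endian datasets, sequence (SQ) recursion
#' with defined or undefined lengths, and the StructureSetROISequence /
#' ROIContourSequence / ContourSequence elements. Pixel data, other transfer
#' syntaxes and DICOM writing are out of scope.
#'
#' @name rtstruct
NULL

.u16 <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L,
          endian = "little", signed = FALSE)
}
.u32 <- function(raw, off) {
  v <- readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L,
               endian = "little")
  if (v < 0) v + 4294967296 else v
}

# parse one explicit-VR little-endian dataset spanning raw[(start+1):end];
# returns list(elements = named list keyed "gggg,eeee", next_off)
parse_dicom_dataset <- function(raw, start, end) {
  elements <- list()
  off <- start
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8L <= end) {
    group <- .u16(raw, off)
    elem <- .u16(raw, off + 2L)
    tag <- sprintf("%04x,%04x", group, elem)
    if (group == 0xFFFE) {
      # item / delimiter tags carry no VR
      len <- .u32(raw, off + 4L)
      if (elem == 0xE00D || elem == 0xE0DD) {  # item / sequence delimiter
        return(list(elements = elements, next_off = off + 8L))
      }
      stop("unexpected item tag outside a sequence at offset ", off)
    }
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (vr %in% long_vrs) {
      len <- .u32(raw, off + 8L)
      body <- off + 12L
    } else {
      len <- .u16(raw, off + 6L)
      body <- off + 8L
    }
    if (vr == "SQ") {
      items <- list()
      ioff <- body
      iend <- if (len == 4294967295) end else body + len
      while (ioff + 8L <= iend) {
        ig <- .u16(raw, ioff); ie <- .u16(raw, ioff + 2L)
        ilen <- .u32(raw, ioff + 4L)
        if (ig == 0xFFFE && ie == 0xE0DD) { ioff <- ioff + 8L; break }
        if (!(ig == 0xFFFE && ie == 0xE000)) {
          stop("malformed sequence: expected an item tag at offset ", ioff)
        }
        if (ilen == 4294967295) {
          sub <- parse_dicom_dataset(raw, ioff + 8L, iend)
          items[[length(items) + 1L]] <- sub$elements
          ioff <- sub$next_off
        } else {
          sub <- parse_dicom_dataset(raw, ioff + 8L, ioff + 8L + ilen)
          items[[length(items) + 1L]] <- sub$elements
          ioff <- ioff + 8L + ilen
        }
      }
      elements[[tag]] <- items
      off <- if (len == 4294967295) ioff else body + len
    } else {
      elements[[tag]] <- raw[seq_len(len) + body]
      off <- body + len
    }
  }
  list(elements = elements, next_off = off)
}

.dicom_string <- function(x) {
  if (is.null(x)) return(NA_character_)
  trimws(rawToChar(x))
}
.dicom_numbers <- function(x) {
  as.numeric(strsplit(.dicom_string(x), "\\\\")[[1L]])
}

#' Read one ROI from a DICOM RT-STRUCT file
#'
#' @param path RT-STRUCT file (explicit VR little endian; the 128-byte
#'   preamble and DICM magic are optional).
#' @param roi_label ROI name to extract (matched against ROIName).
#' @param patient_id identifier for the resulting delineation; defaults to
#'   PatientID from the file when present.
#' @param coplanar_tol maximum allowed z spread within one planar contour, mm.
#' @return a `structure_delineation`; z is taken from the contour data's
#'   third coordinate, and slice thickness is inferred from the z spacing
#'   (1 mm fallback for a single slice).
#' @export
read_rtstruct <- function(path, roi_label, patient_id = NULL,
                          coplanar_tol = 0.01) {
  raw <- readBin(path, "raw", file.size(path))
  off <- 0L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  ds <- parse_dicom_dataset(raw, off, length(raw))$elements
  roi_seq <- ds[["3006,0020"]]
  cont_seq <- ds[["3006,0039"]]
  if (is.null(roi_seq) || is.null(cont_seq)) {
    stop("file lacks StructureSetROISequence / ROIContourSequence; not an RT-STRUCT?")
  }
  roi_names <- vapply(roi_seq, function(it) .dicom_string(it[["3006,0026"]]),
                      character(1))
  roi_numbers <- vapply(roi_seq, function(it) {
    as.integer(.dicom_string(it[["3006,0022"]]))
  }, integer(1))
  hit <- which(roi_names == roi_label)
  if (!length(hit)) {
    stop(sprintf("ROI '%s' not found; available: %s", roi_label,
                 paste(roi_names, collapse = ", ")))
  }
  want <- roi_numbers[hit[1L]]
  contours <- list()
  for (it in cont_seq) {
    refnum <- as.integer(.dicom_string(it[["3006,0084"]]))
    if (is.na(refnum) || refnum != want) next
    for (ct in it[["3006,0040"]]) {
      xyz <- .dicom_numbers(ct[["3006,0050"]])
      m <- matrix(xyz, ncol = 3L, byrow = TRUE)
      if (diff(range(m[, 3L])) > coplanar_tol) {
        stop("non-coplanar contour points (z spread exceeds 0.01 mm)")
      }
      contours[[length(contours) + 1L]] <- clean_contour(m[, 1:2], mean(m[, 3L]))
    }
  }
  if (!length(contours)) stop(sprintf("ROI '%s' carries no contour data", roi_label))
  z <- sort(unique(vapply(contours, function(ct) ct$z_mm, numeric(1))))
  thickness <- if (length(z) > 1L) min(diff(z)) else 1
  if (is.null(patient_id)) {
    patient_id <- .dicom_string(ds[["0010,0020"]])
    if (is.na(patient_id)) patient_id <- "RTSTRUCT"
  }
  structure_delineation(patient_id, roi_label, thickness, contours)
}
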
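# Synthetic RT-STRUCT fixture writer (explicit VR little endian, defined
# lengths). Only used to build test inputs for the reader; kept in the test
# helpers because DICOM writing is outside the package's scope.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_elem <- function(group, elem, vr, value) {
  v <- if (is.character(value)) charToRaw(value) else value
  if (length(v) %% 2L) v <- c(v, charToRaw(" "))
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
    if (long) c(as.raw(c(0L, 0L)), dcm_u32(length(v))) else dcm_u16(length(v)),
    v)
}

dcm_item <- function(content) {
  c(dcm_u16(0xFFFE), dcm_u16(0xE000), dcm_u32(length(content)), content)
}

dcm_sq <- function(group, elem, items) {
  body <- do.call(c, lapply(items, dcm_item))
  c(dcm_u16(group), dcm_u16(elem), charToRaw("SQ"), as.raw(c(0L, 0L)),
    dcm_u32(length(body)), body)
}

# rois: named list; each element a list of n x 3 matrices (x, y, z in mm)
write_synthetic_rtstruct <- function(path, rois, patient_id = "FIX") {
  roi_items <- lapply(seq_along(rois), function(k) {
    c(dcm_elem(0x3006, 0x0022, "IS", as.character(k)),
      dcm_elem(0x3006, 0x0026, "LO", names(rois)[k]))
  })
  contour_items <- lapply(seq_along(rois), function(k) {
    cseq <- dcm_sq(0x3006, 0x0040, lapply(rois[[k]], function(m) {
      data <- paste(sprintf("%.4f", t(m)), collapse = "\\")
      c(dcm_elem(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_elem(0x3006, 0x0046, "IS", as.character(nrow(m))),
        dcm_elem(0x3006, 0x0050, "DS", data))
    }))
    c(cseq, dcm_elem(0x3006, 0x0084, "IS", as.character(k)))
  })
  body <- c(dcm_elem(0x0008, 0x0060, "CS", "RTSTRUCT"),
            dcm_elem(0x0010, 0x0020, "LO", patient_id),
            dcm_sq(0x3006, 0x0020, roi_items),
            dcm_sq(0x3006, 0x0039, contour_items))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), body), con)
  invisible(path)
}
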
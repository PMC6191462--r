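# Minimal synthetic DICOM slice writer (explicit VR little endian) used to
# exercise the series reader. Slices are generated at test time; nothing is
# stored on disk in the repository.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_str <- function(s, pad = " ") {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(pad))
  r
}

dcm_elem <- function(group, elem, vr, value_raw) {
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(dcm_u16(group), dcm_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      dcm_u32(length(value_raw)), value_raw)
  } else {
    c(dcm_u16(group), dcm_u16(elem), charToRaw(vr), dcm_u16(length(value_raw)),
      value_raw)
  }
}

# pixels: integer matrix indexed [x, y] (stored values, not HU)
write_dicom_slice <- function(path, pixels, position, pixel_spacing = c(1, 1),
                              slope = 1, intercept = -1024,
                              transfer_syntax = "1.2.840.10008.1.2.1") {
  nx <- nrow(pixels); ny <- ncol(pixels)
  px_raw <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  body <- c(
    dcm_elem(0x0002, 0x0010, "UI", dcm_str(transfer_syntax, pad = " ")),
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_elem(0x0020, 0x0032, "DS",
             dcm_str(paste(format(position, trim = TRUE), collapse = "\\"))),
    dcm_elem(0x0020, 0x0037, "DS", dcm_str("1\\0\\0\\0\\1\\0")),
    dcm_elem(0x0028, 0x0010, "US", dcm_u16(ny)),   # Rows
    dcm_elem(0x0028, 0x0011, "US", dcm_u16(nx)),   # Columns
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(paste(format(c(pixel_spacing[2], pixel_spacing[1]),
                                  trim = TRUE), collapse = "\\"))),
    dcm_elem(0x0028, 0x0100, "US", dcm_u16(16)),   # BitsAllocated
    dcm_elem(0x0028, 0x0103, "US", dcm_u16(1)),    # PixelRepresentation: signed
    dcm_elem(0x0028, 0x1052, "DS", dcm_str(format(intercept, trim = TRUE))),
    dcm_elem(0x0028, 0x1053, "DS", dcm_str(format(slope, trim = TRUE))),
    dcm_elem(0x7FE0, 0x0010, "OW", px_raw)
  )
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}

# write a whole series into a directory; values[, , k] are stored values
write_dicom_series <- function(dir, values, pixel_spacing = c(1, 1), dz = 1,
                               slope = 1, intercept = -1024, origin = c(0, 0, 0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(dim(values)[3])) {
    write_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                      values[, , k],
                      position = c(origin[1], origin[2], origin[3] + (k - 1) * dz),
                      pixel_spacing = pixel_spacing, slope = slope,
                      intercept = intercept)
  }
  invisible(dir)
}
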
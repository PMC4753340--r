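# Minimal DICOM writer for test fixtures: single-frame grayscale,
# little-endian, explicit or implicit VR data set (the file meta group
# is always explicit, as the standard requires).

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                    endian = "little")

dcm_pad <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  tag <- c(dcm_raw_u16(group), dcm_raw_u16(elem))
  if (!explicit)
    return(c(tag, dcm_raw_u32(length(value)), value))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_raw_u32(length(value)), value)
  else
    c(tag, charToRaw(vr), dcm_raw_u16(length(value)), value)
}

# pixels: integer matrix in the package's row/column layout
write_test_dicom <- function(path, pixels, bits = 8L, spacing_mm = NULL,
                             explicit = TRUE, n_frames = NULL,
                             samples = 1L) {
  uid <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  uid_raw <- dcm_pad(charToRaw(uid), as.raw(0))
  meta_body <- dcm_element(0x0002, 0x0010, "UI", uid_raw, explicit = TRUE)
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_raw_u32(length(meta_body)),
                        explicit = TRUE),
            meta_body)

  v <- as.integer(t(pixels))  # row-major pixel order
  pixel_raw <- if (bits == 8L) as.raw(v)
               else writeBin(v, raw(), size = 2L, endian = "little")
  body <- c(
    dcm_element(0x0028, 0x0002, "US", dcm_raw_u16(samples), explicit),
    if (!is.null(n_frames))
      dcm_element(0x0028, 0x0008, "IS",
                  dcm_pad(charToRaw(as.character(n_frames))), explicit),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(nrow(pixels)), explicit),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(ncol(pixels)), explicit),
    if (!is.null(spacing_mm))
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_pad(charToRaw(paste(spacing_mm, collapse = "\\"))),
                  explicit),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(bits), explicit),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(0L), explicit),
    dcm_element(0x7FE0, 0x0010, if (bits == 8L) "OB" else "OW",
                dcm_pad(pixel_raw, as.raw(0)), explicit))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
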
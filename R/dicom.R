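# Minimal DICOM reader for single-frame grayscale images.
#
# Supports the two uncompressed little-endian transfer syntaxes
# (Explicit VR 1.2.840.10008.1.2.1 and Implicit VR 1.2.840.10008.1.2)
# which cover stored B-mode ultrasound stills.  Encapsulated/compressed
# pixel data, sequences with undefined length, multi-frame and color
# images are rejected with a format error naming the unsupported feature.

DICOM_EXPLICIT <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT <- "1.2.840.10008.1.2"

dcm_u16 <- function(raw2) readBin(raw2, "integer", size = 2L, endian = "little",
                                  signed = FALSE)
# string value with DICOM NUL/space padding stripped (at the raw level:
# R character strings cannot hold embedded NUL bytes)
dcm_string <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))
dcm_u32 <- function(raw4) {
  lo <- dcm_u16(raw4[1:2]); hi <- dcm_u16(raw4[3:4])
  hi * 65536 + lo
}

#' Read a single-frame grayscale DICOM image
#'
#' Reads uncompressed little-endian DICOM (explicit or implicit VR).
#' 8-bit pixel data are taken as stored; deeper data (e.g. 16-bit) are
#' mapped to `[0, 255]` by a min-max affine rescale with half-up
#' rounding.  When the `PixelSpacing` tag (0028,0030) is present its
#' mm values are converted to cm and attached as `spacing_cm`
#' (DICOM orders spacing row first, i.e. y then x).
#'
#' @param path path to a DICOM file.
#' @return A [gray_image()].
#' @export
read_dicom <- function(path) {
  if (!nzchar(path) || !file.exists(path))
    stop("cannot read DICOM: file not found: '", path, "'", call. = FALSE)
  n <- file.size(path)
  bytes <- readBin(path, "raw", n)
  pos <- 1L
  if (n >= 132L && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  } else if (n < 8L) {
    stop("not a DICOM file: '", path, "'", call. = FALSE)
  }

  tags <- list()
  syntax <- DICOM_EXPLICIT  # file meta group is always explicit VR LE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n + 1L && pos <= n) {
    group <- dcm_u16(bytes[pos:(pos + 1L)])
    elem  <- dcm_u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    explicit <- (group == 0x0002L) || syntax == DICOM_EXPLICIT
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (!grepl("^[A-Z]{2}$", vr))
        stop("DICOM parse error: invalid value representation at tag (",
             sprintf("%04x,%04x", group, elem), ")", call. = FALSE)
      if (vr %in% long_vrs) {
        len <- dcm_u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- dcm_u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295)  # undefined length
      stop("unsupported DICOM feature: undefined-length value ",
           "(sequence or encapsulated pixel data)", call. = FALSE)
    if (pos + len - 1L > n)
      stop("DICOM parse error: element value runs past end of file",
           call. = FALSE)
    value <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- value
    if (key == "00020010")
      syntax <- dcm_string(value)
    if (key == "7fe00010") break  # pixel data is last in our scope
  }

  if (!(syntax %in% c(DICOM_EXPLICIT, DICOM_IMPLICIT)))
    stop("unsupported DICOM transfer syntax: ", syntax, call. = FALSE)
  if (is.null(tags[["7fe00010"]]))
    stop("not an image DICOM: no PixelData element (7FE0,0010)",
         call. = FALSE)

  get_us <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v) || length(v) < 2L) return(default)
    dcm_u16(v[1:2])
  }
  get_str <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    dcm_string(v)
  }

  samples <- get_us("00280002", 1L)
  if (samples != 1L)
    stop("unsupported DICOM feature: color image (SamplesPerPixel = ",
         samples, ")", call. = FALSE)
  frames <- get_str("00280008")
  if (!is.null(frames) && as.integer(frames) > 1L)
    stop("unsupported DICOM feature: multi-frame image (NumberOfFrames = ",
         frames, ")", call. = FALSE)
  rows <- get_us("00280010"); cols <- get_us("00280011")
  if (is.null(rows) || is.null(cols))
    stop("not an image DICOM: missing Rows/Columns", call. = FALSE)
  bits <- get_us("00280100", 8L)
  signed <- identical(get_us("00280103", 0L), 1L)

  pd <- tags[["7fe00010"]]
  npx <- rows * cols
  if (bits == 8L) {
    v <- as.integer(pd[seq_len(npx)])
  } else if (bits == 16L) {
    v <- readBin(pd, "integer", n = npx, size = 2L, endian = "little",
                 signed = signed)
    if (!signed) v <- ifelse(v < 0L, v + 65536L, v)
  } else {
    stop("unsupported DICOM feature: BitsAllocated = ", bits, call. = FALSE)
  }
  if (length(v) < npx)
    stop("DICOM parse error: pixel data shorter than Rows x Columns",
         call. = FALSE)
  # stored row by row, top to bottom
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  if (bits != 8L) {
    rng <- range(m)
    m <- if (rng[1L] == rng[2L]) matrix(0L, rows, cols)
         else round_half_up(255 * (m - rng[1L]) / (rng[2L] - rng[1L]))
  }

  spacing_cm <- NULL
  ps <- get_str("00280030")
  if (!is.null(ps) && nzchar(ps)) {
    mm <- as.numeric(strsplit(ps, "\\\\")[[1L]])
    if (length(mm) == 2L && !anyNA(mm))
      spacing_cm <- c(x = mm[2L] / 10, y = mm[1L] / 10)
  }
  gray_image(m, spacing_cm)
}
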
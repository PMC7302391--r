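# Minimal single-frame grayscale DICOM reader (little-endian, explicit or
# implicit VR, uncompressed pixel data). Written in-package because no DICOM
# reader is available among the package's dependencies; it covers the subset
# of the standard needed for single CT slices: Rows, Columns, BitsAllocated,
# PixelRepresentation, RescaleSlope/Intercept and PixelData.

uint16le <- function(raw2) as.integer(raw2[1L]) + 256L * as.integer(raw2[2L])
uint32le <- function(raw4) {
  as.numeric(raw4[1L]) + 256 * as.numeric(raw4[2L]) +
    65536 * as.numeric(raw4[3L]) + 16777216 * as.numeric(raw4[4L])
}

read_dicom_pixels <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM marker): ", path, call. = FALSE)
  }
  pos <- 133L  # first data element after the 128-byte preamble + "DICM"

  # detect explicit VR: bytes 5-6 of the first element are two ASCII letters
  vr_probe <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  explicit <- grepl("^[A-Z]{2}$", vr_probe)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  tags <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- uint16le(bytes[pos:(pos + 1L)])
    elem <- uint16le(bytes[(pos + 2L):(pos + 3L)])
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- uint32le(bytes[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- uint16le(bytes[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- uint32le(bytes[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295) {
      stop("DICOM elements of undefined length (sequences, encapsulated ",
           "pixel data) are unsupported", call. = FALSE)
    }
    key <- sprintf("%04x,%04x", group, elem)
    val_start <- pos + hdr
    if (val_start + len - 1L > n) {
      stop("truncated DICOM element ", key, call. = FALSE)
    }
    if (key %in% c("0028,0002", "0028,0008", "0028,0010", "0028,0011",
                   "0028,0100", "0028,0103", "0028,1052", "0028,1053",
                   "7fe0,0010")) {
      tags[[key]] <- bytes[val_start:(val_start + len - 1L)]
    }
    pos <- val_start + as.integer(len)
  }

  get_us <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    uint16le(tags[[key]][1:2])
  }
  get_str <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    trimws(rawToChar(tags[[key]]))
  }

  rows <- get_us("0028,0010")
  cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]])) {
    stop("DICOM file lacks Rows/Columns/PixelData", call. = FALSE)
  }
  samples <- get_us("0028,0002", 1L)
  frames <- suppressWarnings(as.integer(get_str("0028,0008", "1")))
  if (samples != 1L || (!is.na(frames) && frames != 1L)) {
    stop("multi-frame or colour DICOM input is unsupported", call. = FALSE)
  }
  bits <- get_us("0028,0100", 16L)
  signed <- identical(get_us("0028,0103", 0L), 1L)
  slope <- suppressWarnings(as.numeric(get_str("0028,1053", "1")))
  intercept <- suppressWarnings(as.numeric(get_str("0028,1052", "0")))
  if (is.na(slope)) slope <- 1
  if (is.na(intercept)) intercept <- 0

  pd <- tags[["7fe0,0010"]]
  if (bits == 8L) {
    stored <- as.integer(pd[seq_len(rows * cols)])
    if (signed) stored <- ifelse(stored > 127L, stored - 256L, stored)
  } else if (bits == 16L) {
    stored <- readBin(pd, "integer", n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
  } else {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  if (length(stored) < rows * cols) {
    stop("pixel data shorter than Rows x Columns", call. = FALSE)
  }
  # DICOM stores pixels row by row
  matrix(slope * stored + intercept, nrow = rows, ncol = cols, byrow = TRUE)
}
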
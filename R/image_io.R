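#' Intensity image
#'
#' Container for a 2-D grayscale image. `pixels` is a numeric matrix (rows =
#' image rows), `origin` records the (row, col) offset of a crop in 0-based
#' pixel units, and `scale` stores the `(raw_min, raw_max)` window used by
#' [normalize_image()] so results can be mapped back to raw units.
#'
#' @param pixels Numeric matrix of finite intensities, at least 3 x 3.
#' @param origin Integer length-2 vector, 0-based (row, col) offset.
#' @param scale Optional numeric length-2 vector `(raw_min, raw_max)`.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, origin = c(0L, 0L), scale = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("pixels must be finite", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  }
  structure(list(pixels = pixels, origin = as.integer(origin), scale = scale),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image %d x %d, range [%.4g, %.4g], origin (%d, %d)>\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' Rectangular region of interest
#'
#' 0-based, half-open pixel intervals on each axis: rows
#' `[row_start, row_stop)`, columns `[col_start, col_stop)`.
#'
#' @param row_start,row_stop,col_start,col_stop Integer pixel indices with
#'   `0 <= start < stop`.
#' @return An object of class `roi`.
#' @export
roi <- function(row_start, row_stop, col_start, col_stop) {
  v <- as.integer(c(row_start, row_stop, col_start, col_stop))
  if (any(is.na(v))) stop("ROI indices must be integers", call. = FALSE)
  if (v[1L] < 0L || v[3L] < 0L || v[1L] >= v[2L] || v[3L] >= v[4L]) {
    stop("ROI must satisfy 0 <= start < stop on both axes", call. = FALSE)
  }
  structure(list(row_start = v[1L], row_stop = v[2L],
                 col_start = v[3L], col_stop = v[4L]), class = "roi")
}

#' Binary mask
#'
#' @param pixels Matrix containing only values 0 and 1 (logical accepted).
#' @return An object of class `binary_mask` (a 0/1 numeric matrix).
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels + 0
  if (!is.matrix(pixels) || !all(pixels %in% c(0, 1))) {
    stop("mask pixels must be a matrix of 0/1 values", call. = FALSE)
  }
  structure(pixels, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(unclass(x) == 1)))
  invisible(x)
}

png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 26L)
  # PNG signature (8) + IHDR length/type (8) + width/height (8) + depth byte
  as.integer(hdr[25L])
}

#' Read a grayscale image
#'
#' Reads a single-frame grayscale image and returns raw intensities as an
#' [intensity_image()]. PNG and TIFF values are returned on their stored
#' integer scale (e.g. 0--255 for 8-bit). For DICOM, the rescale
#' slope/intercept is applied when present, so values are in output units
#' (typically Hounsfield units).
#'
#' @param path Path to the image file.
#' @param dialect One of `"auto"`, `"png"`, `"tiff"`, `"dicom"`. `"auto"`
#'   dispatches on the file extension.
#' @return An [intensity_image()].
#' @export
read_image <- function(path, dialect = c("auto", "png", "tiff", "dicom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
                      png = "png", tif = "tiff", tiff = "tiff",
                      dcm = "dicom", dicom = "dicom",
                      stop("cannot infer image dialect from extension '.",
                           ext, "'", call. = FALSE))
  }
  px <- switch(dialect,
    png = {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3L) {
        stop("colour PNG input is unsupported; provide a grayscale image",
             call. = FALSE)
      }
      m * (2^png_bit_depth(path) - 1)
    },
    tiff = {
      m <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(m)) == 3L) {
        stop("colour TIFF input is unsupported; provide a grayscale image",
             call. = FALSE)
      }
      m + 0
    },
    dicom = read_dicom_pixels(path))
  intensity_image(px)
}

#' Normalize image intensities to [0, 1]
#'
#' Linear map of the window `(low, high)` onto `[0, 1]`, clipping values
#' outside the window. The default window is the observed min/max. All model
#' fitting in this package operates on normalized intensities so Gaussian
#' parameters are independent of the acquisition scale.
#'
#' @param img An [intensity_image()].
#' @param window Optional numeric `(low, high)` with `low < high`.
#' @return A normalized [intensity_image()] with `scale` recording the window.
#' @export
normalize_image <- function(img, window = NULL) {
  px <- as_pixel_matrix(img)
  if (is.null(window)) {
    window <- range(px)
    if (window[1L] == window[2L]) {
      stop("constant image: the default min/max window is degenerate; ",
           "supply an explicit window", call. = FALSE)
    }
  }
  if (window[1L] >= window[2L]) {
    stop("normalization window must satisfy low < high", call. = FALSE)
  }
  out <- (px - window[1L]) / (window[2L] - window[1L])
  out[out < 0] <- 0
  out[out > 1] <- 1
  o <- if (inherits(img, "intensity_image")) img$origin else c(0L, 0L)
  intensity_image(out, origin = o, scale = as.numeric(window))
}

#' Crop an image to a region of interest
#'
#' @param img An [intensity_image()].
#' @param r An [roi()] (0-based, half-open).
#' @return The sub-image with `origin` recording the crop offset so masks can
#'   be pasted back at original coordinates.
#' @export
crop_image <- function(img, r) {
  stopifnot(inherits(r, "roi"))
  px <- as_pixel_matrix(img)
  if (r$row_stop > nrow(px) || r$col_stop > ncol(px)) {
    stop("ROI exceeds image extent (", nrow(px), " x ", ncol(px), ")",
         call. = FALSE)
  }
  sub <- px[(r$row_start + 1L):r$row_stop, (r$col_start + 1L):r$col_stop,
            drop = FALSE]
  o <- if (inherits(img, "intensity_image")) img$origin else c(0L, 0L)
  sc <- if (inherits(img, "intensity_image")) img$scale else NULL
  intensity_image(sub, origin = o + c(r$row_start, r$col_start), scale = sc)
}

#' Write a binary mask as a PNG
#'
#' Writes an 8-bit grayscale PNG with values 0 and 255; [read_mask()]
#' reproduces the mask exactly.
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  m <- as_pixel_matrix(mask, "mask")
  if (!all(m %in% c(0, 1))) stop("mask must be 0/1", call. = FALSE)
  storage.mode(m) <- "double"
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' @param path Path to an 8-bit mask PNG (values 0/255).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  binary_mask((m > 0.5) + 0)
}
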
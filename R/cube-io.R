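#' Hyperspectral cube container
#'
#' A light wrapper around a `rows x cols x bands` reflectance array with its
#' band-center wavelengths.
#'
#' @param values Numeric array `rows x cols x bands`.
#' @param wavelengths Strictly increasing numeric vector (nm), one per band.
#' @param kind `"raw"` (digital numbers) or `"corrected"` (reflectance %).
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(values, wavelengths, kind = c("corrected", "raw")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3) abort("`values` must be a rows x cols x bands array.")
  if (is.integer(values)) storage.mode(values) <- "double"
  if (any(dim(values) < 1)) abort("All cube dimensions must be >= 1.")
  if (length(wavelengths) != dim(values)[3]) {
    abort("`wavelengths` length must equal the number of bands.")
  }
  if (any(diff(wavelengths) <= 0)) abort("`wavelengths` must be strictly increasing.")
  if (kind == "corrected" && !all(is.finite(values))) {
    abort("Corrected cube values must be finite.")
  }
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths), kind = kind),
    class = "hsi_cube"
  )
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

# ENVI data-type codes handled (IEEE float)
.envi_types <- list(`4` = list(what = "numeric", size = 4L),
                    `5` = list(what = "numeric", size = 8L))

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1])) {
    abort(paste0("Not an ENVI header (missing 'ENVI' magic): ", header_path))
  }
  body <- paste(txt[-1], collapse = "\n")
  fields <- list()
  # split into "key = value" entries where value may be { ... } across lines
  pat <- "(?s)([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1] == -1) abort("Empty ENVI header.")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    entry <- substr(body, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("(?s)^(.*?)=.*$", "\\1", entry, perl = TRUE)))
    val <- trimws(sub("(?s)^.*?=\\s*", "", entry, perl = TRUE))
    fields[[key]] <- val
  }
  num <- function(key) {
    if (is.null(fields[[key]])) abort(paste0("ENVI header missing `", key, "`."))
    as.numeric(fields[[key]])
  }
  wl_raw <- fields[["wavelength"]]
  if (is.null(wl_raw)) abort("ENVI header missing `wavelength = {...}`.")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", wl_raw), ",")[[1]])
  interleave <- tolower(trimws(fields[["interleave"]] %||% "bsq"))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    abort(paste0("Unsupported interleave: ", interleave))
  }
  dtype <- as.character(as.integer(num("data type")))
  if (!dtype %in% names(.envi_types)) {
    abort(paste0("Unsupported ENVI data type ", dtype, " (only 4 and 5 handled)."))
  }
  list(
    samples = as.integer(num("samples")),
    lines = as.integer(num("lines")),
    bands = as.integer(num("bands")),
    interleave = interleave,
    data_type = dtype,
    byte_order = as.integer(fields[["byte order"]] %||% "0"),
    wavelengths = wl
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ENVI header + raster pair into a cube
#'
#' Supports the key = value header dialect with a `wavelength = {...}` block,
#' BSQ / BIL / BIP interleaves, and IEEE float rasters (ENVI data types 4
#' and 5).
#'
#' @param header_path Path to the `.hdr` text header.
#' @param raster_path Path to the binary raster; defaults to `header_path`
#'   with the `.hdr` extension stripped.
#' @param kind Passed to [hsi_cube()] (`"corrected"` by default).
#' @return An [hsi_cube()].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path, raster_path = NULL, kind = "corrected") {
  if (is.null(raster_path)) raster_path <- sub("\\.hdr$", "", header_path)
  h <- parse_envi_header(header_path)
  if (length(h$wavelengths) != h$bands) {
    abort(sprintf("Header declares %d bands but lists %d wavelengths.",
                  h$bands, length(h$wavelengths)))
  }
  tp <- .envi_types[[h$data_type]]
  n_expected <- h$samples * h$lines * h$bands
  n_avail <- file.size(raster_path) %/% tp$size
  if (is.na(n_avail) || n_avail != n_expected) {
    abort(sprintf(
      "Raster size mismatch: header implies %d values, file holds %s.",
      n_expected, ifelse(is.na(n_avail), "none", n_avail)))
  }
  endian <- if (h$byte_order == 0) "little" else "big"
  raw_vals <- readBin(raster_path, what = tp$what, n = n_expected,
                      size = tp$size, endian = endian)
  # ENVI raster order is row-major within each frame
  vals <- switch(
    h$interleave,
    bsq = aperm(array(raw_vals, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, dim = c(h$bands, h$samples, h$lines)), c(3, 2, 1))
  )
  hsi_cube(vals, h$wavelengths, kind = kind)
}

#' Write a cube as an ENVI header + raster pair
#'
#' @param cube An [hsi_cube()].
#' @param path Raster path; the header is written to `paste0(path, ".hdr")`.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI numeric type code: 5 (float64, default, lossless for
#'   R doubles) or 4 (float32).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  data_type <- as.character(as.integer(data_type))
  if (!data_type %in% names(.envi_types)) abort("`data_type` must be 4 or 5.")
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {soilhsi export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {",
           paste(format(cube$wavelengths, trim = TRUE), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  vals <- switch(
    interleave,
    bsq = as.vector(aperm(cube$values, c(2, 1, 3))),
    bil = as.vector(aperm(cube$values, c(2, 3, 1))),
    bip = as.vector(aperm(cube$values, c(3, 2, 1)))
  )
  writeBin(as.double(vals), path, size = .envi_types[[data_type]]$size,
           endian = "little")
  invisible(path)
}

# replicate a 1 x cols x bands line frame across all rows
expand_line_frame <- function(frame, dims) {
  out <- array(0, dim = dims)
  for (b in seq_len(dims[3])) {
    out[, , b] <- matrix(frame[1, , b], nrow = dims[1], ncol = dims[2], byrow = TRUE)
  }
  out
}

as_frame_array <- function(frame, dims, what) {
  if (inherits(frame, "hsi_cube")) frame <- frame$values
  fd <- dim(frame)
  if (is.null(fd) || !length(fd) %in% c(2, 3)) {
    abort(paste0("`", what, "` must be a 3-D array (or 1 x cols x bands line frame)."))
  }
  if (length(fd) == 3 && all(fd == dims)) return(frame)
  if (length(fd) == 3 && fd[1] == 1 && fd[2] == dims[2] && fd[3] == dims[3]) {
    return(expand_line_frame(frame, dims))
  }
  abort(paste0("`", what, "` shape ", paste(fd, collapse = "x"),
               " is not broadcastable to the sample cube."))
}

#' White/dark reflectance correction
#'
#' Converts a raw digital-number cube to percent reflectance with the usual
#' flat-field equation `I = (I0 - D) / (W - D) * 100`, applied per pixel and
#' band. White and dark references may be full cubes or single-line
#' (`1 x cols x bands`) frames, which are broadcast across rows as acquired
#' by a pushbroom line scanner.
#'
#' @param i0 Raw sample cube ([hsi_cube()] or array).
#' @param white,dark White / dark reference cubes or line frames.
#' @param wavelengths Band wavelengths (taken from `i0` when it is an
#'   `hsi_cube`).
#' @return A corrected [hsi_cube()] on the 0--100 % scale.
#' @examples
#' wl <- c(1000, 1100, 1200)
#' w <- array(90, c(2, 2, 3)); d <- array(10, c(2, 2, 3))
#' raw <- array(50, c(2, 2, 3))
#' correct_reflectance(hsi_cube(raw, wl, "raw"), w, d)$values[1, 1, ]
#' @export
correct_reflectance <- function(i0, white, dark, wavelengths = NULL) {
  if (inherits(i0, "hsi_cube")) {
    wavelengths <- i0$wavelengths
    i0 <- i0$values
  }
  if (is.null(wavelengths)) abort("`wavelengths` required when `i0` is a bare array.")
  dims <- dim(i0)
  W <- as_frame_array(white, dims, "white")
  D <- as_frame_array(dark, dims, "dark")
  denom <- W - D
  if (any(denom == 0)) {
    abort("White and dark references coincide on some pixels (division by zero).")
  }
  hsi_cube((i0 - D) / denom * 100, wavelengths, kind = "corrected")
}

#' Synthesise raw/white/dark frames from a corrected cube
#'
#' Inverse of [correct_reflectance()]: given a corrected reflectance cube and
#' reference frames, produces the raw cube `I0 = I/100 * (W - D) + D` that
#' would correct back to it. Used to exercise the correction path against
#' cubes generated directly in reflectance space.
#'
#' @inheritParams correct_reflectance
#' @param corrected Corrected cube ([hsi_cube()] or array, % scale).
#' @return A raw [hsi_cube()].
#' @export
synthesize_raw_frames <- function(corrected, white, dark, wavelengths = NULL) {
  if (inherits(corrected, "hsi_cube")) {
    wavelengths <- corrected$wavelengths
    corrected <- corrected$values
  }
  if (is.null(wavelengths)) abort("`wavelengths` required when `corrected` is a bare array.")
  dims <- dim(corrected)
  W <- as_frame_array(white, dims, "white")
  D <- as_frame_array(dark, dims, "dark")
  hsi_cube(corrected / 100 * (W - D) + D, wavelengths, kind = "raw")
}

#' Region-of-interest specification
#'
#' Coordinates are 0-based and half-open: rows `[row0, row0 + height)`,
#' columns `[col0, col0 + width)`.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels (>= 1).
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(row0, col0, height, width) {
  if (height < 1 || width < 1) abort("ROI `height` and `width` must be >= 1.")
  if (row0 < 0 || col0 < 0) abort("ROI origin must be non-negative.")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' Centered square ROI for a cube
#'
#' @param cube An [hsi_cube()].
#' @param size Side length in pixels (default 50).
#' @return A [roi_spec()] centered in the image.
#' @export
centered_roi <- function(cube, size = 50L) {
  d <- dim(cube$values)
  if (size > min(d[1:2])) abort("ROI larger than the image.")
  roi_spec(floor((d[1] - size) / 2), floor((d[2] - size) / 2), size, size)
}

#' Crop a region of interest from a cube
#'
#' @param cube An [hsi_cube()].
#' @param roi A [roi_spec()].
#' @return Array `height x width x bands` with attribute `"wavelengths"`.
#' @export
crop_roi <- function(cube, roi) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(roi, "roi_spec"))
  d <- dim(cube$values)
  if (roi$row0 + roi$height > d[1] || roi$col0 + roi$width > d[2]) {
    abort("ROI exceeds image bounds.")
  }
  out <- cube$values[roi$row0 + seq_len(roi$height),
                     roi$col0 + seq_len(roi$width), , drop = FALSE]
  attr(out, "wavelengths") <- cube$wavelengths
  out
}
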
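# ---- internal validators ----------------------------------------------------

check_axis <- function(values, what = "wavenumber axis", min_len = 1L) {
  values <- as.numeric(values)
  if (length(values) < min_len)
    stop(what, " must have at least ", min_len, " points", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop(what, " must be finite", call. = FALSE)
  if (any(values <= 0))
    stop(what, " must be positive (cm-1)", call. = FALSE)
  if (any(diff(values) <= 0))
    stop(what, " must be strictly increasing", call. = FALSE)
  values
}

# ---- spectrum ---------------------------------------------------------------

#' Construct a single Raman spectrum
#'
#' A spectrum pairs a strictly increasing wavenumber axis (cm-1) with one
#' intensity value per channel (CCD counts, arbitrary units).
#'
#' @param wavenumber numeric, strictly increasing, positive (cm-1).
#' @param intensity numeric, same length, finite.
#' @return An object of class `raman_spectrum` with elements `wavenumber`
#'   and `intensity`.
#' @export
#' @examples
#' s <- raman_spectrum(seq(800, 1800, 10), rnorm(101)^2)
raman_spectrum <- function(wavenumber, intensity) {
  wavenumber <- check_axis(wavenumber, min_len = 2L)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavenumber))
    stop("intensity and wavenumber must have the same length", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity must be finite", call. = FALSE)
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "raman_spectrum")
}

#' @exportS3Method base::print
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum: %d channels, %.0f-%.0f cm-1>\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

# ---- hyperspectral cube -----------------------------------------------------

#' Construct a hyperspectral Raman image cube
#'
#' The cube stores intensities as a `depth rows x lateral cols x channels`
#' array.  Row 1 is the tissue surface (articular, media-exposed or
#' trypsin-exposed, depending on the tissue model); the depth of row `r` is
#' `(r - 0.5) * pixel_size_um / 1000` mm (pixel-center convention), so depth
#' grows monotonically with row index.
#'
#' @param data numeric 3-d array, `nrow x ncol x nchannel`.
#' @param wavenumber axis in cm-1, length `dim(data)[3]`.
#' @param pixel_size_um edge length of a (square) pixel in micrometres.
#' @param surface_row row index of the tissue surface (default 1).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavenumber, pixel_size_um = 10, surface_row = 1L) {
  wavenumber <- check_axis(wavenumber)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-d array (rows x cols x channels)", call. = FALSE)
  if (dim(data)[3] != length(wavenumber))
    stop("third array dimension (", dim(data)[3],
         ") must match axis length (", length(wavenumber), ")", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar", call. = FALSE)
  surface_row <- as.integer(surface_row)
  if (surface_row < 1L || surface_row > dim(data)[1])
    stop("surface_row out of range", call. = FALSE)
  structure(list(data = data, wavenumber = wavenumber,
                 pixel_size_um = as.numeric(pixel_size_um),
                 surface_row = surface_row),
            class = "hyper_cube")
}

#' @exportS3Method base::print
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hyper_cube: %d x %d px (%.0f x %.0f um), %d channels %.0f-%.0f cm-1>\n",
    d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um, d[3],
    min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Depths (mm) of the pixel-row centers of a cube or map
#'
#' @param n_rows number of depth rows.
#' @param pixel_size_um pixel size in micrometres.
#' @return numeric vector of depths in mm, length `n_rows`.
#' @export
row_depths_mm <- function(n_rows, pixel_size_um) {
  (seq_len(n_rows) - 0.5) * pixel_size_um / 1000
}

#' Flatten a cube to the pixel-by-channel matrix D
#'
#' Pixels are stacked with the depth (row) index varying fastest, i.e. pixel
#' `p = (c - 1) * nrow + r`; [unflatten_matrix()] inverts this ordering.
#'
#' @param cube a `hyper_cube`.
#' @return numeric matrix, `n_pixels x n_channels`.
#' @export
flatten_cube <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Reshape a per-pixel vector or matrix column back to image geometry
#'
#' @param v numeric vector of length `nrow * ncol` in [flatten_cube()] order.
#' @param nrow,ncol image dimensions.
#' @return numeric `nrow x ncol` matrix.
#' @export
unflatten_matrix <- function(v, nrow, ncol) {
  stopifnot(length(v) == nrow * ncol)
  matrix(v, nrow = nrow, ncol = ncol)
}

# ---- cropping ---------------------------------------------------------------

#' Crop a cube to a wavenumber interval
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi` (closed
#' interval); all other fields are unchanged.  The default analysis range
#' for curve resolution is the biomolecular fingerprint, 800-1800 cm-1.
#'
#' @param cube a `hyper_cube`.
#' @param lo,hi interval bounds in cm-1, `lo < hi`.
#' @return A `hyper_cube` restricted to the channels in `[lo, hi]`.
#' @export
crop_range <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!(is.numeric(lo) && is.numeric(hi)) || lo >= hi)
    stop("need lo < hi", call. = FALSE)
  sel <- which(cube$wavenumber >= lo & cube$wavenumber <= hi)
  if (length(sel) == 0L)
    stop(sprintf("no channels in range [%g, %g] cm-1", lo, hi), call. = FALSE)
  hyper_cube(cube$data[, , sel, drop = FALSE], cube$wavenumber[sel],
             pixel_size_um = cube$pixel_size_um,
             surface_row = cube$surface_row)
}

# ---- band integration -------------------------------------------------------

trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Integrate a spectral band (trapezoidal rule)
#'
#' Trapezoidal integral of the intensity over the channels inside
#' `[lo, hi]`.  Used e.g. for univariate water mapping over the broad OH
#' stretching band (default 3100-3600 cm-1 in [water_map_hw()]).
#'
#' @param spectrum a `raman_spectrum`.
#' @param lo,hi band limits in cm-1, `lo < hi`, inside the axis range.
#' @return scalar integral in a.u. * cm-1.
#' @export
band_integral <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (lo >= hi) stop("need lo < hi", call. = FALSE)
  wn <- spectrum$wavenumber
  if (hi < min(wn) || lo > max(wn))
    stop(sprintf("band [%g, %g] outside axis range [%g, %g]",
                 lo, hi, min(wn), max(wn)), call. = FALSE)
  sel <- which(wn >= lo & wn <= hi)
  if (length(sel) < 2L)
    stop("fewer than 2 channels in band; cannot integrate", call. = FALSE)
  trapz_int(wn[sel], spectrum$intensity[sel])
}

# band integral applied to every pixel of a cube at once (internal)
band_integral_cube <- function(cube, lo, hi) {
  wn <- cube$wavenumber
  if (hi < min(wn) || lo > max(wn))
    stop(sprintf("band [%g, %g] outside axis range [%g, %g]",
                 lo, hi, min(wn), max(wn)), call. = FALSE)
  sel <- which(wn >= lo & wn <= hi)
  if (length(sel) < 2L)
    stop("fewer than 2 channels in band; cannot integrate", call. = FALSE)
  x <- wn[sel]
  n <- length(x)
  # trapezoid quadrature weights on the selected sub-axis
  w <- c(diff(x) / 2, 0) + c(0, diff(x) / 2)
  D <- flatten_cube(cube)[, sel, drop = FALSE]
  v <- as.vector(D %*% w)
  unflatten_matrix(v, dim(cube$data)[1], dim(cube$data)[2])
}

# ---- regions of interest ----------------------------------------------------

#' Define a rectangular region of interest in micrometres
#'
#' Coordinates are relative to the cube origin (top-left = surface-left
#' corner).  The canonical heterogeneity ROI is 250 x 250 um.
#'
#' @param top_um,left_um position of the top-left ROI corner in um.
#' @param height_um,width_um ROI extent in um, both > 0.
#' @return An object of class `roi`.
#' @export
roi <- function(top_um, left_um, height_um, width_um) {
  vals <- c(top_um, left_um, height_um, width_um)
  if (!all(is.finite(vals)))
    stop("ROI coordinates must be finite", call. = FALSE)
  if (top_um < 0 || left_um < 0)
    stop("ROI origin must be non-negative", call. = FALSE)
  if (height_um <= 0 || width_um <= 0)
    stop("ROI must have positive height and width", call. = FALSE)
  structure(list(top_um = top_um, left_um = left_um,
                 height_um = height_um, width_um = width_um), class = "roi")
}

#' Convert a ROI in micrometres to pixel index ranges
#'
#' Returns half-open pixel blocks as inclusive 1-based index vectors:
#' the block starts at `floor(top_um / pixel_size)` (0-based) and spans
#' `round(height_um / pixel_size)` rows, likewise for columns, so adjacent
#' ROIs tile the image without overlap.
#'
#' @param roi a [roi()].
#' @param cube a `hyper_cube`.
#' @return list with integer vectors `rows` and `cols`.
#' @export
roi_to_pixels <- function(roi, cube) {
  stopifnot(inherits(roi, "roi"), inherits(cube, "hyper_cube"))
  ps <- cube$pixel_size_um
  d <- dim(cube$data)
  r0 <- floor(roi$top_um / ps)
  c0 <- floor(roi$left_um / ps)
  nr <- round(roi$height_um / ps)
  nc <- round(roi$width_um / ps)
  if (nr < 1L || nc < 1L)
    stop("ROI smaller than one pixel", call. = FALSE)
  if (r0 + nr > d[1] || c0 + nc > d[2])
    stop(sprintf("ROI exceeds cube extent (%d x %d px)", d[1], d[2]),
         call. = FALSE)
  list(rows = (r0 + 1L):(r0 + nr), cols = (c0 + 1L):(c0 + nc))
}
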
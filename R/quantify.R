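# Quantitative outputs derived from concentration maps: laterally averaged
# depth profiles, anchor-based normalization, conversion to absolute
# % wet-weight concentration, univariate high-wavenumber water mapping, and
# localized heterogeneity (coefficient-of-variation) scoring.

#' Construct a depth profile
#'
#' @param depths_mm strictly increasing depths in mm (pixel-center
#'   convention).
#' @param values concentration values (a.u., normalized, or % wet weight).
#' @param sd optional per-depth spread (same length).
#' @param constituent label.
#' @param normalization optional record, list(scheme, anchor_depth_mm,
#'   anchor_value).
#' @return object of class `depth_profile`.
#' @export
depth_profile <- function(depths_mm, values, sd = NULL, constituent = NA_character_,
                          normalization = NULL) {
  depths_mm <- as.numeric(depths_mm); values <- as.numeric(values)
  if (length(depths_mm) != length(values))
    stop("depths and values must have equal length", call. = FALSE)
  if (any(diff(depths_mm) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (!is.null(sd) && length(sd) != length(values))
    stop("sd length mismatch", call. = FALSE)
  structure(list(depths_mm = depths_mm, values = values, sd = sd,
                 constituent = constituent, normalization = normalization),
            class = "depth_profile")
}

#' @exportS3Method base::print
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile: %s, %d depths %.3f-%.3f mm%s>\n",
              x$constituent, length(x$values), min(x$depths_mm),
              max(x$depths_mm),
              if (is.null(x$normalization)) "" else
                paste0(", normalized (", x$normalization$scheme, ")")))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(depth_mm = x$depths_mm, value = x$values,
             sd = if (is.null(x$sd)) NA_real_ else x$sd,
             constituent = x$constituent,
             normalization = if (is.null(x$normalization)) "none" else
               x$normalization$scheme,
             stringsAsFactors = FALSE)
}

#' Laterally average a concentration map into a depth profile
#'
#' Averages pixel concentrations across the lateral (column) dimension;
#' the `sd` field carries the per-row lateral standard deviation.
#'
#' @param map depth x lateral numeric matrix (one component).
#' @param pixel_size_um pixel size in um.
#' @param constituent label carried into the profile.
#' @return a [depth_profile()] in arbitrary units.
#' @export
lateral_average <- function(map, pixel_size_um, constituent = NA_character_) {
  map <- as.matrix(map)
  if (length(map) == 0L) stop("empty concentration map", call. = FALSE)
  depth_profile(row_depths_mm(nrow(map), pixel_size_um),
                rowMeans(map),
                sd = apply(map, 1, stats::sd),
                constituent = constituent)
}

#' Normalize a depth profile to an anchor
#'
#' Three schemes mirror the field's normalization conventions:
#' `peak_anchor` divides by the value at a stated anchor depth (typically
#' the peak-concentration depth, e.g. 1.4 mm in native cartilage; when no
#' depth is given, the depth of the profile maximum is used);
#' `surface_anchor` divides by the topmost profile point (or a stated
#' near-surface depth such as 0.1 or 0.4 mm); `mean_anchor` divides by the
#' profile mean (used for depth-uniform constituents).  Anchor depths are
#' resolved to the nearest profile point.
#'
#' @param profile a [depth_profile()].
#' @param scheme "peak_anchor", "surface_anchor" or "mean_anchor".
#' @param anchor_depth_mm anchor depth in mm (optional, see above).
#' @return a normalized [depth_profile()] with the normalization record
#'   filled (value 1 at the anchor).
#' @export
normalize_profile <- function(profile,
                              scheme = c("peak_anchor", "surface_anchor",
                                         "mean_anchor"),
                              anchor_depth_mm = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  scheme <- match.arg(scheme)
  d <- profile$depths_mm
  if (scheme == "mean_anchor") {
    anchor_value <- mean(profile$values)
    anchor_depth <- NA_real_
  } else {
    anchor_depth <- if (!is.null(anchor_depth_mm)) anchor_depth_mm
      else if (scheme == "surface_anchor") d[1]
      else d[which.max(profile$values)]
    i <- which.min(abs(d - anchor_depth))
    anchor_depth <- d[i]
    anchor_value <- profile$values[i]
  }
  if (!is.finite(anchor_value) || anchor_value <= 0)
    stop("anchor value must be > 0", call. = FALSE)
  depth_profile(d, profile$values / anchor_value,
                sd = if (is.null(profile$sd)) NULL else
                  profile$sd / anchor_value,
                constituent = profile$constituent,
                normalization = list(scheme = scheme,
                                     anchor_depth_mm = anchor_depth,
                                     anchor_value = anchor_value))
}

#' Convert a relative profile to absolute concentration (% wet weight)
#'
#' Rescales the profile so that its depth-averaged mean equals the bulk
#' mean concentration measured by assay, i.e.
#' `out = in * mean_concentration / mean(in)` (`mode = "mean_match"`,
#' default).  `mode = "direct"` multiplies the profile by
#' `mean_concentration` as-is.
#'
#' @param profile a [depth_profile()] (typically normalized).
#' @param mean_concentration bulk mean concentration in % wet weight, > 0.
#' @param mode "mean_match" or "direct".
#' @return a [depth_profile()] in % wet weight.
#' @export
to_absolute <- function(profile, mean_concentration,
                        mode = c("mean_match", "direct")) {
  stopifnot(inherits(profile, "depth_profile"))
  mode <- match.arg(mode)
  if (!is.finite(mean_concentration) || mean_concentration <= 0)
    stop("mean_concentration must be > 0", call. = FALSE)
  m <- mean(profile$values)
  if (m <= 0) stop("profile mean must be > 0", call. = FALSE)
  f <- if (mode == "mean_match") mean_concentration / m else mean_concentration
  depth_profile(profile$depths_mm, profile$values * f,
                sd = if (is.null(profile$sd)) NULL else profile$sd * f,
                constituent = profile$constituent,
                normalization = list(scheme = "absolute_ww",
                                     anchor_depth_mm = NA_real_,
                                     anchor_value = f))
}

#' Univariate high-wavenumber water map
#'
#' Integrates each (baseline-subtracted) pixel spectrum over the broad OH
#' stretching band (default 3100-3600 cm-1, centred near 3400 cm-1) to map
#' relative water content.  Set `band` to a degenerate single-channel
#' choice via `single_channel` for intensity mapping at ~3400 cm-1
#' instead of integration.
#'
#' @param cube a [hyper_cube()] covering the band.
#' @param band integration limits in cm-1 (default `c(3100, 3600)`).
#' @param baseline a [baseline_params()] applied before integration, or
#'   `NULL` if the cube is already baseline-corrected.  The default uses a
#'   2000-point window: the lower-envelope window must comfortably exceed
#'   the OH band support (~±3 sigma = 840 cm-1), otherwise the opening
#'   clips the band itself and biases the water gradient.
#' @param single_channel if `TRUE`, map the intensity of the channel
#'   nearest `mean(band)` instead of the band integral.
#' @return depth x lateral matrix of water abundance (a.u.; negative
#'   integrals clipped to zero with a warning).
#' @export
water_map_hw <- function(cube, band = c(3100, 3600),
                         baseline = baseline_params(window_points = 2000L),
                         single_channel = FALSE) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (band[1] > max(cube$wavenumber) || band[2] < min(cube$wavenumber))
    stop("water band outside cube axis", call. = FALSE)
  band <- c(max(band[1], min(cube$wavenumber)),
            min(band[2], max(cube$wavenumber)))
  if (!is.null(baseline))
    cube <- subtract_baseline(cube, baseline)$cube
  if (single_channel) {
    ch <- which.min(abs(cube$wavenumber - mean(band)))
    m <- cube$data[, , ch]
  } else {
    m <- band_integral_cube(cube, band[1], band[2])
  }
  if (any(m < 0)) {
    warning("negative water-band integrals clipped to 0")
    m[m < 0] <- 0
  }
  m
}

#' Localized heterogeneity score (coefficient of variation)
#'
#' Computes `100 * sd / mean` over the pixels of a rectangular ROI
#' (sample standard deviation, n - 1).  The canonical ROI is 250 x 250 um,
#' i.e. 625 pixels at 10 um resolution.
#'
#' @param map depth x lateral concentration matrix.
#' @param roi a [roi()].
#' @param pixel_size_um pixel size of the map in um.
#' @param constituent label.
#' @return object of class `heterogeneity_score`: list(roi, constituent,
#'   cov) with `cov` in percent.
#' @export
local_cov <- function(map, roi, pixel_size_um, constituent = NA_character_) {
  map <- as.matrix(map)
  cube_like <- hyper_cube(array(0, c(nrow(map), ncol(map), 2)),
                          c(1, 2), pixel_size_um = pixel_size_um)
  px <- roi_to_pixels(roi, cube_like)
  vals <- map[px$rows, px$cols]
  if (length(vals) < 2L)
    stop("ROI must contain at least 2 pixels", call. = FALSE)
  m <- mean(vals)
  if (m <= 0) stop("ROI mean must be > 0 for a coefficient of variation",
                   call. = FALSE)
  structure(list(roi = roi, constituent = constituent,
                 n_pixels = length(vals),
                 cov = 100 * stats::sd(vals) / m),
            class = "heterogeneity_score")
}

#' @exportS3Method base::print
print.heterogeneity_score <- function(x, ...) {
  cat(sprintf("<heterogeneity: %s, CoV %.2f%% over %d px>\n",
              x$constituent, x$cov, x$n_pixels))
  invisible(x)
}
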
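# Synthetic hyperspectral phantoms of the three cartilage tissue models
# (native explant, engineered construct, trypsin-digested explant) with
# known component spectra, concentration fields, autofluorescence baseline
# and noise, plus simulated sectioned biochemical assays.

# ---- seed substreams --------------------------------------------------------

# One user-facing seed is split into independent substreams (fields,
# baseline, noise, assay, ...) so changing e.g. the noise draw does not
# shift the concentration fields.  Simple multiplicative-congruential mix;
# results stay below 2^31.
substream_seed <- function(seed, id) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (k in seq_len(id + 1L)) {
    s <- (s * 48271) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- component spectral models ----------------------------------------------

#' Gaussian peak specification
#'
#' @param center peak center in cm-1.
#' @param width Gaussian sigma in cm-1, > 0.
#' @param amplitude peak height in a.u., >= 0.
#' @return list of class `peak_spec`.
#' @export
peak_spec <- function(center, width, amplitude) {
  if (width <= 0) stop("peak width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("peak amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "peak_spec")
}

#' Spectral model of a molecular constituent as a sum of Gaussian peaks
#'
#' @param name constituent label (e.g. "GAG", "collagen", "water", "cell").
#' @param peaks list of [peak_spec()] objects, at least one.
#' @return list of class `component_model`.
#' @export
component_model <- function(name, peaks) {
  if (length(peaks) == 0L)
    stop("a component model needs at least one peak", call. = FALSE)
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(name = name, peaks = peaks), class = "component_model")
}

#' Default spectral models of the cartilage constituents
#'
#' Peak positions follow the standard cartilage Raman assignments: GAG
#' carries the 1061 cm-1 S=O sulfate stretch (plus minor CH/COC bands),
#' collagen the 836/875 cm-1 proline/hydroxyproline pair, amide III
#' (1245 cm-1), the CH2 deformation (1450 cm-1) and amide I (1672 cm-1),
#' water the broad OH stretching band near 3400 cm-1 with a weak 1640 cm-1
#' bending mode, and the cellular residual is dominated by the 1004 cm-1
#' phenylalanine ring-breathing mode.
#'
#' @param include_cell include the chondrocyte stand-in component.
#' @return named list of [component_model()]s.
#' @export
default_components <- function(include_cell = FALSE) {
  comps <- list(
    GAG = component_model("GAG", list(
      peak_spec(1061, 12, 1.00),   # nu_s(S=O), the GAG marker band
      peak_spec(940, 14, 0.35),
      peak_spec(1126, 12, 0.30),
      peak_spec(1375, 16, 0.40),
      peak_spec(2935, 35, 0.45)
    )),
    collagen = component_model("collagen", list(
      peak_spec(836, 10, 0.55),    # proline
      peak_spec(875, 10, 0.60),    # hydroxyproline
      peak_spec(1245, 16, 0.75),   # amide III
      peak_spec(1450, 15, 0.85),   # delta(CH2)
      peak_spec(1672, 16, 0.80),   # amide I
      peak_spec(2940, 40, 0.70)
    )),
    water = component_model("water", list(
      peak_spec(3400, 140, 1.20),  # OH stretch, broad
      peak_spec(1640, 35, 0.35)    # OH bend: the distinct ~1640 shoulder of
                                   # highly hydrated (~80 % water) tissue
    ))
  )
  if (include_cell) {
    comps$cell <- component_model("cell", list(
      peak_spec(1004, 7, 1.00),    # phenylalanine
      peak_spec(1340, 18, 0.30),
      peak_spec(1580, 14, 0.25),
      peak_spec(2930, 35, 0.40)
    ))
  }
  comps
}

#' Render a component model on a wavenumber axis
#'
#' @param model a [component_model()].
#' @param wavenumber strictly increasing axis in cm-1.
#' @return a [raman_spectrum()] (non-negative everywhere).
#' @export
render_component_spectrum <- function(model, wavenumber) {
  stopifnot(inherits(model, "component_model"))
  wavenumber <- check_axis(wavenumber)
  y <- numeric(length(wavenumber))
  for (p in model$peaks)
    y <- y + p$amplitude * exp(-0.5 * ((wavenumber - p$center) / p$width)^2)
  raman_spectrum(wavenumber, y)
}

# ---- depth profiles ---------------------------------------------------------

#' Depth-profile model of a constituent
#'
#' @param constituent label.
#' @param shape one of "linear", "sigmoid", "constant".
#' @param value_at_surface,value_at_depth relative concentration at the
#'   first and last pixel-row center; both >= 0.  A constant shape requires
#'   the two to be equal.
#' @param tissue_depth_mm total imaged tissue depth in mm.
#' @param midpoint,steepness sigmoid shape parameters: the inflection
#'   position as a fraction of depth (default 0.5) and the logistic rate
#'   (default 8); ignored for other shapes.
#' @return list of class `profile_model`.
#' @export
profile_model <- function(constituent, shape = c("linear", "sigmoid", "constant"),
                          value_at_surface, value_at_depth,
                          tissue_depth_mm = 3.5, midpoint = 0.5,
                          steepness = 8) {
  shape <- match.arg(shape)
  if (value_at_surface < 0 || value_at_depth < 0)
    stop("profile values must be >= 0", call. = FALSE)
  if (shape == "constant" && value_at_surface != value_at_depth)
    stop("constant shape requires equal endpoint values", call. = FALSE)
  if (midpoint <= 0 || midpoint >= 1 || steepness <= 0)
    stop("need 0 < midpoint < 1 and steepness > 0", call. = FALSE)
  structure(list(constituent = constituent, shape = shape,
                 value_at_surface = value_at_surface,
                 value_at_depth = value_at_depth,
                 tissue_depth_mm = tissue_depth_mm,
                 midpoint = midpoint, steepness = steepness),
            class = "profile_model")
}

#' Sample a profile model at pixel-row centers
#'
#' The profile is parameterized so that the first and last row take exactly
#' `value_at_surface` and `value_at_depth`.
#'
#' @param model a [profile_model()].
#' @param n_rows number of depth rows, >= 1.
#' @param pixel_size_um pixel size in um.
#' @return numeric vector of length `n_rows`.
#' @export
make_profile <- function(model, n_rows, pixel_size_um) {
  stopifnot(inherits(model, "profile_model"), n_rows >= 1L)
  d <- row_depths_mm(n_rows, pixel_size_um)
  if (n_rows == 1L) return(model$value_at_surface)
  t <- (d - d[1]) / (d[n_rows] - d[1])
  v <- switch(model$shape,
    constant = rep(model$value_at_surface, n_rows),
    linear = model$value_at_surface +
      (model$value_at_depth - model$value_at_surface) * t,
    sigmoid = {
      raw <- 1 / (1 + exp(-model$steepness * (t - model$midpoint)))
      raw <- (raw - raw[1]) / (raw[n_rows] - raw[1])
      model$value_at_surface +
        (model$value_at_depth - model$value_at_surface) * raw
    })
  if (any(v < 0)) stop("profile produced negative values", call. = FALSE)
  v
}

#' Spatially separated profile set for parameter-recovery testing
#'
#' Profiles in which each constituent dominates a distinct depth zone
#' (collagen the surface, water the middle, GAG the deep zone, each
#' decaying to near zero elsewhere).  A bilinear model with such zones is
#' essentially free of rotational ambiguity, which makes this the
#' appropriate ground truth for exact parameter-recovery tests of the
#' curve resolution; the tissue-model defaults ([default_profiles()]),
#' whose gradients never vanish, are the realistic counterpart.
#'
#' @param tissue_depth_mm imaged depth in mm.
#' @return named list of [profile_model()]s (GAG, collagen, water).
#' @export
separated_profiles <- function(tissue_depth_mm = 3.5) {
  list(
    GAG = profile_model("GAG", "sigmoid", 0.01, 1.0,
                        tissue_depth_mm, midpoint = 0.70, steepness = 14),
    collagen = profile_model("collagen", "sigmoid", 1.0, 0.02,
                             tissue_depth_mm, midpoint = 0.35,
                             steepness = 14),
    water = profile_model("water", "sigmoid", 1.0, 0.005,
                          tissue_depth_mm, midpoint = 0.55, steepness = 14))
}

# ---- tissue-model defaults --------------------------------------------------

# Relative (0..1-scale) endpoint values are anchored to the measured
# % wet-weight gradients of each tissue model; `ww_mean` is the bulk
# mean concentration in % wet weight used to scale simulated assays.
# Native water declines linearly such that the relative drop from 0.1 mm
# to 2.5 mm depth is exactly 12.5 %.
tissue_model_table <- function(model, include_cell = FALSE) {
  model <- match.arg(model, c("native", "engineered", "digested"))
  water_slope <- 0.125 / (2.5 - 0.1 + 0.1 * 0.125)   # per mm, surface value 1
  tbl <- switch(model,
    native = list(
      tissue_depth_mm = 3.5,
      profiles = list(
        GAG = c(shape = "linear", lo = 0.32, hi = 1.00),       # 3.3 -> 10.3 %ww
        collagen = c(shape = "linear", lo = 0.50, hi = 1.00),  # 4.1 -> 8.2 %ww
        water = c(shape = "linear", lo = 1.00,
                  hi = 1 - water_slope * 3.5)
      ),
      ww_mean = c(GAG = 6.8, collagen = 6.2, water = 78)
    ),
    engineered = list(
      tissue_depth_mm = 3.2,
      profiles = list(
        GAG = c(shape = "linear", lo = 1.00, hi = 0.19),       # 7.3 -> 2.8 %ww
        collagen = c(shape = "linear", lo = 1.00, hi = 0.05),  # 0.9 -> 0.2 %ww
        water = c(shape = "constant", lo = 1.00, hi = 1.00)
      ),
      ww_mean = c(GAG = 5.0, collagen = 0.55, water = 85)
    ),
    digested = list(
      tissue_depth_mm = 2.5,
      profiles = list(
        GAG = c(shape = "linear", lo = 0.16, hi = 1.00),       # 1.7 -> 6.7 %ww
        collagen = c(shape = "constant", lo = 1.00, hi = 1.00), # uniform, 9.7 %ww
        water = c(shape = "constant", lo = 1.00, hi = 1.00)
      ),
      ww_mean = c(GAG = 4.2, collagen = 9.7, water = 80)
    ))
  if (include_cell) tbl$ww_mean <- c(tbl$ww_mean, cell = 1)
  tbl
}

#' Default profile models for a tissue model
#'
#' Native cartilage: GAG and collagen increase with distance from the
#' articular surface while water decreases (12.5 % relative drop between
#' 0.1 and 2.5 mm depth).  Engineered constructs: GAG and collagen decrease
#' from the media-exposed surface.  Digested cartilage: GAG increases from
#' the trypsin-exposed surface while collagen stays uniform.
#'
#' @param model "native", "engineered" or "digested".
#' @return named list of [profile_model()]s (GAG, collagen, water).
#' @export
default_profiles <- function(model = c("native", "engineered", "digested")) {
  model <- match.arg(model)
  tbl <- tissue_model_table(model)
  lapply(stats::setNames(names(tbl$profiles), names(tbl$profiles)), function(nm) {
    p <- tbl$profiles[[nm]]
    profile_model(nm, shape = p[["shape"]],
                  value_at_surface = as.numeric(p[["lo"]]),
                  value_at_depth = as.numeric(p[["hi"]]),
                  tissue_depth_mm = tbl$tissue_depth_mm)
  })
}

# ---- phantom generation -----------------------------------------------------

# smooth, mean-one multiplicative lateral factor (per image column)
lateral_factor <- function(n_cols, cv, smooth_w = 5L) {
  if (cv <= 0 || n_cols < 2L) return(rep(1, n_cols))
  z <- stats::rnorm(n_cols)
  if (smooth_w > 1L && n_cols > smooth_w) {
    k <- rep(1 / smooth_w, smooth_w)
    zp <- c(rev(z[seq_len(smooth_w)]), z, rev(z)[seq_len(smooth_w)])
    z <- stats::filter(zp, k, sides = 2)[(smooth_w + 1):(smooth_w + n_cols)]
    z <- as.numeric(z) / sqrt(sum(k^2))       # restore unit variance
  }
  f <- exp(cv * z)
  f / mean(f)
}

# smooth 2-d random field with mean one, used for the cellular component
blob_field <- function(n_rows, n_cols, cv) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  k <- max(3L, round(min(n_rows, n_cols) / 8))
  sm <- function(M) {
    M <- apply(M, 2, function(v) stats::filter(c(rev(v[1:k]), v, rev(v)[1:k]),
      rep(1 / k, k), sides = 2)[(k + 1):(k + length(v))])
    t(apply(t(M), 2, function(v) stats::filter(c(rev(v[1:k]), v, rev(v)[1:k]),
      rep(1 / k, k), sides = 2)[(k + 1):(k + length(v))]))
  }
  z <- sm(z)
  z <- (z - mean(z)) / stats::sd(z)
  f <- exp(cv * z)
  f / mean(f)
}

#' Generate a synthetic hyperspectral cartilage phantom
#'
#' Builds `cube = sum_k c_k(x) s_k(nu) + baseline(x, nu) + noise` for one of
#' the three tissue models, returning both the emitted cube and the full
#' ground truth (rendered component spectra, concentration fields, baseline)
#' for parameter-recovery testing.  Deterministic given `seed`; the seed is
#' split into independent substreams for fields, baseline and noise.
#'
#' @param tissue_model "native", "engineered" or "digested".
#' @param n_rows,n_cols image geometry in pixels (defaults 350 x 100,
#'   i.e. ~3500 x 1000 um at 10 um resolution).
#' @param wavenumber acquisition axis in cm-1 (default 600-3600 cm-1 at
#'   4 cm-1 steps).
#' @param pixel_size_um pixel size; if `NULL`, derived as
#'   `tissue_depth_mm * 1000 / n_rows` so the phantom always spans the full
#'   model tissue depth.
#' @param components named list of [component_model()]s
#'   (default [default_components()]).
#' @param profiles named list of [profile_model()]s
#'   (default [default_profiles()] for the tissue model).
#' @param lateral_cv multiplicative lateral (per-column) variation of the
#'   concentration fields; either one value or a named vector per
#'   constituent.  Depth monotonicity of each column is preserved.
#' @param baseline_level autofluorescence amplitude relative to the mean
#'   pure Raman intensity (0 disables the baseline).
#' @param noise_level Gaussian noise level relative to the mean intensity,
#'   with an intensity-proportional (shot-noise-like) component
#'   (0 disables noise).
#' @param include_cell add the chondrocyte stand-in component.
#' @param seed integer seed.
#' @return list with elements `cube` (a [hyper_cube()]) and `truth`
#'   (class `phantom_truth`: `spectra` k x n_channels matrix,
#'   `fields` named list of depth x lateral matrices, `baseline` array,
#'   `components`, `profiles`, `ww_mean`, `params`, `seed`).
#' @export
make_phantom <- function(tissue_model = c("native", "engineered", "digested"),
                         n_rows = 350L, n_cols = 100L,
                         wavenumber = seq(600, 3600, by = 4),
                         pixel_size_um = NULL,
                         components = default_components(include_cell),
                         profiles = default_profiles(tissue_model),
                         lateral_cv = c(GAG = 0.10, collagen = 0.10,
                                        water = 0.03, cell = 0.15),
                         baseline_level = 1.0, noise_level = 0.02,
                         include_cell = FALSE, seed = 1L) {
  tissue_model <- match.arg(tissue_model)
  wavenumber <- check_axis(wavenumber)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 1L)
    stop("phantom needs n_rows >= 2 and n_cols >= 1", call. = FALSE)
  tbl <- tissue_model_table(tissue_model, include_cell)
  if (is.null(pixel_size_um))
    pixel_size_um <- tbl$tissue_depth_mm * 1000 / n_rows
  constituents <- names(components)
  missing_prof <- setdiff(setdiff(constituents, "cell"), names(profiles))
  if (length(missing_prof))
    stop("no profile model for: ", paste(missing_prof, collapse = ", "),
         call. = FALSE)

  nch <- length(wavenumber)
  S <- t(vapply(components, function(m)
    render_component_spectrum(m, wavenumber)$intensity, numeric(nch)))
  rownames(S) <- constituents

  cv_of <- function(nm) {
    if (length(lateral_cv) == 1L && is.null(names(lateral_cv)))
      return(as.numeric(lateral_cv))
    if (nm %in% names(lateral_cv)) return(as.numeric(lateral_cv[[nm]]))
    0
  }

  fields <- with_seed(substream_seed(seed, 1L), {
    out <- list()
    for (nm in constituents) {
      if (nm == "cell") {
        out[[nm]] <- 0.15 * blob_field(n_rows, n_cols, max(cv_of(nm), 0.05))
      } else {
        prof <- make_profile(profiles[[nm]], n_rows, pixel_size_um)
        out[[nm]] <- outer(prof, lateral_factor(n_cols, cv_of(nm)))
      }
    }
    out
  })

  C <- vapply(fields, as.vector, numeric(n_rows * n_cols))  # n_px x k
  clean <- C %*% S
  signal_scale <- mean(clean)

  baseline <- NULL
  if (baseline_level > 0) {
    baseline <- with_seed(substream_seed(seed, 2L), {
      n_px <- n_rows * n_cols
      amp <- baseline_level * signal_scale *
        stats::runif(n_px, 0.7, 1.3)
      tau <- stats::runif(n_px, 800, 1600)
      mix <- stats::runif(n_px, 0.4, 0.8)      # share of exponential term
      x <- (wavenumber - wavenumber[1]) / diff(range(wavenumber))
      # broad per-pixel autofluorescence: exponential decay + gentle quadratic
      B <- matrix(0, n_px, nch)
      ex <- exp(-outer(1 / tau, wavenumber - wavenumber[1]))
      qd <- matrix(rep(1 - 0.6 * x + 0.25 * x^2, each = n_px), n_px, nch)
      B <- amp * (mix * ex + (1 - mix) * qd)
      B
    })
    clean <- clean + baseline
  }

  data <- clean
  if (noise_level > 0) {
    data <- with_seed(substream_seed(seed, 3L), {
      sd_add <- noise_level * signal_scale
      sd_prop <- noise_level * abs(clean)
      clean + matrix(stats::rnorm(length(clean), 0,
                                  sqrt(sd_add^2 + sd_prop^2)),
                     nrow(clean), ncol(clean))
    })
  }

  cube <- hyper_cube(array(data, dim = c(n_rows, n_cols, nch)), wavenumber,
                     pixel_size_um = pixel_size_um)
  truth <- structure(list(
    spectra = S, wavenumber = wavenumber, fields = fields,
    baseline = if (is.null(baseline)) NULL else
      array(baseline, dim = c(n_rows, n_cols, nch)),
    components = components, profiles = profiles,
    tissue_model = tissue_model, ww_mean = tbl$ww_mean,
    pixel_size_um = pixel_size_um,
    params = list(n_rows = n_rows, n_cols = n_cols,
                  baseline_level = baseline_level, noise_level = noise_level,
                  lateral_cv = lateral_cv, include_cell = include_cell),
    seed = as.integer(seed)), class = "phantom_truth")
  list(cube = cube, truth = truth)
}

#' @exportS3Method base::print
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: %s model, %d components, %d x %d px>\n",
              x$tissue_model, nrow(x$spectra), x$params$n_rows,
              x$params$n_cols))
  invisible(x)
}

# ---- simulated sectioned assays ---------------------------------------------

#' Simulate a sectioned biochemical assay from phantom ground truth
#'
#' The tissue depth is divided into `n_sections` equal transverse slabs
#' (8 sections for native cartilage, 4 for engineered and digested tissue
#' in the canonical designs); the per-slab concentration is the mean of the
#' ground-truth field over the slab, scaled to % wet weight by the
#' constituent-specific bulk mean, and perturbed by multiplicative Gaussian
#' noise with coefficient of variation `noise_cv`.
#'
#' @param truth a `phantom_truth` from [make_phantom()].
#' @param n_sections number of depth sections, >= 2 and <= number of rows.
#' @param noise_cv multiplicative noise CV (0 = exact slab means).
#' @param seed integer seed (independent of the phantom substreams).
#' @param constituents which fields to assay (default all but "cell").
#' @return object of class `sectioned_assay`: list with
#'   `section_mid_depths_mm`, `concentrations` (n_sections x constituent
#'   matrix, % wet weight), `n_sections`.
#' @export
sample_assay <- function(truth, n_sections = 8L, noise_cv = 0.075,
                         seed = 1L,
                         constituents = setdiff(names(truth$fields), "cell")) {
  stopifnot(inherits(truth, "phantom_truth"))
  n_sections <- as.integer(n_sections)
  n_rows <- truth$params$n_rows
  if (n_sections < 2L)
    stop("need at least 2 sections", call. = FALSE)
  if (n_sections > n_rows)
    stop("more sections than depth rows", call. = FALSE)
  grp <- cut(seq_len(n_rows), breaks = n_sections, labels = FALSE)
  depths <- row_depths_mm(n_rows, truth$pixel_size_um)
  mids <- as.numeric(tapply(depths, grp, mean))
  conc <- sapply(constituents, function(nm) {
    f <- truth$fields[[nm]]
    slab <- as.numeric(tapply(rowMeans(f), grp, mean))
    scale <- if (nm %in% names(truth$ww_mean))
      truth$ww_mean[[nm]] / mean(f) else 1
    slab * scale
  })
  conc <- matrix(conc, nrow = n_sections,
                 dimnames = list(NULL, constituents))
  if (noise_cv > 0) {
    conc <- with_seed(substream_seed(seed, 4L), {
      pmax(conc * matrix(stats::rnorm(length(conc), 1, noise_cv),
                         nrow(conc), ncol(conc)), 0)
    })
  }
  structure(list(section_mid_depths_mm = mids, concentrations = conc,
                 n_sections = n_sections), class = "sectioned_assay")
}

#' @exportS3Method base::print
print.sectioned_assay <- function(x, ...) {
  cat(sprintf("<sectioned_assay: %d sections, %s>\n", x$n_sections,
              paste(colnames(x$concentrations), collapse = ", ")))
  invisible(x)
}
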
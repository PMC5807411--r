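# Per-pixel autofluorescence baseline estimation and subtraction.
#
# The default estimator is a morphological lower envelope: a rolling-window
# minimum followed by a rolling maximum (a grey-scale opening, which leaves
# broad structure intact while flattening features narrower than the
# window) and a moving-average smooth.  An asymmetric-least-squares
# (Whittaker-smoother) alternative is provided.  Negative residuals after
# subtraction are kept: the non-negativity constraints of the curve
# resolution apply to the factors C and S, not to the data matrix D.

#' Baseline-estimation parameters
#'
#' `window_points` is quoted on a native 3600-channel acquisition axis
#' (one channel per cm-1 over 0-3600 cm-1) and is rescaled in proportion to
#' the actual channel count of the spectrum being processed.
#'
#' @param method "rolling_shape" (morphological lower envelope, default) or
#'   "asymmetric_ls" (Whittaker smoother with asymmetric weights).
#' @param window_points rolling-window width in native channels (>= 3).
#' @param lambda smoothness penalty for `asymmetric_ls` (> 0).
#' @param p asymmetry parameter for `asymmetric_ls` (0 < p < 1); weights
#'   `p` above the fit, `1 - p` below.
#' @param max_iter weight-reassignment iterations for `asymmetric_ls`.
#' @return list of class `baseline_params`.
#' @export
baseline_params <- function(method = c("rolling_shape", "asymmetric_ls"),
                            window_points = 1000L, lambda = 1e6, p = 0.001,
                            max_iter = 10L) {
  method <- match.arg(method)
  if (window_points < 3L) stop("window_points must be >= 3", call. = FALSE)
  if (lambda <= 0 || p <= 0 || p >= 1)
    stop("need lambda > 0 and 0 < p < 1", call. = FALSE)
  structure(list(method = method, window_points = as.integer(window_points),
                 lambda = lambda, p = p, max_iter = as.integer(max_iter)),
            class = "baseline_params")
}

# native channel count the window is quoted on (0-3600 cm-1, 1/cm-1)
.native_channels <- 3600L

effective_window <- function(params, n_channels) {
  w <- max(3L, round(params$window_points * n_channels / .native_channels))
  if (w > n_channels)
    stop(sprintf("baseline window (%d points) exceeds spectrum length (%d)",
                 w, n_channels), call. = FALSE)
  as.integer(w)
}

# reflect each row of M through its endpoints (linear-trend-preserving pad)
pad_reflect <- function(M, h) {
  n <- ncol(M)
  h <- min(h, n - 1L)
  left <- 2 * M[, 1] - M[, (h + 1):2, drop = FALSE]
  right <- 2 * M[, n] - M[, (n - 1):(n - h), drop = FALSE]
  cbind(left, M, right)
}

# rolling min/max over window 2h+1 along the rows of padded matrix
roll_extreme <- function(P, h, n, fun = pmin) {
  out <- P[, (h + 1):(h + n), drop = FALSE]
  for (s in c(-h:-1, 1:h))
    out <- fun(out, P[, (h + 1 + s):(h + n + s), drop = FALSE])
  out
}

roll_mean <- function(M, h) {
  n <- ncol(M)
  P <- pad_reflect(M, h)
  acc <- P[, (h + 1):(h + n), drop = FALSE]
  for (s in c(-h:-1, 1:h))
    acc <- acc + P[, (h + 1 + s):(h + n + s), drop = FALSE]
  acc / (2 * h + 1)
}

# matrix version: one baseline per row of M (pixels x channels)
estimate_baseline_matrix <- function(M, params) {
  n <- ncol(M)
  w <- effective_window(params, n)
  if (params$method == "rolling_shape") {
    h <- max(1L, w %/% 2L)
    P <- pad_reflect(M, h)
    er <- roll_extreme(P, h, n, pmin)           # erosion
    op <- roll_extreme(pad_reflect(er, h), h, n, pmax)  # dilation -> opening
    b <- roll_mean(op, max(1L, h %/% 2L))       # smooth
    # a rolling minimum of a noisy spectrum sits a few noise sigmas below
    # the true envelope; re-center by the lower-quartile gap, which tracks
    # the off-peak offset (and is ~0 for noiseless input) without being
    # pulled up by peak channels
    gap <- M - b
    b + apply(gap, 1, stats::quantile, probs = 0.25, names = FALSE)
  } else {
    t(apply(M, 1, asls_baseline, lambda = params$lambda, p = params$p,
            max_iter = params$max_iter))
  }
}

# Whittaker smoother with asymmetric weights (Eilers-style)
asls_baseline <- function(y, lambda = 1e6, p = 0.001, max_iter = 10L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Estimate the autofluorescence baseline of one spectrum
#'
#' @param spectrum a [raman_spectrum()].
#' @param params a [baseline_params()].
#' @return a [raman_spectrum()] holding the smooth baseline estimate.
#' @export
estimate_baseline <- function(spectrum, params = baseline_params()) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(params, "baseline_params"))
  b <- estimate_baseline_matrix(matrix(spectrum$intensity, nrow = 1), params)
  raman_spectrum(spectrum$wavenumber, as.numeric(b))
}

#' Subtract the per-pixel autofluorescence baseline from a cube
#'
#' Applies [estimate_baseline()] to every pixel spectrum and subtracts it.
#' Small negative residuals are kept (not clipped).
#'
#' @param cube a [hyper_cube()].
#' @param params a [baseline_params()].
#' @return list with elements `cube` (baseline-subtracted [hyper_cube()])
#'   and `baseline` (the estimated baseline as a `hyper_cube`).
#' @export
subtract_baseline <- function(cube, params = baseline_params()) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  M <- flatten_cube(cube)
  B <- estimate_baseline_matrix(M, params)
  out <- hyper_cube(array(M - B, dim = d), cube$wavenumber,
                    pixel_size_um = cube$pixel_size_um,
                    surface_row = cube$surface_row)
  bl <- hyper_cube(array(B, dim = d), cube$wavenumber,
                   pixel_size_um = cube$pixel_size_um,
                   surface_row = cube$surface_row)
  list(cube = out, baseline = bl)
}
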
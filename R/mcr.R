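# Non-negativity-constrained multivariate curve resolution by alternating
# least squares (MCR-ALS).  The bilinear model is D = C S + E, with D the
# pixel-by-channel matrix, C >= 0 the per-pixel component abundances and
# S >= 0 the pure component spectra.  Rows of S are kept at unit Euclidean
# norm to fix the intensity/scale ambiguity; all magnitude lives in C.

# ---- non-negative least squares ---------------------------------------------

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `argmin_x ||A x - b||_2` subject to `x >= 0` exactly (active-set,
#' not projection or clipping).  Zero columns of `A` receive coefficient 0.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol tolerance on the dual (gradient) test.
#' @return numeric coefficient vector of length n.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  x <- numeric(n)
  passive <- logical(n)
  zero_col <- colSums(abs(A)) == 0
  grad <- function(x) {
    w <- as.numeric(crossprod(A, b - A %*% x))
    w[zero_col] <- -Inf
    w
  }
  w <- grad(x)
  gtol <- tol * max(1, sum(abs(crossprod(A, b))))
  it <- 0L
  max_outer <- 30L * n + 30L
  while (it < max_outer && any(!passive & w > gtol)) {
    it <- it + 1L
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- numeric(n)
      zi <- qr.coef(qr(A[, idx, drop = FALSE]), b)
      zi[is.na(zi)] <- 0
      z[idx] <- zi
      if (all(z[idx] >= 0)) { x <- z; break }
      neg <- idx[z[idx] < 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- grad(x)
  }
  pmax(x, 0)
}

# Exact NNLS for many right-hand sides sharing one design matrix.
# For k = ncol(A) small, the optimum's support is one of the 2^k subsets;
# the restricted unconstrained LS solution on the true support satisfies
# the KKT conditions and is feasible, so picking the feasible candidate
# with the smallest residual over all subsets is exact.  Works entirely on
# the k x k normal equations, so the cost per subset is independent of the
# number of rows and right-hand sides beyond two precomputed cross
# products.
nnls_multi <- function(A, B, tol = 1e-9) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- ncol(A); nrhs <- ncol(B)
  if (k > 12L)
    stop("support enumeration limited to k <= 12 components", call. = FALSE)
  G <- crossprod(A)                  # k x k
  H <- crossprod(A, B)               # k x nrhs
  bb <- colSums(B^2)
  X <- matrix(0, k, nrhs)
  best <- bb                         # empty support
  subsets <- lapply(seq_len(2^k - 1L), function(code)
    which(bitwAnd(code, bitwShiftL(1L, 0:(k - 1L))) > 0L))
  subsets <- subsets[order(lengths(subsets))]
  for (T in subsets) {
    GT <- G[T, T, drop = FALSE]
    ch <- tryCatch(chol(GT), error = function(e) NULL)
    if (is.null(ch) ||
        any(diag(ch) <= sqrt(.Machine$double.eps) * sqrt(max(diag(GT)))))
      next                            # (near-)singular support
    XT <- backsolve(ch, forwardsolve(t(ch), H[T, , drop = FALSE]))
    XT <- matrix(XT, nrow = length(T))
    sc <- pmax(1, apply(abs(XT), 2, max))
    feas_idx <- which(colSums(XT < -tol * rep(sc, each = nrow(XT))) == 0L)
    if (!length(feas_idx)) next
    XT[XT < 0] <- 0
    # at the restricted LS solution, ||B - A_T x||^2 = bb - x' H_T
    obj <- bb[feas_idx] -
      colSums(XT[, feas_idx, drop = FALSE] * H[T, feas_idx, drop = FALSE])
    imp <- obj < best[feas_idx] - tol * pmax(1, best[feas_idx])
    win <- feas_idx[imp]
    if (length(win)) {
      X[, win] <- 0
      X[T, win] <- XT[, win, drop = FALSE]
      best[win] <- obj[imp]
    }
  }
  X
}

# ---- component containers ---------------------------------------------------

#' Construct a set of component spectra
#'
#' @param spectra k x n_channels non-negative matrix S.
#' @param wavenumber axis in cm-1, length n_channels.
#' @param names component labels (default from rownames).
#' @return object of class `component_spectra`.
#' @export
component_spectra <- function(spectra, wavenumber, names = rownames(spectra)) {
  spectra <- as.matrix(spectra)
  wavenumber <- check_axis(wavenumber)
  if (ncol(spectra) != length(wavenumber))
    stop("spectra columns must match axis length", call. = FALSE)
  if (any(spectra < 0))
    stop("component spectra must be non-negative", call. = FALSE)
  if (is.null(names)) names <- paste0("component_", seq_len(nrow(spectra)))
  rownames(spectra) <- names
  structure(list(spectra = spectra, wavenumber = wavenumber, names = names),
            class = "component_spectra")
}

#' @exportS3Method base::print
print.component_spectra <- function(x, ...) {
  cat(sprintf("<component_spectra: %d components [%s], %d channels>\n",
              nrow(x$spectra), paste(x$names, collapse = ", "),
              length(x$wavenumber)))
  invisible(x)
}

# ---- initialization ---------------------------------------------------------

#' Initialize component spectra from the data matrix
#'
#' All methods are deterministic given their inputs (and, for
#' `seeded_random`, the seed):
#'
#' * `purest_channel` (default): selects k maximally mutually dissimilar
#'   *channels* in the SIMPLISMA purest-variable spirit (greedy
#'   maximization of the orthogonal residual of the unit-normalized channel
#'   profiles), takes the corresponding abundance images `D[, channels]` as
#'   the initial concentration estimate, and returns the non-negative
#'   least-squares spectra solved against them.  Because well-resolved
#'   Raman peaks give each constituent nearly pure channels even when no
#'   pixel is spectrally pure, this start is the most reliable for tissue
#'   images.
#' * `purest_pixel`: picks maximally mutually dissimilar pixel spectra
#'   (first the most intense pixel, then greedy orthogonal-residual
#'   maximization).
#' * `seeded_random`: random pixel spectra drawn reproducibly from `seed`.
#'
#' @param D pixel x channel matrix.
#' @param k number of components, `1 <= k <= min(dim(D))`.
#' @param method "purest_channel", "purest_pixel" or "seeded_random".
#' @param seed integer seed for `seeded_random`.
#' @param wavenumber optional axis for the returned object (defaults to
#'   channel index if missing).
#' @return a [component_spectra()] with k unit-norm non-negative rows.
#' @export
init_components <- function(D, k, method = c("purest_channel", "purest_pixel",
                                             "seeded_random"),
                            seed = 1L, wavenumber = NULL) {
  method <- match.arg(method)
  D <- as.matrix(D)
  if (k < 1L || k > min(dim(D)))
    stop("k must be between 1 and min(dim(D))", call. = FALSE)
  if (is.null(wavenumber)) wavenumber <- seq_len(ncol(D))
  if (method == "purest_channel") {
    cn <- sqrt(colSums(D^2))
    cn[cn == 0] <- 1
    Dn <- sweep(D, 2, cn, `/`)
    sel <- which.max(colSums(D^2))
    if (k > 1L) {
      basis <- Dn[, sel, drop = FALSE]
      for (i in 2:k) {
        res <- 1 - colSums(crossprod(basis, Dn)^2)
        res[sel] <- -Inf
        sel <- c(sel, which.max(res))
        v <- Dn[, sel[i]] - basis %*% crossprod(basis, Dn[, sel[i]])
        nv <- sqrt(sum(v^2))
        basis <- cbind(basis, if (nv > 0) v / nv else 0)
      }
    }
    C0 <- pmax(D[, sel, drop = FALSE], 0)
    S <- nnls_multi(C0, D)
    nrm <- sqrt(rowSums(S^2))
    nrm[nrm == 0] <- 1
    return(component_spectra(S / nrm, wavenumber,
                             names = paste0("component_", seq_len(k))))
  }
  if (method == "purest_pixel") {
    norms <- sqrt(rowSums(D^2))
    sel <- which.max(norms)
    if (k > 1L) {
      basis <- D[sel, , drop = FALSE] / norms[sel]  # orthonormal rows
      for (i in 2:k) {
        # squared residual of each pixel after projection onto span(basis)
        P <- D %*% t(basis)                 # n_px x (i-1) coefficients
        res <- rowSums(D^2) - rowSums(P^2)
        res[sel] <- -Inf
        sel <- c(sel, which.max(res))
        v <- D[sel[i], ] -
          as.numeric(crossprod(basis, basis %*% D[sel[i], ]))
        nv <- sqrt(sum(v^2))
        basis <- rbind(basis, if (nv > 0) v / nv else 0)
      }
    }
  } else {
    sel <- with_seed(seed, sample.int(nrow(D), k))
  }
  S <- D[sel, , drop = FALSE]
  S[S < 0] <- 0
  nrm <- sqrt(rowSums(S^2))
  nrm[nrm == 0] <- 1
  S <- S / nrm
  component_spectra(S, wavenumber,
                    names = paste0("component_", seq_len(k)))
}

# ---- the ALS fit ------------------------------------------------------------

#' Fit a non-negativity-constrained MCR-ALS model
#'
#' Alternates exact non-negative least-squares solves of C given S (per
#' pixel) and of S given C (per channel), renormalizing the rows of S to
#' unit norm (with the inverse rescaling absorbed into C) after each S
#' update.  Iteration stops when the relative change of the residual
#' Frobenius norm falls below `tol` or after `max_iter` iterations.
#'
#' Multiple images may be fitted jointly by passing a list of cubes: their
#' pixel matrices are stacked into one D, a single S is resolved, and
#' per-cube concentration maps are returned.
#'
#' @param x a [hyper_cube()] or a list of them.
#' @param k number of components (default 4: collagen, GAG, water and a
#'   cellular residual in the canonical cartilage model).
#' @param fit_range wavenumber interval used for the fit (default the
#'   fingerprint range, 800-1800 cm-1); `NULL` fits the full axis.
#' @param tol relative residual-change convergence tolerance.
#' @param max_iter maximum number of ALS iterations.
#' @param init initialization method, see [init_components()].
#' @param seed seed for `init = "seeded_random"`.
#' @return object of class `mcr_fit`: `S` ([component_spectra()]),
#'   `C` (pixel x k matrix), `maps` (named list of depth x lateral
#'   matrices; a list of such lists when several cubes were fitted),
#'   `explained_variance_total` and `explained_variance_per_component`
#'   (percent), `n_iterations`, `converged`, `residual_norm`,
#'   `residual_history`.
#' @export
fit_mcr <- function(x, k = 4L, fit_range = c(800, 1800), tol = 1e-6,
                    max_iter = 200L,
                    init = c("purest_channel", "purest_pixel",
                             "seeded_random"),
                    seed = 1L) {
  init <- match.arg(init)
  cubes <- if (inherits(x, "hyper_cube")) list(x) else x
  stopifnot(length(cubes) >= 1L,
            all(vapply(cubes, inherits, logical(1), "hyper_cube")))
  if (!is.null(fit_range))
    cubes <- lapply(cubes, crop_range, lo = fit_range[1], hi = fit_range[2])
  wn <- cubes[[1]]$wavenumber
  for (cb in cubes[-1])
    if (!isTRUE(all.equal(cb$wavenumber, wn)))
      stop("all cubes must share one wavenumber axis", call. = FALSE)
  Ds <- lapply(cubes, flatten_cube)
  D <- do.call(rbind, Ds)
  if (anyNA(D) || any(!is.finite(D)))
    stop("non-finite intensities in D", call. = FALSE)

  S <- init_components(D, k, method = init, seed = seed, wavenumber = wn)$spectra
  d2 <- sum(D^2)
  res_hist <- numeric(0)
  res_prev <- Inf
  converged <- FALSE
  iter <- 0L
  C <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    C <- t(nnls_multi(t(S), t(D)))          # pixels x k
    St <- nnls_multi(C, D)                  # k x channels
    # guard against dead components (all-zero spectrum): re-seed from the
    # worst-reconstructed pixel spectrum
    dead <- rowSums(St^2) == 0
    if (any(dead)) {
      R <- D - C %*% St
      worst <- which.max(rowSums(R^2))
      for (j in which(dead)) St[j, ] <- pmax(D[worst, ], 0)
    }
    nrm <- sqrt(rowSums(St^2))
    S <- St / nrm
    C <- sweep(C, 2, nrm, `*`)
    res <- sqrt(sum((D - C %*% S)^2))
    res_hist <- c(res_hist, res)
    if (res^2 <= 1e-20 * d2) { converged <- TRUE; break }  # exact fit
    if (is.finite(res_prev)) {
      rel <- abs(res_prev - res) / max(res_prev, .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    res_prev <- res
  }
  if (!converged)
    warning(sprintf("MCR-ALS did not converge in %d iterations", iter))
  # final C consistent with the final S
  C <- t(nnls_multi(t(S), t(D)))
  res <- sqrt(sum((D - C %*% S)^2))

  ev_total <- 100 * (1 - res^2 / d2)
  ev_comp <- vapply(seq_len(k), function(j)
    100 * sum((C[, j, drop = FALSE] %*% S[j, , drop = FALSE])^2) / d2,
    numeric(1))
  names(ev_comp) <- rownames(S)

  # split C back into per-cube maps
  split_maps <- function(Cmat, cube) {
    d <- dim(cube$data)
    out <- lapply(seq_len(ncol(Cmat)), function(j)
      unflatten_matrix(Cmat[, j], d[1], d[2]))
    names(out) <- rownames(S)
    out
  }
  offsets <- cumsum(c(0L, vapply(Ds, nrow, integer(1))))
  maps <- lapply(seq_along(cubes), function(i)
    split_maps(C[(offsets[i] + 1L):offsets[i + 1L], , drop = FALSE],
               cubes[[i]]))
  if (length(cubes) == 1L) maps <- maps[[1]]

  structure(list(
    S = component_spectra(S, wn),
    C = C, maps = maps,
    pixel_size_um = cubes[[1]]$pixel_size_um,
    explained_variance_total = ev_total,
    explained_variance_per_component = ev_comp,
    n_iterations = iter, converged = converged,
    residual_norm = res, residual_history = res_hist),
    class = "mcr_fit")
}

#' @exportS3Method base::print
print.mcr_fit <- function(x, ...) {
  cat(sprintf(
    "<mcr_fit: %d components, %d iterations (%s), explained variance %.2f%%>\n",
    nrow(x$S$spectra), x$n_iterations,
    if (x$converged) "converged" else "not converged",
    x$explained_variance_total))
  invisible(x)
}

# ---- degenerate-component merging -------------------------------------------

#' Merge spectrally degenerate components
#'
#' Components whose pure spectra correlate with Pearson r at or above
#' `r_threshold` are grouped by transitive closure and summed: the merged
#' concentration map is the elementwise sum, the merged spectrum the
#' concentration-weighted mean renormalized to unit norm.  Typical use is
#' collapsing orientation-split collagen components into one.
#'
#' @param fit an `mcr_fit`.
#' @param r_threshold Pearson correlation threshold (default 0.9).
#' @return an `mcr_fit` with possibly fewer components.
#' @export
merge_degenerate <- function(fit, r_threshold = 0.9) {
  stopifnot(inherits(fit, "mcr_fit"))
  S <- fit$S$spectra
  k <- nrow(S)
  if (k < 2L) return(fit)
  R <- suppressWarnings(stats::cor(t(S)))
  R[!is.finite(R)] <- 0
  # union-find transitive closure
  grp <- seq_len(k)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    if (R[i, j] >= r_threshold) grp[find(j)] <- find(i)
  grp <- vapply(seq_len(k), find, integer(1))
  groups <- split(seq_len(k), grp)
  if (length(groups) == k) return(fit)

  w <- colSums(fit$C)                       # total abundance weights
  Snew <- matrix(0, length(groups), ncol(S))
  Cnew <- matrix(0, nrow(fit$C), length(groups))
  nms <- character(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    wg <- w[idx]; if (sum(wg) == 0) wg <- rep(1, length(idx))
    s <- colSums(S[idx, , drop = FALSE] * wg) / sum(wg)
    Snew[g, ] <- s / sqrt(sum(s^2))
    Cnew[, g] <- rowSums(fit$C[, idx, drop = FALSE])
    nms[g] <- paste(rownames(S)[idx], collapse = "+")
  }
  out <- fit
  out$S <- component_spectra(Snew, fit$S$wavenumber, names = nms)
  out$C <- Cnew
  remap <- function(maps) {
    res <- lapply(groups, function(idx) Reduce(`+`, maps[idx]))
    names(res) <- nms
    res
  }
  if (is.list(fit$maps) && inherits(fit$maps[[1]], "matrix")) {
    out$maps <- remap(fit$maps)
  } else {
    out$maps <- lapply(fit$maps, remap)
  }
  ev <- vapply(groups, function(idx)
    sum(fit$explained_variance_per_component[idx]), numeric(1))
  names(ev) <- nms
  out$explained_variance_per_component <- ev
  out
}

# ---- reference matching -----------------------------------------------------

#' Match resolved components against reference spectra
#'
#' Finds the one-to-one assignment between resolved and reference spectra
#' that maximizes the total Pearson correlation (exhaustive over
#' assignments; k is small).  References on a different axis are resampled
#' onto the component axis by linear interpolation.  When there are more
#' components than references, unmatched components are labelled
#' `"residual"`.
#'
#' @param S resolved [component_spectra()].
#' @param refs reference [component_spectra()].
#' @return list with `assignment` (data.frame: component, reference, r,
#'   r_squared) and `S` (the input with components renamed to their matched
#'   reference, unmatched ones to "residual").
#' @export
match_references <- function(S, refs) {
  stopifnot(inherits(S, "component_spectra"),
            inherits(refs, "component_spectra"))
  Rm <- refs$spectra
  if (!isTRUE(all.equal(refs$wavenumber, S$wavenumber))) {
    Rm <- t(apply(refs$spectra, 1, function(y)
      stats::approx(refs$wavenumber, y, xout = S$wavenumber, rule = 2)$y))
  }
  kS <- nrow(S$spectra); kR <- nrow(Rm)
  corm <- matrix(NA_real_, kS, kR)
  for (i in seq_len(kS)) for (j in seq_len(kR))
    corm[i, j] <- suppressWarnings(stats::cor(S$spectra[i, ], Rm[j, ]))
  corm[!is.finite(corm)] <- -1

  # exhaustive assignment: choose which components get a reference and in
  # what order (k is small throughout)
  n_assign <- min(kS, kR)
  comps <- utils::combn(kS, n_assign, simplify = FALSE)
  best <- NULL; best_val <- -Inf
  perm_all <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm_all(v[-i]), function(p) c(v[i], p))))
  }
  ref_perms <- perm_all(seq_len(kR))
  for (cs in comps) {
    for (rp in ref_perms) {
      rp <- rp[seq_len(n_assign)]
      val <- sum(corm[cbind(cs, rp)])
      if (val > best_val) { best_val <- val; best <- cbind(cs, rp) }
    }
  }
  assignment <- data.frame(
    component = S$names[best[, 1]],
    reference = refs$names[best[, 2]],
    r = corm[best],
    r_squared = corm[best]^2,
    stringsAsFactors = FALSE)
  new_names <- S$names
  new_names[best[, 1]] <- refs$names[best[, 2]]
  new_names[setdiff(seq_len(kS), best[, 1])] <- "residual"
  out <- component_spectra(S$spectra, S$wavenumber, names = new_names)
  list(assignment = assignment, S = out)
}
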
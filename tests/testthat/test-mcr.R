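test_that("nnls_solve handles the canonical edge cases", {
  # b inside the non-negative cone: constraint inactive
  A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  x_true <- c(2, 3)
  b <- A %*% x_true
  expect_equal(nnls_solve(A, as.numeric(b)), x_true, tolerance = 1e-10)

  # fully active constraint
  expect_equal(nnls_solve(matrix(c(1, 0), 2, 1), c(-1, 0)), 0)

  # zero column gets coefficient zero
  A0 <- cbind(c(1, 1), c(0, 0))
  x <- nnls_solve(A0, c(1, 2))
  expect_equal(x[2], 0)
  expect_equal(x[1], 1.5, tolerance = 1e-10)
})

test_that("nnls_solve and nnls_multi agree with a brute-force orthant search", {
  set.seed(42)
  for (i in 1:30) {
    m <- sample(3:4, 1); n <- sample(2:3, 1)
    if (n >= m) n <- m - 1L            # overdetermined: unique optimum
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    x_as <- nnls_solve(A, b)
    x_en <- as.vector(ramanECM:::nnls_multi(A, matrix(b)))
    x_gr <- grid_nnls(A, b)
    expect_lt(max(abs(x_as - x_gr)), 1e-6)
    expect_lt(max(abs(x_en - x_gr)), 1e-6)
  }
})

test_that("nnls_solve agrees with an independent library implementation", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (i in 1:50) {
    m <- sample(3:8, 1); n <- sample(1:(m - 1), 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    expect_equal(nnls_solve(A, b), pracma::lsqnonneg(A, b)$x,
                 tolerance = 1e-8)
  }
})

test_that("nnls_multi solves many right-hand sides like nnls_solve", {
  set.seed(11)
  A <- matrix(abs(rnorm(40 * 4)), 40, 4)
  B <- matrix(rnorm(40 * 25), 40, 25)
  X <- ramanECM:::nnls_multi(A, B)
  for (j in seq_len(25))
    expect_equal(X[, j], nnls_solve(A, B[, j]), tolerance = 1e-8)
})

test_that("initialization is deterministic and selects dissimilar spectra", {
  ph <- clean_phantom()
  D <- flatten_cube(crop_range(ph$cube, 800, 1800))
  # k = 1 purest pixel: the most intense pixel spectrum, unit norm
  S1 <- init_components(D, 1, method = "purest_pixel")
  i_max <- which.max(sqrt(rowSums(D^2)))
  expect_equal(as.numeric(S1$spectra),
               D[i_max, ] / sqrt(sum(D[i_max, ]^2)), tolerance = 1e-12)

  for (m in c("purest_channel", "purest_pixel", "seeded_random")) {
    a <- init_components(D, 3, method = m, seed = 4L)
    b <- init_components(D, 3, method = m, seed = 4L)
    expect_identical(a$spectra, b$spectra)
    expect_true(all(abs(sqrt(rowSums(a$spectra^2)) - 1) < 1e-12))
    expect_true(all(a$spectra >= 0))
  }

  # on a separated noiseless phantom each initial spectrum correlates with
  # a distinct true component
  S3 <- init_components(D, 3, method = "purest_channel")
  sel <- ph$truth$wavenumber >= 800 & ph$truth$wavenumber <= 1800
  cm <- abs(cor(t(S3$spectra), t(ph$truth$spectra[, sel])))
  best <- unname(apply(cm, 1, which.max))
  expect_equal(sort(best), 1:3)          # one distinct component each
  expect_true(all(apply(cm, 1, max) > 0.8))
})

test_that("fit_mcr factorizes an exact rank-1 matrix", {
  set.seed(3)
  wn <- seq(800, 1800, by = 10)
  c_true <- abs(rnorm(30)) + 0.1
  s_true <- abs(sin(seq_len(length(wn)))) + 0.1
  D <- outer(c_true, s_true)
  cube <- hyper_cube(array(D, c(6, 5, length(wn))), wn)
  fit <- fit_mcr(cube, k = 1, fit_range = NULL)
  recon <- fit$C %*% fit$S$spectra
  expect_lt(sqrt(sum((recon - D)^2)) / sqrt(sum(D^2)), 1e-8)
  expect_gt(fit$explained_variance_total, 99.99)
})

test_that("fit_mcr recovers a noiseless separated 3-component phantom", {
  ph <- clean_phantom()
  fit <- fit_mcr(ph$cube, k = 3)
  m <- match_to_truth(fit, ph$truth)
  expect_true(all(m$assignment$r_squared > 0.98))
  for (i in seq_len(3)) {
    j <- which(fit$S$names == m$assignment$component[i])[1]
    r <- cor(as.vector(fit$maps[[j]]),
             as.vector(ph$truth$fields[[m$assignment$reference[i]]]))
    expect_gt(r, 0.99)
  }
})

test_that("the ALS residual norm is non-increasing", {
  ph <- noisy_phantom()
  fit <- suppressWarnings(fit_mcr(ph$cube, k = 3, max_iter = 60))
  expect_true(all(diff(fit$residual_history) <= 1e-8 *
                    fit$residual_history[-length(fit$residual_history)]))
})

test_that("explained variance is consistent and bounded", {
  ph <- noisy_phantom()
  fit <- suppressWarnings(fit_mcr(ph$cube, k = 3, max_iter = 60))
  expect_gte(fit$explained_variance_total, 0)
  expect_lte(fit$explained_variance_total, 100)
  expect_true(all(fit$explained_variance_per_component >= 0))
})

test_that("rescaling D rescales the reconstruction exactly", {
  ph <- clean_phantom()
  f1 <- fit_mcr(ph$cube, k = 3, max_iter = 80)
  cube2 <- hyper_cube(ph$cube$data * 7.3, ph$cube$wavenumber,
                      pixel_size_um = ph$cube$pixel_size_um)
  f2 <- fit_mcr(cube2, k = 3, max_iter = 80)
  r1 <- f1$C %*% f1$S$spectra
  r2 <- f2$C %*% f2$S$spectra
  expect_lt(sqrt(sum((r2 - 7.3 * r1)^2)) / sqrt(sum((7.3 * r1)^2)), 1e-5)
})

test_that("converged abundances equal per-pixel NNLS against the final S", {
  set.seed(8)
  wn <- seq(1000, 1700, by = 100)
  D <- matrix(abs(rnorm(6 * 8)), 6, 8)
  cube <- hyper_cube(array(D, c(3, 2, 8)), wn)
  fit <- suppressWarnings(fit_mcr(cube, k = 2, fit_range = NULL))
  for (p in seq_len(6))
    expect_equal(fit$C[p, ], nnls_solve(t(fit$S$spectra), D[p, ]),
                 tolerance = 1e-9)
})

test_that("merging a duplicated component preserves the reconstruction", {
  ph <- clean_phantom()
  fit <- fit_mcr(ph$cube, k = 3, max_iter = 80)
  # duplicate component 1 with its abundance split between the copies
  S2 <- rbind(fit$S$spectra, fit$S$spectra[1, ])
  C2 <- cbind(fit$C, fit$C[, 1] * 0.4)
  C2[, 1] <- fit$C[, 1] * 0.6
  dup <- fit
  dup$S <- component_spectra(S2, fit$S$wavenumber,
                             names = c(fit$S$names, "dup"))
  dup$C <- C2
  d <- dim(ph$cube$data)
  dup$maps <- lapply(seq_len(4), function(j)
    unflatten_matrix(C2[, j], d[1], d[2]))
  names(dup$maps) <- dup$S$names
  dup$explained_variance_per_component <-
    c(fit$explained_variance_per_component, 0)

  merged <- merge_degenerate(dup, r_threshold = 0.9)
  expect_equal(nrow(merged$S$spectra), 3)
  pre <- C2 %*% S2
  post <- merged$C %*% merged$S$spectra
  expect_lt(sqrt(sum((post - pre)^2)) / sqrt(sum(pre^2)), 1e-10)
  # merged map is exactly the sum of the duplicate maps
  g <- grep("\\+", merged$S$names)
  expect_equal(merged$C[, g], C2[, 1] + C2[, 4], tolerance = 1e-12)
})

test_that("merge_degenerate is a no-op below threshold", {
  ph <- clean_phantom()
  fit <- fit_mcr(ph$cube, k = 3, max_iter = 80)
  m <- merge_degenerate(fit, r_threshold = 0.9)
  expect_identical(m$S$spectra, fit$S$spectra)
})

test_that("match_references recovers identity and permutations", {
  wn <- seq(800, 1800, by = 10)
  S <- component_spectra(rbind(
    exp(-0.5 * ((wn - 1061) / 15)^2),
    exp(-0.5 * ((wn - 1450) / 15)^2),
    exp(-0.5 * ((wn - 1245) / 15)^2)), wn, names = c("a", "b", "c"))
  self <- match_references(S, S)
  expect_true(all(self$assignment$r_squared > 1 - 1e-12))
  expect_equal(self$assignment$component, self$assignment$reference)

  # shuffled disjoint-support references: exact permutation recovery,
  # verified against an exhaustive search over all 6 assignments
  refs <- component_spectra(S$spectra[c(3, 1, 2), ], wn,
                            names = c("c", "a", "b"))
  m <- match_references(S, refs)
  expect_equal(m$assignment$reference[match(c("a", "b", "c"),
                                            m$assignment$component)],
               c("a", "b", "c"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  scores <- vapply(perms, function(p)
    sum(diag(cor(t(S$spectra), t(refs$spectra[p, , drop = FALSE])))),
    numeric(1))
  expect_equal(sum(m$assignment$r), max(scores), tolerance = 1e-12)

  # more components than references: leftovers become "residual"
  refs2 <- component_spectra(S$spectra[1:2, ], wn, names = c("a", "b"))
  m2 <- match_references(S, refs2)
  expect_true("residual" %in% m2$S$names)
})

test_that("fitting a list of cubes shares S and splits the maps", {
  ph1 <- make_phantom("native", n_rows = 14, n_cols = 5,
                      wavenumber = test_axis(16),
                      profiles = separated_profiles(),
                      baseline_level = 0, noise_level = 0, seed = 61L)
  ph2 <- make_phantom("digested", n_rows = 10, n_cols = 7,
                      wavenumber = test_axis(16),
                      baseline_level = 0, noise_level = 0, seed = 62L)
  fit <- suppressWarnings(fit_mcr(list(ph1$cube, ph2$cube), k = 3,
                                  max_iter = 120))
  expect_length(fit$maps, 2)
  expect_equal(dim(fit$maps[[1]][[1]]), c(14, 5))
  expect_equal(dim(fit$maps[[2]][[1]]), c(10, 7))
  expect_equal(nrow(fit$C), 14 * 5 + 10 * 7)
})
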
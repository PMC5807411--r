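test_that("rendered component spectra peak at the canonical assignments", {
  wn <- seq(600, 3600, by = 2)
  gag <- render_component_spectrum(default_components()$GAG, wn)
  expect_lt(abs(wn[which.max(gag$intensity)] - 1061), 2 + 1e-9)

  col <- render_component_spectrum(default_components()$collagen,
                                   seq(600, 3600, by = 1))
  local_max <- function(s, center, halfwidth = 30) {
    sel <- which(abs(s$wavenumber - center) <= halfwidth)
    i <- sel[which.max(s$intensity[sel])]
    # a genuine local maximum, not a shoulder
    s$intensity[i] > s$intensity[i - 1] && s$intensity[i] > s$intensity[i + 1]
  }
  expect_true(local_max(col, 1245))
  expect_true(local_max(col, 1450))

  # single unit-amplitude Gaussian evaluates to its amplitude at the mode
  one <- component_model("x", list(peak_spec(1000, 10, 1)))
  s <- render_component_spectrum(one, seq(900, 1100, by = 1))
  expect_equal(max(s$intensity), 1, tolerance = 1e-12)
  expect_error(component_model("empty", list()), "at least one peak")
})

test_that("make_profile respects shape, endpoints and monotonicity", {
  native <- default_profiles("native")
  p <- make_profile(native$GAG, 50, 70)
  expect_true(all(diff(p) > 0))                 # increasing from surface
  expect_equal(p[1], native$GAG$value_at_surface)
  expect_equal(p[50], native$GAG$value_at_depth)

  eng <- default_profiles("engineered")
  expect_true(all(diff(make_profile(eng$GAG, 50, 64)) < 0))  # decreasing

  cst <- profile_model("w", "constant", 1, 1)
  expect_equal(make_profile(cst, 7, 10), rep(1, 7))
  expect_error(profile_model("w", "constant", 1, 2), "equal endpoint")
})

test_that("noiseless phantom is an exact bilinear mixture", {
  ph <- clean_phantom()
  D <- flatten_cube(ph$cube)
  C <- vapply(ph$truth$fields, as.vector, numeric(nrow(D)))
  recon <- C %*% ph$truth$spectra
  expect_lt(max(abs(D - recon)), 1e-10)
})

test_that("unconstrained least squares against the true spectra recovers
           the true concentrations on noiseless data", {
  ph <- clean_phantom()
  D <- flatten_cube(ph$cube)
  S <- ph$truth$spectra
  C_hat <- t(qr.solve(S %*% t(S), S %*% t(D)))
  C_true <- vapply(ph$truth$fields, as.vector, numeric(nrow(D)))
  expect_lt(max(abs(C_hat - C_true)), 1e-8)
})

test_that("phantom generation is deterministic given the seed", {
  a <- make_phantom("native", n_rows = 12, n_cols = 6,
                    wavenumber = test_axis(16), seed = 5L)
  b <- make_phantom("native", n_rows = 12, n_cols = 6,
                    wavenumber = test_axis(16), seed = 5L)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$truth$fields, b$truth$fields)
  d <- make_phantom("native", n_rows = 12, n_cols = 6,
                    wavenumber = test_axis(16), seed = 6L)
  expect_false(identical(a$cube$data, d$cube$data))
})

test_that("tissue-model fields carry the documented depth signatures", {
  nat <- make_phantom("native", n_rows = 30, n_cols = 8,
                      wavenumber = test_axis(16), seed = 3L)$truth$fields
  # non-decreasing GAG/collagen at every lateral position
  expect_true(all(apply(nat$GAG, 2, function(v) all(diff(v) >= 0))))
  expect_true(all(apply(nat$collagen, 2, function(v) all(diff(v) >= 0))))
  expect_true(all(apply(nat$water, 2, function(v) all(diff(v) <= 0))))

  eng <- make_phantom("engineered", n_rows = 30, n_cols = 8,
                      wavenumber = test_axis(16), seed = 3L)$truth$fields
  expect_true(all(apply(eng$GAG, 2, function(v) all(diff(v) <= 0))))
  expect_true(all(apply(eng$collagen, 2, function(v) all(diff(v) <= 0))))

  dig <- make_phantom("digested", n_rows = 30, n_cols = 8,
                      wavenumber = test_axis(16), seed = 3L)$truth$fields
  expect_true(all(apply(dig$collagen, 2, function(v)
    max(v) - min(v) < 1e-12)))                   # uniform collagen
  expect_true(all(apply(dig$GAG, 2, function(v) all(diff(v) >= 0))))
})

test_that("native water profile drops 12.5 % between 0.1 and 2.5 mm", {
  ph <- make_phantom("native", n_rows = 70, n_cols = 4,
                     wavenumber = test_axis(16), noise_level = 0,
                     baseline_level = 0, lateral_cv = 0, seed = 1L)
  prof <- rowMeans(ph$truth$fields$water)
  d <- row_depths_mm(70, ph$cube$pixel_size_um)
  v <- stats::approx(d, prof, xout = c(0.1, 2.5))$y
  expect_equal(100 * (v[1] - v[2]) / v[1], 12.5, tolerance = 0.02)
})

test_that("sectioned assays average slabs exactly when noiseless", {
  ph <- clean_phantom()
  a0 <- sample_assay(ph$truth, n_sections = 8, noise_cv = 0, seed = 1L)
  expect_equal(a0$n_sections, 8)
  expect_equal(nrow(a0$concentrations), 8)
  expect_true(all(diff(a0$section_mid_depths_mm) > 0))
  # slab means computed independently
  grp <- cut(seq_len(40), 8, labels = FALSE)
  f <- ph$truth$fields$GAG
  slab <- as.numeric(tapply(rowMeans(f), grp, mean))
  scale <- ph$truth$ww_mean[["GAG"]] / mean(f)
  expect_equal(unname(a0$concentrations[, "GAG"]), slab * scale,
               tolerance = 1e-12)

  # constant field -> equal sections
  dig <- make_phantom("digested", n_rows = 24, n_cols = 6,
                      wavenumber = test_axis(16), lateral_cv = 0, seed = 2L)
  ad <- sample_assay(dig$truth, n_sections = 4, noise_cv = 0, seed = 1L)
  expect_lt(diff(range(ad$concentrations[, "collagen"])), 1e-10)

  expect_error(sample_assay(ph$truth, n_sections = 1), "at least 2")
  expect_error(sample_assay(ph$truth, n_sections = 400), "more sections")
  # determinism of the noisy assay
  a1 <- sample_assay(ph$truth, 8, noise_cv = 0.075, seed = 9L)
  a2 <- sample_assay(ph$truth, 8, noise_cv = 0.075, seed = 9L)
  expect_identical(a1$concentrations, a2$concentrations)
})
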
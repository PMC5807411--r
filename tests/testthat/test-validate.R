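test_that("pair_profiles interpolates the profile at section mid-depths", {
  prof <- depth_profile(c(0, 1), c(0, 10), constituent = "GAG")
  assay <- list(section_mid_depths_mm = c(0.25, 0.5, 1),
                concentrations = c(2, 4, 9))
  pp <- pair_profiles(prof, assay)
  expect_equal(pp$raman_value, c(2.5, 5, 10))
  expect_equal(pp$assay_value, c(2, 4, 9))

  # coinciding depths need no interpolation
  prof2 <- depth_profile(c(0.5, 1.5, 2.5), c(3, 6, 9), constituent = "x")
  pp2 <- pair_profiles(prof2, list(section_mid_depths_mm = c(0.5, 2.5),
                                   concentrations = c(1, 2)))
  expect_equal(pp2$raman_value, c(3, 9))

  expect_error(pair_profiles(prof, list(section_mid_depths_mm = 1,
                                        concentrations = 2)),
               "at least 2")
  expect_warning(pair_profiles(prof, list(
    section_mid_depths_mm = c(0.5, 2), concentrations = c(1, 2))), "clamped")
})

test_that("r_squared and rmsep match their closed forms", {
  x <- c(1, 2, 3)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, c(1, 3, 2)), 0.25)
  expect_equal(rmsep(c(1, 1), c(1, 3)), 100 * sqrt(2) / 2)
  expect_equal(round(rmsep(c(1, 1), c(1, 3)), 2), 70.71)
  expect_equal(rmsep(c(2, 4, 6), c(2, 4, 6)), 0)

  # both are invariant to common positive rescaling
  set.seed(2)
  a <- runif(8) + 1; b <- runif(8) + 1
  expect_equal(r_squared(3 * a, 3 * b), r_squared(a, b))
  expect_equal(rmsep(5 * a, 5 * b), rmsep(a, b), tolerance = 1e-12)

  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(c(1, 2), c(1, 2)), "at least 3")
  expect_error(rmsep(c(1, 2), c(-1, -2)), "> 0")
})

test_that("r_squared of independent series is near zero", {
  set.seed(99)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(r_squared(x, y), 0.02)
})

test_that("two_way_anova matches the balanced cell-mean oracle", {
  set.seed(5)
  # textbook balanced 2x3 with 4 replicates
  f1 <- rep(c("raman", "assay"), each = 12)
  f2 <- rep(rep(1:3, each = 4), 2)
  y <- rnorm(24, mean = as.numeric(f2))
  tab <- two_way_anova(y, f1, f2)
  orc <- anova_oracle(y, f1, f2)
  got <- tab[match(c("technique", "depth", "technique:depth", "residual"),
                   tab$term), ]
  expect_equal(got$sum_sq, orc$ss, tolerance = 1e-8)
  expect_equal(got$df, orc$df)
  expect_equal(got$F[1:3], orc$F, tolerance = 1e-8)
  expect_equal(got$p[1:3],
               stats::pf(orc$F, orc$df[1:3], orc$df[4], lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("two_way_anova handles degenerate inputs", {
  f1 <- rep(c("a", "b"), each = 4)
  f2 <- rep(1:4, 2)
  tab <- two_way_anova(rep(2.5, 8), f1, f2)
  expect_true(all(tab$sum_sq == 0))
  expect_true(all(tab$p[tab$term != "residual"] == 1))

  expect_error(two_way_anova(1:4, rep("a", 4), rep(1:2, 2)), "2 levels")
  expect_error(two_way_anova(1:4, c("a", "a", "a", "b"),
                             c(1, 2, 1, 1)), "empty design cells")
})

test_that("an injected technique offset is detected", {
  set.seed(6)
  base <- sin((1:6) / 2) + 3
  y <- c(base + rnorm(6, 0, 0.05), base + 1 + rnorm(6, 0, 0.05))
  tab <- two_way_anova(y, rep(c("raman", "assay"), each = 6), rep(1:6, 2))
  expect_lt(tab$p[tab$term == "technique"], 0.05)
})

test_that("validate_constituent is self-consistent on shared ground truth", {
  # linear gradients: slab means coincide with mid-depth values
  ph <- make_phantom("native", n_rows = 40, n_cols = 8,
                     wavenumber = test_axis(16), baseline_level = 0,
                     noise_level = 0, seed = 110L)
  ps <- ph$cube$pixel_size_um
  assay <- sample_assay(ph$truth, n_sections = 8, noise_cv = 0, seed = 1L)
  anorm <- normalize_profile(
    depth_profile(assay$section_mid_depths_mm,
                  assay$concentrations[, "GAG"], constituent = "GAG"),
    "peak_anchor")
  # both series anchored at the same positional value (the assay anchor)
  prof <- normalize_profile(
    lateral_average(ph$truth$fields$GAG, ps, "GAG"), "peak_anchor",
    anchor_depth_mm = anorm$normalization$anchor_depth_mm)
  rep_ <- validate_constituent(prof,
    list(section_mid_depths_mm = anorm$depths_mm,
         concentrations = anorm$values))
  expect_gt(rep_$r_squared, 0.99)
  expect_lt(rep_$rmsep_percent, 2)
  expect_gt(rep_$anova$p[rep_$anova$term == "technique"], 0.05)

  # a deliberate +50 % assay offset must be flagged
  rep2 <- validate_constituent(prof,
    list(section_mid_depths_mm = anorm$depths_mm,
         concentrations = anorm$values * 1.5))
  expect_lt(rep2$anova$p[rep2$anova$term == "technique"], 0.05)

  expect_error(validate_constituent(prof,
    list(section_mid_depths_mm = 1.5, concentrations = 2)), "at least 2")
})

test_that("the technique test keeps its nominal type-I error", {
  ph <- clean_phantom()
  ps <- ph$cube$pixel_size_um
  prof <- normalize_profile(
    lateral_average(ph$truth$fields$GAG, ps, "GAG"), "peak_anchor")
  exact <- sample_assay(ph$truth, n_sections = 8, noise_cv = 0, seed = 1L)
  truth_sections <- pair_profiles(prof, list(
    section_mid_depths_mm = exact$section_mid_depths_mm,
    concentrations = exact$concentrations[, "GAG"]))$raman_value
  set.seed(123)
  n_sim <- 1000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    # both techniques observe the same section truth with independent
    # measurement noise: the technique null holds
    raman_rep <- truth_sections * rnorm(8, 1, 0.05)
    assay_rep <- truth_sections * rnorm(8, 1, 0.05)
    tab <- two_way_anova(c(raman_rep, assay_rep),
                         rep(c("raman", "assay"), each = 8),
                         rep(1:8, 2))
    if (tab$p[tab$term == "technique"] < 0.05) hits <- hits + 1L
  }
  expect_equal(hits / n_sim, 0.05, tolerance = 0.02 / 0.05)
})
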
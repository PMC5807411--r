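# End-to-end pipeline: phantom (or stored cube) -> baseline subtraction ->
# fingerprint crop -> MCR-ALS -> degenerate merge -> reference matching ->
# depth profiles / water map / localized CoV -> validation against the
# sectioned assay.  Fully deterministic given the config seed.

.config_keys <- c("tissue_model", "n_rows", "n_cols", "wavenumber",
                  "pixel_size_um", "baseline_level", "noise_level",
                  "lateral_cv", "include_cell", "baseline", "fit",
                  "water_band", "normalization", "assay", "cov_depths_mm",
                  "seed", "input_cube", "write_cube")

norm_defaults <- function(tissue_model) {
  switch(tissue_model,
    native = list(
      GAG = list(scheme = "peak_anchor", anchor_depth_mm = 1.4),
      collagen = list(scheme = "peak_anchor", anchor_depth_mm = 1.4),
      water = list(scheme = "surface_anchor", anchor_depth_mm = 0.1)),
    engineered = list(
      GAG = list(scheme = "surface_anchor", anchor_depth_mm = 0.4),
      collagen = list(scheme = "surface_anchor", anchor_depth_mm = 0.4),
      water = list(scheme = "surface_anchor", anchor_depth_mm = 0.4)),
    digested = list(
      GAG = list(scheme = "peak_anchor", anchor_depth_mm = 2.5),
      collagen = list(scheme = "mean_anchor", anchor_depth_mm = NA),
      water = list(scheme = "mean_anchor", anchor_depth_mm = NA)))
}

#' Build a validated pipeline configuration
#'
#' Returns the full default configuration for a tissue model, with any
#' field overridden through `...`.  Unknown keys are rejected.
#'
#' Defaults reflect the canonical acquisition design: 350 x 100 px geometry,
#' 600-3600 cm-1 axis at 4 cm-1 steps, rolling-shape baseline with a
#' 1000-point native window, fingerprint fit range 800-1800 cm-1 with k = 4
#' and merge threshold 0.9, water band 3100-3600 cm-1, 8 assay sections
#' for native tissue and 4 otherwise, and per-constituent normalization
#' anchors (peak at 1.4 mm for native GAG/collagen, surface at 0.1 mm for
#' native water, surface at 0.4 mm for engineered constituents, peak at
#' 2.5 mm for digested GAG and mean-anchoring for digested collagen).
#'
#' @param tissue_model "native", "engineered" or "digested".
#' @param ... overrides for any configuration key.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(tissue_model = c("native", "engineered",
                                             "digested"), ...) {
  tissue_model <- match.arg(tissue_model)
  cfg <- list(
    tissue_model = tissue_model,
    n_rows = 350L, n_cols = 100L,
    wavenumber = list(lo = 600, hi = 3600, step = 4),
    pixel_size_um = NULL,
    baseline_level = 1.0, noise_level = 0.02,
    lateral_cv = list(GAG = 0.10, collagen = 0.10, water = 0.03,
                      cell = 0.15),
    include_cell = TRUE,
    baseline = list(method = "rolling_shape", window_points = 1000L),
    fit = list(range = c(800, 1800), k = 4L, tol = 1e-6, max_iter = 200L,
               merge_threshold = 0.9, init = "purest_channel"),
    water_band = c(3100, 3600),
    normalization = norm_defaults(tissue_model),
    assay = list(n_sections = if (tissue_model == "native") 8L else 4L,
                 noise_cv = 0.075),
    cov_depths_mm = switch(tissue_model,
                           native = c(deep = 2.5),
                           engineered = c(periphery = 0.1, central = 2.0),
                           digested = c(deep = 1.5)),
    seed = 1L,
    input_cube = NULL,
    write_cube = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), .config_keys)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, over, keep.null = TRUE)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly / the configuration.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), .config_keys)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, c(list(tissue_model = raw$tissue_model),
                             raw[setdiff(names(raw), "tissue_model")]))
}

roi_at_depth <- function(depth_mm, map, pixel_size_um, size_um = 250) {
  H <- nrow(map) * pixel_size_um
  W <- ncol(map) * pixel_size_um
  size_um <- min(size_um, H, W)
  top <- min(max(depth_mm * 1000 - size_um / 2, 0), H - size_um)
  left <- min(max(W / 2 - size_um / 2, 0), W - size_um)
  roi(top, left, size_um, size_um)
}

#' Run the full analysis pipeline
#'
#' Executes phantom generation (or loads a stored cube), baseline
#' subtraction, fingerprint-range MCR-ALS with degenerate-component
#' merging and matching against the ground-truth reference spectra,
#' high-wavenumber water mapping, laterally averaged normalized and
#' absolute depth profiles, localized CoV scores, and statistical
#' validation against the simulated sectioned assay.  All result tables
#' are written to `out_dir` as CSV/JSON; the run is deterministic given
#' the configuration (including its seed).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log messages to the console.
#' @return (invisibly) list with `fit`, `matched`, `profiles`,
#'   `assay`, `validation`, `cov`, `truth`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "log.txt")
  cat("", file = log_file)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    msg <- sprintf("stage=%s elapsed=%.2fs", name,
                   proc.time()[["elapsed"]] - t0)
    cat(msg, "\n", file = log_file, append = TRUE)
    if (!quiet) message(msg)
    res
  }

  wn <- seq(config$wavenumber$lo, config$wavenumber$hi,
            by = config$wavenumber$step)

  ph <- stage("phantom", {
    if (!is.null(config$input_cube)) {
      list(cube = read_cube(config$input_cube), truth = NULL)
    } else {
      make_phantom(config$tissue_model,
                   n_rows = config$n_rows, n_cols = config$n_cols,
                   wavenumber = wn, pixel_size_um = config$pixel_size_um,
                   lateral_cv = unlist(config$lateral_cv),
                   baseline_level = config$baseline_level,
                   noise_level = config$noise_level,
                   include_cell = config$include_cell,
                   seed = config$seed)
    }
  })
  cube <- ph$cube; truth <- ph$truth
  ps <- cube$pixel_size_um
  if (isTRUE(config$write_cube))
    stage("write_cube", write_cube(cube, file.path(out_dir, "cube"),
                                   seed = config$seed))

  assay <- if (!is.null(truth))
    stage("assay", sample_assay(truth, n_sections = config$assay$n_sections,
                                noise_cv = config$assay$noise_cv,
                                seed = config$seed)) else NULL

  bl_par <- baseline_params(method = config$baseline$method,
                            window_points = config$baseline$window_points)
  # the water map keeps its own (wider-window) default baseline: the
  # envelope window must exceed the broad OH band support
  water_map <- stage("water_map",
                     water_map_hw(cube, band = config$water_band))
  pre <- stage("preprocess", subtract_baseline(cube, bl_par))

  fit <- stage("fit_mcr",
               fit_mcr(pre$cube, k = config$fit$k,
                       fit_range = config$fit$range, tol = config$fit$tol,
                       max_iter = config$fit$max_iter,
                       init = config$fit$init, seed = config$seed))
  fit <- stage("merge_degenerate",
               merge_degenerate(fit, config$fit$merge_threshold))

  matched <- NULL
  maps <- fit$maps
  if (!is.null(truth)) {
    matched <- stage("match_references", {
      refs <- component_spectra(
        truth$spectra[, truth$wavenumber >= config$fit$range[1] &
                        truth$wavenumber <= config$fit$range[2],
                      drop = FALSE],
        truth$wavenumber[truth$wavenumber >= config$fit$range[1] &
                           truth$wavenumber <= config$fit$range[2]])
      match_references(fit$S, refs)
    })
    nms <- make.unique(matched$S$names)
    names(maps) <- nms
    fit$S <- matched$S
  }

  res <- analyze_model(fit, maps, water_map, truth, assay, config, ps,
                       out_dir, stage)
  invisible(c(list(fit = fit, matched = matched, assay = assay,
                   truth = truth), res))
}

# Shared per-tissue-model quantification + validation + output writing,
# used by run_pipeline (single model) and run_study (joint fit).
analyze_model <- function(fit, maps, water_map, truth, assay, config, ps,
                          out_dir, stage) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- stage("profiles", {
    out <- list()
    for (nm in intersect(c("GAG", "collagen"), names(maps))) {
      raw <- lateral_average(maps[[nm]], ps, constituent = nm)
      sch <- config$normalization[[nm]]
      norm <- normalize_profile(raw, sch$scheme,
                                anchor_depth_mm =
                                  if (is.null(sch$anchor_depth_mm) ||
                                      is.na(sch$anchor_depth_mm)) NULL
                                  else sch$anchor_depth_mm)
      out[[nm]] <- list(raw = raw, normalized = norm,
                        uniform = if (!is.null(assay))
                          profile_slope_p(norm,
                            assay$section_mid_depths_mm) > 0.05 else NA)
    }
    wprof <- lateral_average(water_map, ps, constituent = "water")
    sch <- config$normalization$water
    out$water <- list(raw = wprof,
                      normalized = normalize_profile(wprof, sch$scheme,
                        anchor_depth_mm =
                          if (is.null(sch$anchor_depth_mm) ||
                              is.na(sch$anchor_depth_mm)) NULL
                          else sch$anchor_depth_mm),
                      uniform = NA)
    out
  })

  # absolute % wet-weight profiles via the bulk assay means
  if (!is.null(truth)) {
    for (nm in names(profiles)) {
      if (nm %in% names(truth$ww_mean))
        profiles[[nm]]$absolute <-
          to_absolute(profiles[[nm]]$normalized, truth$ww_mean[[nm]])
    }
  }

  validation <- NULL
  if (!is.null(assay)) {
    validation <- stage("validate", {
      out <- list()
      for (nm in intersect(names(profiles),
                           colnames(assay$concentrations))) {
        sch <- config$normalization[[nm]]
        aprof <- depth_profile(assay$section_mid_depths_mm,
                               assay$concentrations[, nm],
                               constituent = nm)
        anorm <- normalize_profile(aprof, sch$scheme,
                                   anchor_depth_mm =
                                     if (is.null(sch$anchor_depth_mm) ||
                                         is.na(sch$anchor_depth_mm)) NULL
                                     else sch$anchor_depth_mm)
        alist <- list(section_mid_depths_mm = anorm$depths_mm,
                      concentrations = anorm$values)
        # anchor the Raman profile at the same positional value used for
        # the assay normalization (the nearest section depth)
        rnorm_ <- normalize_profile(profiles[[nm]]$raw, sch$scheme,
          anchor_depth_mm = anorm$normalization$anchor_depth_mm)
        out[[nm]] <- validate_constituent(rnorm_, alist, constituent = nm)
      }
      out
    })
  }

  cov_scores <- stage("local_cov", {
    rows <- list()
    for (i in seq_along(config$cov_depths_mm)) {
      region <- names(config$cov_depths_mm)[i]
      for (nm in intersect(c("GAG", "collagen"), names(maps))) {
        r <- roi_at_depth(config$cov_depths_mm[[i]], maps[[nm]], ps)
        sc <- local_cov(maps[[nm]], r, ps, constituent = nm)
        rows[[length(rows) + 1L]] <- data.frame(
          tissue = config$tissue_model, region = region, constituent = nm,
          cov_percent = sc$cov, n_pixels = sc$n_pixels)
      }
    }
    if (length(rows) == 0L)
      data.frame(tissue = character(), region = character(),
                 constituent = character(), cov_percent = numeric(),
                 n_pixels = integer())
    else do.call(rbind, rows)
  })

  paths <- stage("write_results", {
    p <- list()
    p$config <- file.path(out_dir, "config.json")
    write_config(config, p$config)
    p$spectra <- file.path(out_dir, "resolved_spectra.csv")
    write_spectra_csv(fit$S, p$spectra)
    prof_rows <- list()
    for (nm in names(profiles)) {
      for (kind in intersect(c("raw", "normalized", "absolute"),
                             names(profiles[[nm]]))) {
        df <- as.data.frame(profiles[[nm]][[kind]])
        df$kind <- kind
        df$uniform <- profiles[[nm]]$uniform
        prof_rows[[length(prof_rows) + 1L]] <- df
      }
    }
    p$profiles <- file.path(out_dir, "profiles.csv")
    data.table::fwrite(do.call(rbind, prof_rows), p$profiles)
    if (!is.null(assay)) {
      adf <- data.frame(depth_mm = assay$section_mid_depths_mm,
                        assay$concentrations, check.names = FALSE)
      p$assay <- file.path(out_dir, "assay.csv")
      data.table::fwrite(adf, p$assay)
    }
    if (!is.null(validation)) {
      vdf <- do.call(rbind, lapply(validation, function(v) {
        pt <- function(term) {
          x <- v$anova$p[v$anova$term == term]
          if (length(x)) x else NA_real_
        }
        data.frame(constituent = v$constituent, r2 = v$r_squared,
                   rmsep_percent = v$rmsep_percent,
                   p_technique = pt("technique"), p_depth = pt("depth"),
                   p_interaction = pt("technique:depth"))
      }))
      p$validation_csv <- file.path(out_dir, "validation.csv")
      data.table::fwrite(vdf, p$validation_csv)
      p$validation_json <- file.path(out_dir, "validation.json")
      jsonlite::write_json(
        lapply(validation, function(v)
          list(constituent = v$constituent, r_squared = v$r_squared,
               rmsep_percent = v$rmsep_percent, anova = v$anova,
               paired_points = v$paired_points)),
        p$validation_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    p$cov <- file.path(out_dir, "cov.csv")
    data.table::fwrite(cov_scores, p$cov)
    p
  })

  list(profiles = profiles, validation = validation, cov = cov_scores,
       paths = paths)
}

#' Run the joint multi-tissue study
#'
#' Analyzes all tissue models jointly: the images are combined into a
#' single dataset and resolved together — one phantom per
#' configuration is generated and baseline-subtracted, a single MCR-ALS
#' model with shared component spectra is fitted to the stacked pixel
#' matrix, and each tissue model is then quantified and validated from its
#' own concentration maps.  Joint resolution constrains the factorization
#' far better than per-tissue fits, because the union of concentration
#' patterns across tissue models spans a much wider abundance range.
#'
#' @param configs named list of [pipeline_config()]s, one per tissue model
#'   (use distinct seeds).  Fit settings (range, k, tolerance, merge
#'   threshold) are taken from the first config.
#' @param out_dir output directory; per-model results go to
#'   `out_dir/<name>/`.
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) list with `fit`, `matched` and one entry per model
#'   (each as in [run_pipeline()]).
#' @export
run_study <- function(configs, out_dir, quiet = FALSE) {
  stopifnot(length(configs) >= 1L,
            all(vapply(configs, inherits, logical(1), "pipeline_config")))
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, `[[`, character(1), "tissue_model")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "log.txt")
  cat("", file = log_file)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    msg <- sprintf("stage=%s elapsed=%.2fs", name,
                   proc.time()[["elapsed"]] - t0)
    cat(msg, "\n", file = log_file, append = TRUE)
    if (!quiet) message(msg)
    res
  }
  cfg1 <- configs[[1]]

  models <- stage("phantoms", lapply(configs, function(cf) {
    wn <- seq(cf$wavenumber$lo, cf$wavenumber$hi, by = cf$wavenumber$step)
    ph <- make_phantom(cf$tissue_model, n_rows = cf$n_rows,
                       n_cols = cf$n_cols, wavenumber = wn,
                       pixel_size_um = cf$pixel_size_um,
                       lateral_cv = unlist(cf$lateral_cv),
                       baseline_level = cf$baseline_level,
                       noise_level = cf$noise_level,
                       include_cell = cf$include_cell, seed = cf$seed)
    ph$assay <- sample_assay(ph$truth, n_sections = cf$assay$n_sections,
                             noise_cv = cf$assay$noise_cv, seed = cf$seed)
    ph
  }))

  pres <- stage("preprocess", lapply(models, function(ph) {
    cfb <- cfg1$baseline
    subtract_baseline(ph$cube, baseline_params(method = cfb$method,
      window_points = cfb$window_points))$cube
  }))

  fit <- stage("fit_mcr_joint",
               fit_mcr(unname(pres), k = cfg1$fit$k,
                       fit_range = cfg1$fit$range, tol = cfg1$fit$tol,
                       max_iter = cfg1$fit$max_iter, init = cfg1$fit$init,
                       seed = cfg1$seed))
  fit <- stage("merge_degenerate",
               merge_degenerate(fit, cfg1$fit$merge_threshold))

  truth1 <- models[[1]]$truth
  matched <- stage("match_references", {
    sel <- truth1$wavenumber >= cfg1$fit$range[1] &
      truth1$wavenumber <= cfg1$fit$range[2]
    refs <- component_spectra(truth1$spectra[, sel, drop = FALSE],
                              truth1$wavenumber[sel])
    match_references(fit$S, refs)
  })
  nms <- make.unique(matched$S$names)
  fit$S <- matched$S

  out <- list(fit = fit, matched = matched)
  per_cube_maps <- if (length(models) == 1L) list(fit$maps) else fit$maps
  for (i in seq_along(models)) {
    nm_model <- names(models)[i]
    maps <- per_cube_maps[[i]]
    names(maps) <- nms
    ph <- models[[i]]
    wmap <- stage(paste0("water_map_", nm_model),
                  water_map_hw(ph$cube, band = configs[[i]]$water_band))
    res <- analyze_model(fit, maps, wmap, ph$truth, ph$assay, configs[[i]],
                         ph$cube$pixel_size_um,
                         file.path(out_dir, nm_model), stage)
    res$assay <- ph$assay
    res$truth <- ph$truth
    out[[nm_model]] <- res
  }
  invisible(out)
}
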
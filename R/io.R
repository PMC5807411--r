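# File containers.  A cube is stored as a directory holding
#   axis.csv        single column `wavenumber_cm1`
#   intensities.csv long form `row,col,channel,intensity`
#   meta.json       pixel_size_um, surface_row, provenance, seed
# Component/reference spectra travel as a wide CSV with a
# `wavenumber_cm1` column plus one column per named component.

#' Write a hyperspectral cube to a directory container
#'
#' @param cube a [hyper_cube()].
#' @param path directory to create/fill.
#' @param provenance free-text provenance string stored in the metadata.
#' @param seed optional generator seed stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, provenance = "ramanECM", seed = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$data)
  data.table::fwrite(data.table::data.table(wavenumber_cm1 = cube$wavenumber),
                     file.path(path, "axis.csv"))
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                     channel = seq_len(d[3]))
  data.table::fwrite(data.table::data.table(
    row = idx$row, col = idx$col, channel = idx$channel,
    intensity = as.vector(cube$data)), file.path(path, "intensities.csv"))
  meta <- list(n_rows = d[1], n_cols = d[2], n_channels = d[3],
               pixel_size_um = cube$pixel_size_um,
               surface_row = cube$surface_row, provenance = provenance,
               seed = seed)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a hyperspectral cube from a directory container
#'
#' Enforces axis monotonicity and pixel-grid completeness; a missing
#' (row, col) pixel or a shape/metadata mismatch is an error naming the
#' offending field.
#'
#' @param path directory written by [write_cube()].
#' @return a [hyper_cube()].
#' @export
read_cube <- function(path) {
  axis_file <- file.path(path, "axis.csv")
  int_file <- file.path(path, "intensities.csv")
  meta_file <- file.path(path, "meta.json")
  for (f in c(axis_file, int_file, meta_file))
    if (!file.exists(f)) stop("missing cube file: ", f, call. = FALSE)
  wn <- data.table::fread(axis_file)$wavenumber_cm1
  if (any(diff(wn) <= 0))
    stop("axis.csv: wavenumbers must be strictly increasing", call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (f in c("n_rows", "n_cols", "n_channels", "pixel_size_um"))
    if (is.null(meta[[f]])) stop("meta.json: missing field ", f, call. = FALSE)
  if (meta$n_channels != length(wn))
    stop("meta.json: n_channels does not match axis length", call. = FALSE)
  dt <- data.table::fread(int_file)
  need <- c("row", "col", "channel", "intensity")
  if (!all(need %in% names(dt)))
    stop("intensities.csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n_exp <- meta$n_rows * meta$n_cols * meta$n_channels
  if (nrow(dt) != n_exp) {
    # locate a hole for the error message
    px <- unique(dt[, c("row", "col")])
    full <- expand.grid(row = seq_len(meta$n_rows), col = seq_len(meta$n_cols))
    miss <- full[!paste(full$row, full$col) %in% paste(px$row, px$col), ]
    if (nrow(miss) > 0L)
      stop(sprintf("intensities.csv: missing pixel (row %d, col %d)",
                   miss$row[1], miss$col[1]), call. = FALSE)
    stop(sprintf("intensities.csv: expected %d values, found %d",
                 n_exp, nrow(dt)), call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(meta$n_rows, meta$n_cols, meta$n_channels))
  arr[cbind(dt$row, dt$col, dt$channel)] <- dt$intensity
  if (anyNA(arr)) {
    hole <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop(sprintf("intensities.csv: missing pixel (row %d, col %d)",
                 hole[1], hole[2]), call. = FALSE)
  }
  hyper_cube(arr, wn, pixel_size_um = meta$pixel_size_um,
             surface_row = if (is.null(meta$surface_row)) 1L else
               meta$surface_row)
}

#' Write component spectra to a wide CSV
#'
#' @param S a [component_spectra()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(S, path) {
  stopifnot(inherits(S, "component_spectra"))
  dt <- data.table::data.table(wavenumber_cm1 = S$wavenumber)
  for (i in seq_along(S$names)) dt[[S$names[i]]] <- S$spectra[i, ]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read component spectra from a wide CSV
#'
#' @param path CSV with a `wavenumber_cm1` column and one column per
#'   component; duplicate component names are an error.
#' @return a [component_spectra()].
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path)
  if (!"wavenumber_cm1" %in% names(dt))
    stop("spectra CSV must have a wavenumber_cm1 column", call. = FALSE)
  comp <- names(dt)[names(dt) != "wavenumber_cm1"]
  if (length(comp) == 0L)
    stop("spectra CSV has no component columns", call. = FALSE)
  if (anyDuplicated(comp))
    stop("duplicate component names: ",
         paste(unique(comp[duplicated(comp)]), collapse = ", "),
         call. = FALSE)
  for (nm in comp) {
    v <- dt[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d", nm, bad),
           call. = FALSE)
    }
  }
  S <- t(as.matrix(dt[, comp, with = FALSE]))
  component_spectra(S, dt$wavenumber_cm1, names = comp)
}
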
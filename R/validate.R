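# Statistical comparison of Raman-derived depth profiles with sectioned
# biochemical assay profiles: pairing by interpolation at section
# mid-depths, squared Pearson correlation, RMSEP as a percentage of the
# mean observed value, and two-way (technique x depth) ANOVA.

#' Pair a Raman depth profile with assay sections
#'
#' Linearly interpolates the (densely sampled) Raman profile at each assay
#' section mid-depth.  Section depths outside the profile range are clamped
#' to the nearest profile endpoint with a warning.
#'
#' @param raman a [depth_profile()].
#' @param assay a [sample_assay()] result, or a data.frame/list with
#'   `section_mid_depths_mm` and a vector of values via `constituent`.
#' @param constituent which assay column to pair (defaults to the
#'   profile's constituent).
#' @return data.frame with columns `depth_mm`, `raman_value`,
#'   `assay_value`.
#' @export
pair_profiles <- function(raman, assay, constituent = raman$constituent) {
  stopifnot(inherits(raman, "depth_profile"))
  depths <- assay$section_mid_depths_mm
  if (length(depths) < 2L)
    stop("need at least 2 assay sections", call. = FALSE)
  vals <- if (is.matrix(assay$concentrations))
    assay$concentrations[, constituent] else assay$concentrations
  rng <- range(raman$depths_mm)
  if (any(depths < rng[1] | depths > rng[2]))
    warning("assay depths outside Raman profile range; clamped")
  ram <- stats::approx(raman$depths_mm, raman$values, xout = depths,
                       rule = 2)$y
  data.frame(depth_mm = depths, raman_value = ram, assay_value = vals)
}

#' Squared Pearson correlation between two series
#'
#' @param x,y numeric series of equal length >= 3, neither constant.
#' @return scalar in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(x, y)^2
}

#' Root mean square error of prediction, percent of the observed mean
#'
#' `100 * sqrt(mean((pred - obs)^2)) / mean(obs)`.
#'
#' @param pred,obs numeric series of equal length >= 1; `mean(obs) > 0`.
#' @return RMSEP in percent.
#' @export
rmsep <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1L)
    stop("pred and obs must have equal positive length", call. = FALSE)
  if (mean(obs) <= 0) stop("mean(obs) must be > 0", call. = FALSE)
  100 * sqrt(mean((pred - obs)^2)) / mean(obs)
}

#' Two-way ANOVA (technique x depth), type-II sums of squares
#'
#' Tests the effect of measurement technique (Raman vs assay), depth, and
#' (when every cell has replicates) their interaction on concentration.
#' Sums of squares are type II; F ratios use the residual mean square and
#' p-values come from the F distribution.  When all responses are equal,
#' all sums of squares are zero and p is reported as 1.
#'
#' @param values numeric response.
#' @param technique factor (e.g. "raman"/"assay"), >= 2 levels.
#' @param depth factor of depth positions, >= 2 levels.
#' @param interaction include the technique:depth interaction; requires
#'   more than one replicate per cell (default: automatic).
#' @return data.frame with rows technique, depth, (interaction,) residual
#'   and columns `sum_sq`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(values, technique, depth, interaction = NULL) {
  technique <- factor(technique); depth <- factor(depth)
  if (nlevels(technique) < 2L || nlevels(depth) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  tab <- table(technique, depth)
  if (any(tab == 0L))
    stop("empty design cells", call. = FALSE)
  if (is.null(interaction)) interaction <- all(tab > 1L)
  if (interaction && !all(tab >= 1L))
    stop("interaction requires at least one replicate per cell", call. = FALSE)
  if (interaction && !any(tab > 1L))
    stop("interaction requires replicated cells (no residual df otherwise)",
         call. = FALSE)
  dat <- data.frame(y = as.numeric(values), technique = technique,
                    depth = depth)
  form <- if (interaction) y ~ technique * depth else y ~ technique + depth
  fit <- stats::lm(form, data = dat)
  if (stats::sd(dat$y) == 0) {
    rows <- c("technique", "depth", if (interaction) "technique:depth",
              "residual")
    dfs <- c(nlevels(technique) - 1L, nlevels(depth) - 1L,
             if (interaction) (nlevels(technique) - 1L) * (nlevels(depth) - 1L))
    dfs <- c(dfs, nrow(dat) - 1L - sum(dfs))
    return(data.frame(term = rows, sum_sq = 0, df = dfs,
                      F = c(rep(0, length(rows) - 1L), NA),
                      p = c(rep(1, length(rows) - 1L), NA)))
  }
  a <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (!is.null(a)) {
    out <- data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
    out$term <- sub("^Residuals$", "residual", out$term)
    rownames(out) <- NULL
    return(out)
  }
  # degenerate: (near-)zero residual; type-II sums of squares by explicit
  # model comparison, with F/p resolved by whether each term's SS is zero
  rss <- function(f) sum(stats::lm(f, data = dat)$residuals^2)
  r_full <- sum(fit$residuals^2)
  r_add <- if (interaction) rss(y ~ technique + depth) else r_full
  ss <- c(technique = rss(y ~ depth) - r_add,
          depth = rss(y ~ technique) - r_add)
  if (interaction) ss <- c(ss, "technique:depth" = r_add - r_full)
  dfs <- c(nlevels(technique) - 1L, nlevels(depth) - 1L,
           if (interaction) (nlevels(technique) - 1L) *
             (nlevels(depth) - 1L))
  df_res <- nrow(dat) - 1L - sum(dfs)
  eps <- 1e-12 * sum((dat$y - mean(dat$y))^2)
  Fv <- ifelse(ss <= eps, 0, Inf)
  pv <- ifelse(ss <= eps, 1, 0)
  data.frame(term = c(names(ss), "residual"),
             sum_sq = c(pmax(ss, 0), r_full),
             df = c(dfs, df_res),
             F = c(Fv, NA), p = c(pv, NA))
}

#' Full validation of one constituent
#'
#' Pairs the Raman profile with the assay sections and reports the squared
#' Pearson correlation, the RMSEP (percent of the mean assay value) and the
#' two-way technique x depth ANOVA on the stacked paired series.  Both
#' series should carry matching normalization (same scheme and anchor).
#'
#' @param raman a normalized [depth_profile()].
#' @param assay a `sectioned_assay` (values normalized under the same
#'   scheme) or anything accepted by [pair_profiles()].
#' @param constituent assay column to validate.
#' @return object of class `validation_report`: list(constituent,
#'   r_squared, rmsep_percent, anova, paired_points).
#' @export
validate_constituent <- function(raman, assay,
                                 constituent = raman$constituent) {
  pp <- pair_profiles(raman, assay, constituent)
  rs <- r_squared(pp$raman_value, pp$assay_value)
  rm <- rmsep(pp$raman_value, pp$assay_value)
  vals <- c(pp$raman_value, pp$assay_value)
  tech <- rep(c("raman", "assay"), each = nrow(pp))
  dep <- factor(rep(seq_len(nrow(pp)), 2))
  an <- two_way_anova(vals, tech, dep)
  structure(list(constituent = constituent, r_squared = rs,
                 rmsep_percent = rm, anova = an, paired_points = pp),
            class = "validation_report")
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  p_tech <- x$anova$p[x$anova$term == "technique"]
  cat(sprintf(
    "<validation: %s, R2 = %.3f, RMSEP = %.1f%%, technique p = %.3f>\n",
    x$constituent, x$r_squared, x$rmsep_percent, p_tech))
  invisible(x)
}

# Slope-vs-depth uniformity test of a profile evaluated at section-level
# resolution: the profile is interpolated at the assay mid-depths and the
# regression slope tested against zero.  Returns the slope p-value
# (p > alpha => "uniform").
profile_slope_p <- function(profile, depths_mm) {
  v <- stats::approx(profile$depths_mm, profile$values, xout = depths_mm,
                     rule = 2)$y
  fit <- stats::lm(v ~ depths_mm)
  co <- summary(fit)$coefficients
  if (nrow(co) < 2L || !is.finite(co[2, 4])) return(1)
  co[2, 4]
}
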
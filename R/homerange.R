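#' Autocorrelation-aware kernel home-range estimate
#'
#' Gaussian kernel density over the relocations, discretized to grid-cell
#' probability masses. The bandwidth corrects for serial autocorrelation
#' by using the effective sample size in place of the number of fixes:
#' per-axis `h^2 = sigma2 * dof_area^(-2/(d+2))` with `d = 2`, the
#' Gaussian reference rule evaluated at the number of statistically
#' independent home-range crossings rather than the (much larger) fix
#' count. Cell masses are exact integrals of each kernel over the cell
#' box (products of normal CDF differences), then renormalized to sum
#' to 1.
#'
#' @param track A [clean_track()] result.
#' @param fit Its [fit_ou()] result.
#' @param spec Target [grid_spec()] — the same grid the fire rasters use.
#' @param residency Optional [classify_residency()] result; a non-resident
#'   verdict is refused (a drifting animal has no defined range).
#' @param level Highest-density-region level for the reported support
#'   (default 0.95).
#' @param frame Coordinate frame of `spec`: the track's [local_frame()]
#'   when the grid is in degrees (default), or `NULL` when the grid is in
#'   the track's own km coordinates.
#' @return An object of class `home_range`: `id`, `pmf` (kind `weight`),
#'   `hdr` (mask raster of the level-HDR support), `area_km2`,
#'   `bandwidth_km`, `level`, and `fit` (sigma2/tau/dof_area used).
#' @export
estimate_pmf <- function(track, fit, spec, residency = NULL, level = 0.95,
                         frame = attr(track, "frame")) {
  if (!is.null(residency) && residency$verdict != "resident")
    ft_stop("refusing to estimate a home range for a non-resident individual",
            "non_resident_error")
  stopifnot(inherits(spec, "grid_spec"))
  h <- sqrt(fit$sigma2) * max(fit$dof_area, 1)^(-1 / 4)  # km, per axis
  if (is.null(frame)) {
    cx <- track$x; cy <- track$y
    sdx <- h; sdy <- h
  } else {
    p <- unproject_xy(track$x, track$y, frame)
    cx <- p$lon; cy <- p$lat
    sdx <- h / frame$k_lon; sdy <- h / frame$k_lat
  }
  n <- length(cx)
  res <- spec$resolution
  xe <- spec$origin_lon + (0:spec$n_cols) * res
  ye <- spec$origin_lat - (0:spec$n_rows) * res      # descending
  Px <- stats::pnorm(outer(cx, xe[-1], function(c, e) (e - c) / sdx)) -
    stats::pnorm(outer(cx, xe[-length(xe)], function(c, e) (e - c) / sdx))
  Py <- stats::pnorm(outer(cy, ye[-length(ye)], function(c, e) (e - c) / sdy)) -
    stats::pnorm(outer(cy, ye[-1], function(c, e) (e - c) / sdy))
  m <- crossprod(Py, Px) / n                          # n_rows x n_cols
  m[m < 1e-12] <- 0
  tot <- sum(m)
  if (tot <= 0)
    ft_stop("track mass falls entirely outside the grid", "alignment_error")
  pmf <- grid_raster(spec, m / tot, kind = "weight")
  hdr <- hdr_support(pmf, level)
  structure(list(id = attr(track, "id") %||% "animal",
                 pmf = pmf, hdr = hdr$mask,
                 area_km2 = hdr$area_km2,
                 bandwidth_km = h, level = level,
                 fit = list(sigma2 = fit$sigma2, tau = fit$tau,
                            dof_area = fit$dof_area)),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range '%s': %.1f km2 at %.0f%% HDR, bandwidth %.2f km\n",
              x$id, x$area_km2, 100 * x$level, x$bandwidth_km))
  invisible(x)
}

hdr_support <- function(pmf, level) {
  v <- as.vector(pmf$values)
  o <- order(v, decreasing = TRUE)        # stable for ties
  cs <- cumsum(v[o])
  k <- which(cs >= level - 1e-12)[1]
  sel <- o[seq_len(k)]
  m <- matrix(0, pmf$spec$n_rows, pmf$spec$n_cols)
  m[sel] <- 1
  list(mask = grid_raster(pmf$spec, m, kind = "mask"),
       area_km2 = k * pmf$spec$cell_area)
}

#' Highest-density-region area of a home range
#'
#' Cells sorted by probability mass (descending, stable ties) are
#' accumulated until they hold at least `level` of the distribution; the
#' HDR is that cell set.
#'
#' @param hr A [estimate_pmf()] result (or any object with a `pmf`
#'   `grid_raster`).
#' @param level Mass level in (0, 1); default 0.95.
#' @return List `area_km2` and `mask` (a `grid_raster`).
#' @export
hdr_area <- function(hr, level = 0.95) {
  stopifnot(level > 0, level < 1)
  pmf <- if (inherits(hr, "grid_raster")) hr else hr$pmf
  s <- hdr_support(pmf, level)
  list(area_km2 = s$area_km2, mask = s$mask)
}

#' Fire impact on one home range in one year
#'
#' The burned fraction of a home range is the probability mass sitting on
#' fire-occurrence cells: `sum(pmf * occurrence)`. Burned extent converts
#' that fraction to km² of the HDR area. Mean fire intensity within the
#' range is the pmf-weighted mean brightness over burned cells (an
#' unweighted mean is available).
#'
#' @param hr A [estimate_pmf()] result.
#' @param fy A [build_fire_year()] result on the same grid.
#' @param weighted pmf-weight the intensity mean? Default `TRUE`.
#' @return One-row data frame: `id`, `year`, `burn_fraction`,
#'   `burned_km2`, `mean_intensity_K` (`NA` in a fire-free year).
#' @export
hr_burn <- function(hr, fy, weighted = TRUE) {
  check_aligned(hr$pmf, fy$occurrence)
  w <- hr$pmf$values * fy$occurrence$values
  bf <- sum(w)
  mi <- if (bf > 0) {
    if (weighted) sum(w * fy$intensity$values) / bf
    else mean(fy$intensity$values[w > 0])
  } else NA_real_
  data.frame(id = hr$id, year = fy$year, burn_fraction = bf,
             burned_km2 = bf * hr$area_km2, mean_intensity_K = mi)
}

#' Fire impact on the protected part of one home range
#'
#' Triple overlay pmf x PA x fire: `pa_km2` is the HR mass inside
#' protected areas scaled to the HDR area, `pa_burned_km2` the part of it
#' on fire cells, `pa_burn_fraction` their ratio (`NA` when the range has
#' no protected mass).
#'
#' @param hr A [estimate_pmf()] result.
#' @param pa_mask Protected-area mask on the same grid.
#' @param fy A [build_fire_year()] result on the same grid.
#' @return One-row data frame: `id`, `year`, `pa_km2`, `pa_burned_km2`,
#'   `pa_burn_fraction`.
#' @export
hr_pa_burn <- function(hr, pa_mask, fy) {
  check_aligned(hr$pmf, pa_mask)
  check_aligned(hr$pmf, fy$occurrence)
  pmf <- hr$pmf$values
  pa_mass <- sum(pmf * pa_mask$values)
  pa_burn_mass <- sum(pmf * pa_mask$values * fy$occurrence$values)
  data.frame(id = hr$id, year = fy$year,
             pa_km2 = pa_mass * hr$area_km2,
             pa_burned_km2 = pa_burn_mass * hr$area_km2,
             pa_burn_fraction = if (pa_mass > 0) pa_burn_mass / pa_mass
                                else NA_real_)
}

#' Summarise fire impact across a cohort of home ranges
#'
#' @param records Data frame of [hr_burn()] rows for one year (optionally
#'   merged with [hr_pa_burn()] columns).
#' @param affected_threshold An HR counts as affected when its
#'   `burn_fraction` exceeds this (default 0: any burned mass).
#' @return List `n_hr`, `n_affected`, `pct_affected` (nearest integer
#'   percent), `median_burn_fraction_affected`, `total_burned_km2`, and —
#'   when PA columns are present — `total_pa_km2`, `total_pa_burned_km2`,
#'   `pct_pa_burned`.
#' @export
cohort_summary <- function(records, affected_threshold = 0) {
  if (!nrow(records)) ft_stop("no home-range records", "insufficient_data")
  aff <- records$burn_fraction > affected_threshold
  out <- list(
    n_hr = nrow(records),
    n_affected = sum(aff),
    pct_affected = round(100 * sum(aff) / nrow(records)),
    median_burn_fraction_affected =
      if (any(aff)) stats::median(records$burn_fraction[aff]) else NA_real_,
    total_burned_km2 = sum(records$burned_km2))
  if (all(c("pa_km2", "pa_burned_km2") %in% names(records))) {
    out$total_pa_km2 <- sum(records$pa_km2)
    out$total_pa_burned_km2 <- sum(records$pa_burned_km2)
    out$pct_pa_burned <- if (out$total_pa_km2 > 0)
      round(100 * out$total_pa_burned_km2 / out$total_pa_km2) else NA_real_
  }
  out
}
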
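#' Convert a per-100-km² density raster to individuals per cell
#'
#' Published large-carnivore density products report expected individuals
#' per 100 km². Dividing by 100 and scaling by the declared cell area gives
#' expected individuals per cell, so the raster sum is the expected total
#' abundance inside the grid.
#'
#' @param raw `grid_raster` of densities in individuals per 100 km².
#' @return An object of class `density_surface`: list with `raster`
#'   (kind `density`, individuals per cell) and `total` (its sum).
#' @export
density_from_per100km2 <- function(raw) {
  stopifnot(inherits(raw, "grid_raster"))
  if (any(raw$values < 0, na.rm = TRUE))
    ft_stop("density input has negative cells", "data_error")
  v <- raw$values / 100 * raw$spec$cell_area
  r <- grid_raster(raw$spec, v, kind = "density")
  structure(list(raster = r, total = raster_sum(r)),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("density_surface: total %.2f individuals over %d x %d cells\n",
              x$total, x$raster$spec$n_rows, x$raster$spec$n_cols))
  invisible(x)
}

#' Fraction of a region's area burned in one year
#'
#' Normalizes the region mask to unit mass and sums it over fire-occurrence
#' cells: with equal-area cells this is the burned proportion of the
#' region.
#'
#' @param region_mask Region mask raster.
#' @param fy A [build_fire_year()] result.
#' @return Burned fraction in \[0, 1\].
#' @export
exposed_fraction <- function(region_mask, fy) {
  w <- normalize_mask(region_mask)
  raster_sum(overlay_product(w, fy$occurrence))
}

#' Density-weighted count of individuals exposed to fire
#'
#' Sums the density surface over the region's fire cells: the expected
#' number of individuals whose cell burned — a proxy for animals
#' displaced, injured or killed, not a mortality estimate.
#'
#' @param density A [density_from_per100km2()] result (or any
#'   `density_surface`).
#' @param fy A [build_fire_year()] result.
#' @param region_mask Region mask raster.
#' @return List `affected`, `total` (individuals in the region) and
#'   `pct_affected` (= 100 * affected / total; `NA` when the region holds
#'   no individuals).
#' @export
exposed_count <- function(density, fy, region_mask) {
  if (sum(region_mask$values) <= 0)
    ft_stop("empty region", "empty_region_error")
  check_aligned(density$raster, region_mask)
  check_aligned(density$raster, fy$occurrence)
  dv <- density$raster$values
  total <- sum(dv * region_mask$values)
  affected <- sum(dv * region_mask$values * fy$occurrence$values)
  list(affected = affected, total = total,
       pct_affected = if (total > 0) 100 * affected / total else NA_real_)
}

#' Burned extent and fraction of protected areas within a region
#'
#' @param pa_mask Protected-area mask raster.
#' @param fy A [build_fire_year()] result.
#' @param region_mask Region mask raster.
#' @return List `pa_km2` (PA extent inside the region), `burned_km2`, and
#'   `fraction` = burned / extent (`NA` when the region holds no PA cells).
#' @export
pa_burn_fraction <- function(pa_mask, fy, region_mask) {
  check_aligned(pa_mask, region_mask)
  check_aligned(pa_mask, fy$occurrence)
  ca <- pa_mask$spec$cell_area
  inreg <- pa_mask$values * region_mask$values
  pa_km2 <- sum(inreg) * ca
  burned_km2 <- sum(inreg * fy$occurrence$values) * ca
  list(pa_km2 = pa_km2, burned_km2 = burned_km2,
       fraction = if (pa_km2 > 0) burned_km2 / pa_km2 else NA_real_)
}

#' Annual exposure table across regions
#'
#' One row per (year, region): density-weighted affected and total counts,
#' percentage affected, burned area fraction, and mean fire intensity over
#' the region's burned cells. When `partition` names regions declared to
#' partition the first region (an ecoregion split into countries), the sum
#' of their affected counts is checked against the whole-region row.
#'
#' @param density A `density_surface`.
#' @param fire_years List of [build_fire_year()] results (one per year).
#' @param region_masks Named list of region mask rasters.
#' @param partition Optional character vector: names in `region_masks`
#'   whose masks partition `region_masks[[1]]`.
#' @return Data frame of class `exposure_table` with columns `year`,
#'   `region`, `proxy_affected`, `proxy_total`, `pct_affected`,
#'   `burned_fraction`, `mean_intensity_K`.
#' @export
annual_series <- function(density, fire_years, region_masks,
                          partition = NULL) {
  stopifnot(length(fire_years) >= 1, length(region_masks) >= 1)
  if (is.null(names(region_masks)))
    names(region_masks) <- sprintf("region_%d", seq_along(region_masks))
  rows <- list()
  for (fy in fire_years) {
    for (rn in names(region_masks)) {
      m <- region_masks[[rn]]
      ec <- exposed_count(density, fy, m)
      st <- intensity_stats(fy, m)
      rows[[length(rows) + 1L]] <- data.frame(
        year = fy$year, region = rn,
        proxy_affected = ec$affected, proxy_total = ec$total,
        pct_affected = ec$pct_affected,
        burned_fraction = exposed_fraction(m, fy),
        mean_intensity_K = st$mean_K)
    }
    if (!is.null(partition)) {
      whole <- rn_first <- names(region_masks)[1]
      tot <- sum(vapply(partition, function(p)
        exposed_count(density, fy, region_masks[[p]])$affected, 0))
      ref <- exposed_count(density, fy, region_masks[[whole]])$affected
      if (abs(tot - ref) > 1e-6 * max(1, abs(ref)))
        warning(sprintf(
          "year %d: declared partition sums to %.9g but '%s' gives %.9g",
          fy$year, tot, whole, ref))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("exposure_table", "data.frame")
  out
}

#' Ratio of one year's value to the median of reference years
#'
#' The factor effect used to contextualise an extreme year: e.g. a 2020
#' exposure 3.3 times the median of the 15 previous years. Median uses the
#' standard midpoint rule for even counts.
#'
#' @param x Named numeric vector of annual values; names are years.
#' @param year Year to compare (character or integer).
#' @param reference_years Years forming the reference median.
#' @return The ratio; `NA` when the reference median is zero.
#' @export
factor_effect <- function(x, year, reference_years) {
  yrs <- as.character(reference_years)
  if (!length(yrs)) ft_stop("reference_years is empty", "data_error")
  if (!all(yrs %in% names(x)) || !as.character(year) %in% names(x))
    ft_stop("year(s) missing from the series", "data_error")
  m <- stats::median(x[yrs])
  if (m == 0) return(NA_real_)
  unname(x[as.character(year)] / m)
}

#' Regional shares of one year's affected total
#'
#' @param series An `exposure_table` (or data frame with `year`, `region`,
#'   `proxy_affected`).
#' @param year Year to summarise.
#' @param regions Optional region names to include (defaults to all rows of
#'   that year); pass the partition regions so the whole-region row is not
#'   double counted.
#' @return Named numeric vector of integer percentages (rounded to the
#'   nearest percent) of that year's affected total; `NA`s when the total
#'   is zero.
#' @export
share_by_region <- function(series, year, regions = NULL) {
  d <- series[series$year == year, , drop = FALSE]
  if (!is.null(regions)) d <- d[d$region %in% regions, , drop = FALSE]
  if (!nrow(d)) ft_stop("year not present in series", "data_error")
  tot <- sum(d$proxy_affected)
  if (tot <= 0) {
    out <- rep(NA_real_, nrow(d))
  } else {
    out <- round(100 * d$proxy_affected / tot)
  }
  stats::setNames(out, d$region)
}
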
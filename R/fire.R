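#' Read an active-fire detection table
#'
#' Reads a FIRMS-style CSV of satellite active-fire detections. Column
#' names are configurable so archives with different dialects parse
#' identically; rows that fail to parse (blank or non-numeric coordinates
#' or brightness, unparseable dates) are skipped and counted rather than
#' aborting the run.
#'
#' @param path CSV file.
#' @param columns Named list mapping the canonical fields `lon`, `lat`,
#'   `date`, `brightness` (and optionally `confidence`) to column names in
#'   the file.
#' @return A data frame of class `fire_detections` with columns `lon`,
#'   `lat`, `date` (`Date`), `brightness` (Kelvin) and `confidence`
#'   (`NA` when absent), plus attribute `n_skipped`.
#' @export
read_fire_detections <- function(path,
                                 columns = list(lon = "longitude",
                                                lat = "latitude",
                                                date = "acq_date",
                                                brightness = "brightness",
                                                confidence = "confidence")) {
  if (!file.exists(path)) ft_stop(paste("no such file:", path), "format_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("lon", "lat", "date", "brightness")
  miss <- setdiff(unlist(columns[need]), names(raw))
  if (length(miss))
    ft_stop(paste("missing mandatory column(s):", paste(miss, collapse = ", ")),
            "format_error")
  lon <- suppressWarnings(as.numeric(raw[[columns$lon]]))
  lat <- suppressWarnings(as.numeric(raw[[columns$lat]]))
  bright <- suppressWarnings(as.numeric(raw[[columns$brightness]]))
  date <- as.Date(raw[[columns$date]], optional = TRUE)
  conf <- if (!is.null(columns$confidence) && columns$confidence %in% names(raw))
    suppressWarnings(as.numeric(raw[[columns$confidence]])) else NA_real_
  ok <- is.finite(lon) & is.finite(lat) & is.finite(bright) & !is.na(date) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90 & bright > 0
  out <- data.frame(lon = lon[ok], lat = lat[ok], date = date[ok],
                    brightness = bright[ok],
                    confidence = if (length(conf) > 1) conf[ok] else conf)
  attr(out, "n_skipped") <- sum(!ok)
  class(out) <- c("fire_detections", "data.frame")
  out
}

#' Keep detections whose brightness exceeds a threshold
#'
#' Fire occurrence is declared only where brightness temperature is
#' strictly above the threshold (default 325 K, the standard cut used to
#' separate true fire pixels from warm surfaces in 1-km thermal-anomaly
#' products). The inequality is strict: a detection at exactly 325 K is
#' dropped.
#'
#' @param dets A `fire_detections` data frame.
#' @param threshold_K Brightness threshold in Kelvin (default 325).
#' @return The retained subset, same class, with attribute `threshold_K`.
#' @export
filter_by_threshold <- function(dets, threshold_K = 325) {
  stopifnot(threshold_K > 0)
  out <- dets[dets$brightness > threshold_K, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_K") <- threshold_K
  class(out) <- c("fire_detections", "data.frame")
  out
}

#' Build annual fire occurrence and intensity rasters
#'
#' Bins detections dated within one calendar year to grid cells by
#' cell-centre containment of the detection point. A cell's occurrence is
#' 1 when at least one detection falls in it; its intensity is the `max`
#' (default) or `mean` of the brightnesses recorded there that year.
#'
#' @param dets `fire_detections`, already brightness-filtered.
#' @param spec Target [grid_spec()].
#' @param year Calendar year (Jan 1 - Dec 31).
#' @param aggregate Per-cell intensity aggregation, `"max"` or `"mean"`.
#' @return An object of class `fire_year`: list with `year`, `occurrence`
#'   and `intensity` rasters, `n_detections_used`, and `aggregate`.
#'   A year with no detections yields valid all-zero rasters.
#' @export
build_fire_year <- function(dets, spec, year, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  yr <- as.integer(format(dets$date, "%Y"))
  d <- dets[!is.na(yr) & yr == year, , drop = FALSE]
  occ <- matrix(0, spec$n_rows, spec$n_cols)
  intens <- matrix(0, spec$n_rows, spec$n_cols)
  n_used <- 0L
  if (nrow(d)) {
    idx <- point_to_cell(spec, d$lon, d$lat)
    keep <- !is.na(idx$row)
    n_used <- sum(keep)
    if (n_used) {
      cells <- (idx$col[keep] - 1L) * spec$n_rows + idx$row[keep]
      agg <- if (aggregate == "max")
        tapply(d$brightness[keep], cells, max)
      else
        tapply(d$brightness[keep], cells, mean)
      ci <- as.integer(names(agg))
      occ[ci] <- 1
      intens[ci] <- as.numeric(agg)
    }
  }
  structure(list(year = as.integer(year),
                 occurrence = grid_raster(spec, occ, kind = "occurrence"),
                 intensity = grid_raster(spec, intens, kind = "intensity"),
                 n_detections_used = n_used,
                 aggregate = aggregate),
            class = "fire_year")
}

#' @export
print.fire_year <- function(x, ...) {
  cat(sprintf("fire_year %d: %d burned cells from %d detections (%s intensity)\n",
              x$year, sum(x$occurrence$values), x$n_detections_used,
              x$aggregate))
  invisible(x)
}

#' Daily fire profile within a region
#'
#' Counts, for each day of the year, the grid cells (not detections)
#' inside the mask with at least one detection, and the mean brightness of
#' that day's in-mask detections.
#'
#' @param dets `fire_detections` (brightness-filtered).
#' @param year Calendar year.
#' @param mask Region mask raster; its grid also does the cell binning.
#' @return Data frame with one row per day of the year: `doy`,
#'   `n_cells_with_fire`, `mean_intensity_K` (`NA` on fire-free days).
#' @export
daily_profile <- function(dets, year, mask) {
  spec <- mask$spec
  ndays <- if (is_leap(year)) 366L else 365L
  out <- data.frame(doy = seq_len(ndays), n_cells_with_fire = 0L,
                    mean_intensity_K = NA_real_)
  yr <- as.integer(format(dets$date, "%Y"))
  d <- dets[!is.na(yr) & yr == year, , drop = FALSE]
  if (!nrow(d)) return(out)
  idx <- point_to_cell(spec, d$lon, d$lat)
  keep <- !is.na(idx$row)
  keep[keep] <- mask$values[cbind(idx$row[keep], idx$col[keep])] > 0
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) return(out)
  cells <- (idx$col[keep] - 1L) * spec$n_rows + idx$row[keep]
  doy <- as.integer(format(d$date, "%j"))
  for (g in split(seq_len(nrow(d)), doy)) {
    day <- doy[g[1]]
    out$n_cells_with_fire[day] <- length(unique(cells[g]))
    out$mean_intensity_K[day] <- mean(d$brightness[g])
  }
  out
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Fire-intensity statistics over burned cells in a region
#'
#' @param fy A [build_fire_year()] result.
#' @param mask Region mask, alignment-compatible.
#' @return List `mean_K`, `median_K`, `burned_cells`. With no burned cells
#'   inside the mask, the statistics are `NA` (undefined), not 0.
#' @export
intensity_stats <- function(fy, mask) {
  check_aligned(fy$occurrence, mask)
  sel <- fy$occurrence$values > 0 & mask$values > 0
  n <- sum(sel)
  if (n == 0)
    return(list(mean_K = NA_real_, median_K = NA_real_, burned_cells = 0L))
  v <- fy$intensity$values[sel]
  list(mean_K = mean(v), median_K = stats::median(v), burned_cells = as.integer(n))
}
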
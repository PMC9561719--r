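#' Configuration for a synthetic wildfire-exposure scenario
#'
#' Bundles every knob of the generator with defaults sized to a large
#' tropical-wetland study system: a ~160,000 km² region at nominal 1-km
#' cells split into three unequal country sub-regions, a smooth density
#' surface normalized to 1668 individuals, ~10% protected-area coverage,
#' 48 range-resident tracked individuals, and fire seasons concentrated
#' in the dry season with a brightness distribution straddling the 325 K
#' occurrence threshold.
#'
#' @param seed Integer master seed; every component derives its own
#'   sub-seed from it, so outputs are reproducible and adding a component
#'   never reshuffles the others.
#' @param bounds Region bounding box `c(lon_min, lat_min, lon_max,
#'   lat_max)` in degrees.
#' @param resolution Cell edge in degrees (0.01 ~ 1.1 km).
#' @param cell_area Declared cell area in km².
#' @param country_shares Named longitude-share split of the region into
#'   sub-regions (a partition used for per-country accounting).
#' @param n_protected_areas,pa_size_km Protected areas: count and edge
#'   range (km) of non-overlapping rectangles placed inside the region.
#' @param abundance Total expected individuals; the density surface is
#'   rescaled so its raster sum equals this.
#' @param density_corr_km Correlation length (km) of the smoothed density
#'   field; 0 gives an i.i.d. field.
#' @param n_individuals Number of tracked individuals.
#' @param sigma2_range,tau_range Per-individual OU parameters drawn
#'   uniformly: stationary variance (km² per axis) and home-range
#'   crossing timescale (days).
#' @param track_span_days,track_dt_days Sampling span and fix interval.
#' @param years Fire-season years to simulate.
#' @param n_ignitions,detections_per_ignition,cluster_spread_km Fire
#'   clustering: ignition centres uniform in the region; detection counts
#'   per ignition are Poisson; detections scatter around the centre with
#'   this Gaussian sd.
#' @param season_mean_doy,season_sd_doy Dry-season concentration of
#'   detection dates (day of year).
#' @param subthreshold_share Share of detections generated below the
#'   325 K occurrence threshold (they exercise the filter).
#' @param brightness_shape Gamma shape of the brightness excess over
#'   300 K; the scale is solved so `subthreshold_share` falls below 325 K.
#' @param target_burn_fraction Optional q in (0, 1): the last year's
#'   fires are instead placed on the cells holding the top q of each
#'   tracked individual's true range mass (a placement-controlled
#'   scenario with known per-individual burned mass).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            bounds = c(-58.9, -21.0, -55.3, -16.5),
                            resolution = 0.01,
                            cell_area = 1,
                            country_shares = c(west = 0.82, central = 0.16,
                                               east = 0.02),
                            n_protected_areas = 6,
                            pa_size_km = c(25, 55),
                            abundance = 1668,
                            density_corr_km = 50,
                            n_individuals = 48,
                            sigma2_range = c(10, 50),
                            tau_range = c(1, 5),
                            track_span_days = 180,
                            track_dt_days = 1 / 12,
                            years = 2005:2020,
                            n_ignitions = 60,
                            detections_per_ignition = 40,
                            cluster_spread_km = 5,
                            season_mean_doy = 240,
                            season_sd_doy = 30,
                            subthreshold_share = 0.3,
                            brightness_shape = 2,
                            target_burn_fraction = NULL) {
  cfg <- as.list(environment())
  stopifnot(abundance > 0, n_individuals >= 1, resolution > 0,
            all(sigma2_range > 0), all(tau_range > 0),
            subthreshold_share >= 0, subthreshold_share < 1,
            abs(sum(country_shares) - 1) < 1e-9)
  if (!is.null(target_burn_fraction))
    stopifnot(target_burn_fraction > 0, target_burn_fraction < 1)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scenario_config")
}

# Counter-based sub-seed: stable under addition of new components.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483629)
}

#' Grid and coordinate frame of a scenario
#'
#' `scenario_spec` returns the [grid_spec()] every layer of the scenario
#' lives on; `scenario_frame` the [local_frame()] (centred on the region)
#' used to convert km-scale parameters to degrees.
#'
#' @param cfg A [scenario_config()].
#' @return A `grid_spec` / frame list respectively.
#' @export
scenario_spec <- function(cfg) {
  make_grid(cfg$bounds, cfg$resolution, cfg$cell_area)
}

#' @rdname scenario_spec
#' @export
scenario_frame <- function(cfg) {
  local_frame((cfg$bounds[1] + cfg$bounds[3]) / 2,
              (cfg$bounds[2] + cfg$bounds[4]) / 2)
}

# Separable Gaussian smoothing of a matrix (reflected edges).
smooth_field <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  r <- ceiling(3 * sd_cells)
  k <- stats::dnorm(seq(-r, r), sd = sd_cells)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(min(r, n))]), v, rev(v[seq.int(n, by = -1,
                                               length.out = min(r, n))]))
    out <- stats::filter(vp, k, sides = 2)
    out[(length(vp) - n - min(r, n) + 1):(length(vp) - min(r, n))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

#' Simulate the landscape: region, countries, protected areas, density
#'
#' The density surface is a smoothed positive random field rescaled so
#' its raster sum equals the configured abundance; protected areas are
#' non-overlapping rectangles inside the region; country sub-regions
#' partition the region by longitude.
#'
#' @param cfg A [scenario_config()].
#' @return List: `spec`, `region_polygon`, `country_polygons`,
#'   `pa_polygons` (ring-matrix features), `region_mask`,
#'   `country_masks`, `pa_mask` (rasters), `density`
#'   (a `density_surface`) and `truth` (abundance, PA extent in cells,
#'   country cell counts).
#' @export
simulate_landscape <- function(cfg) {
  spec <- scenario_spec(cfg)
  frame <- scenario_frame(cfg)
  set.seed(sub_seed(cfg$seed, 1))
  b <- cfg$bounds
  region <- rect_ring(b[1], b[2], b[3], b[4])
  # Country partition by longitude cuts.
  cuts <- b[1] + cumsum(c(0, cfg$country_shares)) * (b[3] - b[1])
  country_polygons <- lapply(seq_along(cfg$country_shares), function(i)
    list(rect_ring(cuts[i], b[2], cuts[i + 1], b[4])))
  names(country_polygons) <- names(cfg$country_shares)
  # Non-overlapping rectangular PAs by rejection sampling.
  deg_x <- function(km) km / frame$k_lon
  deg_y <- function(km) km / frame$k_lat
  pa <- list(); tries <- 0
  while (length(pa) < cfg$n_protected_areas && tries < 2000) {
    tries <- tries + 1
    w <- stats::runif(1, cfg$pa_size_km[1], cfg$pa_size_km[2])
    h <- stats::runif(1, cfg$pa_size_km[1], cfg$pa_size_km[2])
    x0 <- stats::runif(1, b[1], b[3] - deg_x(w))
    y0 <- stats::runif(1, b[2], b[4] - deg_y(h))
    cand <- c(x0, y0, x0 + deg_x(w), y0 + deg_y(h))
    clash <- any(vapply(pa, function(p)
      cand[1] < p[3] && cand[3] > p[1] && cand[2] < p[4] && cand[4] > p[2],
      TRUE))
    if (!clash) pa[[length(pa) + 1L]] <- cand
  }
  if (length(pa) < cfg$n_protected_areas)
    ft_stop("could not place the requested protected areas in the region",
            "config_error")
  pa_polygons <- lapply(pa, function(p) list(rect_ring(p[1], p[2], p[3], p[4])))
  names(pa_polygons) <- sprintf("pa_%02d", seq_along(pa_polygons))
  region_mask <- rasterize_polygons(list(region), spec)
  country_masks <- lapply(country_polygons, rasterize_polygons, spec = spec)
  pa_mask <- rasterize_polygons(pa_polygons, spec)
  # Smoothed positive field, zero outside the region, rescaled.
  raw <- matrix(stats::rexp(spec$n_rows * spec$n_cols),
                spec$n_rows, spec$n_cols)
  sd_cells <- cfg$density_corr_km / (spec$resolution * frame$k_lat)
  f <- smooth_field(raw, sd_cells) * region_mask$values
  f <- f / sum(f) * cfg$abundance
  dens <- structure(list(raster = grid_raster(spec, f, kind = "density"),
                         total = sum(f)),
                    class = "density_surface")
  list(spec = spec, frame = frame,
       region_polygon = list(region = list(region)),
       country_polygons = country_polygons,
       pa_polygons = pa_polygons,
       region_mask = region_mask, country_masks = country_masks,
       pa_mask = pa_mask, density = dens,
       truth = list(abundance = cfg$abundance,
                    pa_cells = sum(pa_mask$values),
                    country_cells = vapply(country_masks,
                                           function(m) sum(m$values), 0)))
}

# Gamma scale such that P(300 + Gamma(shape, scale) <= 325) = share.
brightness_scale <- function(share, shape) {
  if (share <= 0) return(NA_real_)
  stats::uniroot(function(s) stats::pgamma(25, shape = shape, scale = s) - share,
                 c(1e-3, 1e4), tol = 1e-10)$root
}

#' Simulate one fire season of active-fire detections
#'
#' Ignition centres fall uniformly in the region; each spawns a Poisson
#' number of detections scattered with a Gaussian of the configured
#' spread; dates concentrate in the dry season; brightness is 300 K plus
#' a Gamma excess whose scale is solved so the configured share falls
#' below the 325 K occurrence threshold.
#'
#' @param cfg A [scenario_config()].
#' @param year Calendar year to stamp on the detections.
#' @return List: `detections` (data frame with `longitude`, `latitude`,
#'   `acq_date`, `brightness`, `confidence` — the dialect the reader
#'   expects) and `truth` (`occurrence`: the oracle occurrence raster
#'   from supra-threshold detections; `n_supra`).
#' @export
simulate_fire_season <- function(cfg, year) {
  spec <- scenario_spec(cfg)
  frame <- scenario_frame(cfg)
  set.seed(sub_seed(cfg$seed, 1000 + year))
  b <- cfg$bounds
  n_ign <- stats::rpois(1, cfg$n_ignitions)
  if (n_ign == 0 || cfg$n_ignitions == 0) {
    det <- data.frame(longitude = numeric(), latitude = numeric(),
                      acq_date = character(), brightness = numeric(),
                      confidence = numeric())
    occ <- grid_raster(spec, 0, kind = "occurrence")
    return(list(detections = det, truth = list(occurrence = occ, n_supra = 0L)))
  }
  cx <- stats::runif(n_ign, b[1], b[3])
  cy <- stats::runif(n_ign, b[2], b[4])
  nd <- stats::rpois(n_ign, cfg$detections_per_ignition)
  lon <- stats::rnorm(sum(nd), rep(cx, nd), cfg$cluster_spread_km / frame$k_lon)
  lat <- stats::rnorm(sum(nd), rep(cy, nd), cfg$cluster_spread_km / frame$k_lat)
  doy <- pmin(pmax(round(stats::rnorm(sum(nd), cfg$season_mean_doy,
                                      cfg$season_sd_doy)), 1),
              if (is_leap(year)) 366 else 365)
  dates <- as.Date(doy - 1, origin = as.Date(sprintf("%d-01-01", year)))
  n <- sum(nd)
  sub <- stats::runif(n) < cfg$subthreshold_share
  bright <- numeric(n)
  if (cfg$subthreshold_share > 0) {
    sc <- brightness_scale(cfg$subthreshold_share, cfg$brightness_shape)
    excess <- stats::rgamma(n, shape = cfg$brightness_shape, scale = sc)
    # Condition each detection on its side of the threshold so the share
    # below 325 K is exact-in-expectation and seed-stable.
    u <- stats::runif(n)
    p25 <- stats::pgamma(25, cfg$brightness_shape, scale = sc)
    q <- ifelse(sub, u * p25, p25 + u * (1 - p25))
    bright <- 300 + stats::qgamma(q, cfg$brightness_shape, scale = sc)
  } else {
    bright <- 325 + 1e-6 + stats::rgamma(n, shape = cfg$brightness_shape,
                                         scale = 12)
  }
  det <- data.frame(longitude = lon, latitude = lat,
                    acq_date = format(dates, "%Y-%m-%d"),
                    brightness = bright,
                    confidence = round(stats::runif(n, 50, 100)))
  supra <- det$brightness > 325
  idx <- point_to_cell(spec, lon[supra], lat[supra])
  occ <- matrix(0, spec$n_rows, spec$n_cols)
  keep <- !is.na(idx$row)
  occ[cbind(idx$row[keep], idx$col[keep])] <- 1
  list(detections = det,
       truth = list(occurrence = grid_raster(spec, occ, kind = "occurrence"),
                    n_supra = sum(supra)))
}

#' Simulate OU tracks with known home-range parameters
#'
#' Each individual gets a range centre inside the region (kept clear of
#' the edges), OU parameters drawn from the configured ranges, and an
#' exact-transition OU sample at the configured fix schedule, converted
#' to lon/lat through the scenario frame.
#'
#' @param cfg A [scenario_config()].
#' @return List: `tracks` (named list of raw data frames with
#'   `timestamp`, `lon`, `lat` — [clean_track()] input) and `truth`
#'   (per-individual data frame: `id`, `mu_lon`, `mu_lat`, `sigma2`,
#'   `tau`).
#' @export
simulate_ou_tracks <- function(cfg) {
  frame <- scenario_frame(cfg)
  b <- cfg$bounds
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  times <- seq(0, cfg$track_span_days, by = cfg$track_dt_days)
  tracks <- list(); truth <- list()
  for (i in seq_len(cfg$n_individuals)) {
    set.seed(sub_seed(cfg$seed, 2000 + i))
    sigma2 <- stats::runif(1, cfg$sigma2_range[1], cfg$sigma2_range[2])
    tau <- stats::runif(1, cfg$tau_range[1], cfg$tau_range[2])
    margin_x <- 4 * sqrt(sigma2) / frame$k_lon
    margin_y <- 4 * sqrt(sigma2) / frame$k_lat
    mu_lon <- stats::runif(1, b[1] + margin_x, b[3] - margin_x)
    mu_lat <- stats::runif(1, b[2] + margin_y, b[4] - margin_y)
    xy <- simulate_ou(times, mu = c(0, 0), sigma2 = sigma2, tau = tau)
    id <- sprintf("ind_%02d", i)
    tracks[[id]] <- data.frame(
      timestamp = t0 + times * 86400,
      lon = mu_lon + xy[, 1] / frame$k_lon,
      lat = mu_lat + xy[, 2] / frame$k_lat)
    truth[[id]] <- data.frame(id = id, mu_lon = mu_lon, mu_lat = mu_lat,
                              sigma2 = sigma2, tau = tau)
  }
  list(tracks = tracks, truth = do.call(rbind, truth))
}

# Exact cell masses of a bivariate normal on a grid (degrees, via frame).
gaussian_cell_pmf <- function(spec, mu_lon, mu_lat, sigma2, frame) {
  res <- spec$resolution
  sdx <- sqrt(sigma2) / frame$k_lon
  sdy <- sqrt(sigma2) / frame$k_lat
  xe <- spec$origin_lon + (0:spec$n_cols) * res
  ye <- spec$origin_lat - (0:spec$n_rows) * res
  px <- diff(stats::pnorm(xe, mu_lon, sdx))
  py <- -diff(stats::pnorm(ye, mu_lat, sdy))
  m <- outer(py, px)
  m / sum(m)
}

#' Fires placed on a known fraction of each range's mass
#'
#' For a placement-controlled scenario: computes each individual's true
#' (closed-form) range mass per cell, takes top cells until the covered
#' mass is as close to `q` as the cell discretization allows, and emits
#' one supra-threshold detection at each cell centre. The oracle mass
#' actually covered (within half a cell's mass of `q`) is recorded per
#' individual.
#'
#' @param cfg A [scenario_config()] with `target_burn_fraction` set.
#' @param truth The `truth` data frame from [simulate_ou_tracks()].
#' @param year Calendar year for the detection dates.
#' @return List: `detections` (reader-dialect data frame) and `truth`
#'   (data frame `id`, `mass_covered`; plus `occurrence` raster).
#' @export
placement_fires <- function(cfg, truth, year) {
  q <- cfg$target_burn_fraction
  if (is.null(q)) ft_stop("target_burn_fraction is not set", "config_error")
  spec <- scenario_spec(cfg)
  frame <- scenario_frame(cfg)
  occ <- matrix(0, spec$n_rows, spec$n_cols)
  covered <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    m <- gaussian_cell_pmf(spec, truth$mu_lon[i], truth$mu_lat[i],
                           truth$sigma2[i], frame)
    o <- order(as.vector(m), decreasing = TRUE)
    cs <- cumsum(m[o])
    k <- which(cs >= q)[1]
    if (k > 1 && abs(cs[k - 1] - q) < abs(cs[k] - q)) k <- k - 1
    occ[o[seq_len(k)]] <- 1
    covered[i] <- cs[k]
  }
  cells <- which(occ > 0)
  rr <- (cells - 1) %% spec$n_rows + 1
  cc <- (cells - 1) %/% spec$n_rows + 1
  ctr <- cell_centres(spec)
  det <- data.frame(longitude = ctr$lon[cc], latitude = ctr$lat[rr],
                    acq_date = sprintf("%d-08-15", year),
                    brightness = 352.3, confidence = 100)
  list(detections = det,
       truth = list(per_individual = data.frame(id = truth$id,
                                                mass_covered = covered),
                    occurrence = grid_raster(spec, occ, kind = "occurrence")))
}

#' Generate and persist a complete scenario bundle
#'
#' Writes every layer in the same public plain-text formats the real
#' pipeline reads — density as ESRI ASCII grid, region/country/PA
#' polygons as GeoJSON, fire seasons as FIRMS-dialect CSV, tracks as a
#' Movebank-dialect CSV — plus a ground-truth JSON and a MANIFEST with
#' seed and per-file checksums, so the synthetic path exercises the real
#' readers end to end.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory? Default `FALSE`
#'   (refusal error).
#' @return The directory path, invisibly; side effect: files on disk.
#' @export
make_scenario <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    ft_stop("output directory exists and is not empty (use force = TRUE)",
            "refusal_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "fires"), showWarnings = FALSE)
  land <- simulate_landscape(cfg)
  write_ascii_grid(land$density$raster, file.path(dir, "density.asc"))
  write_geojson_polygons(c(land$region_polygon, land$country_polygons),
                         file.path(dir, "regions.geojson"))
  write_geojson_polygons(land$pa_polygons,
                         file.path(dir, "protected_areas.geojson"))
  tr <- simulate_ou_tracks(cfg)
  track_rows <- do.call(rbind, lapply(names(tr$tracks), function(id) {
    d <- tr$tracks[[id]]
    data.frame(`individual-local-identifier` = id,
               timestamp = format(d$timestamp, "%Y-%m-%d %H:%M:%S"),
               `location-long` = d$lon, `location-lat` = d$lat,
               check.names = FALSE)
  }))
  utils::write.csv(track_rows, file.path(dir, "tracks.csv"),
                   row.names = FALSE, quote = FALSE)
  burn_truth <- list()
  placement_truth <- NULL
  last <- max(cfg$years)
  for (y in cfg$years) {
    if (!is.null(cfg$target_burn_fraction) && y == last) {
      fs <- placement_fires(cfg, tr$truth, y)
      placement_truth <- fs$truth$per_individual
    } else {
      fs <- simulate_fire_season(cfg, y)
    }
    utils::write.csv(fs$detections,
                     file.path(dir, "fires", sprintf("fires_%d.csv", y)),
                     row.names = FALSE, quote = FALSE)
    occ <- fs$truth$occurrence
    burn_truth[[as.character(y)]] <- list(
      burned_cells = sum(occ$values),
      burned_fraction_region =
        sum(occ$values * land$region_mask$values) /
        sum(land$region_mask$values),
      abundance_in_burned_cells =
        sum(occ$values * land$density$raster$values))
  }
  gt <- list(seed = cfg$seed,
             abundance = land$truth$abundance,
             pa_cells = land$truth$pa_cells,
             country_cells = as.list(land$truth$country_cells),
             individuals = tr$truth,
             fire_years = burn_truth,
             placement = placement_truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- setdiff(list.files(dir, recursive = TRUE), "MANIFEST.json")
  manifest <- list(seed = cfg$seed,
                   created = "synthetic scenario bundle",
                   files = lapply(stats::setNames(files, files), function(f)
                     unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
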
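#' Local metric frame for a tracked individual
#'
#' Telemetry arrives in lon/lat but movement models work in a planar km
#' frame. The frame used here is a local equirectangular projection about
#' `(lon0, lat0)`: x = (lon - lon0) * 111.320 * cos(lat0) km, y =
#' (lat - lat0) * 110.574 km. Being affine, it maps a lon/lat grid exactly
#' onto a km grid, so kernel masses integrate exactly over cell edges; at
#' home-range scale (tens of km) its distortion relative to an azimuthal
#' projection is negligible.
#'
#' @param lon0,lat0 Frame origin in degrees (conventionally the track
#'   centroid).
#' @return A list `lon0`, `lat0`, `k_lon`, `k_lat` (km per degree).
#' @export
local_frame <- function(lon0, lat0) {
  list(lon0 = lon0, lat0 = lat0,
       k_lon = 111.320 * cos(lat0 * pi / 180),
       k_lat = 110.574)
}

#' @rdname local_frame
#' @param lon,lat Coordinates to project.
#' @param frame A frame from [local_frame()].
#' @return For `project_lonlat`, a list `x`, `y` in km.
#' @export
project_lonlat <- function(lon, lat, frame) {
  list(x = (lon - frame$lon0) * frame$k_lon,
       y = (lat - frame$lat0) * frame$k_lat)
}

#' @rdname local_frame
#' @param x,y Planar km coordinates to invert.
#' @return For `unproject_xy`, a list `lon`, `lat` in degrees.
#' @export
unproject_xy <- function(x, y, frame) {
  list(lon = frame$lon0 + x / frame$k_lon,
       lat = frame$lat0 + y / frame$k_lat)
}

#' Read GPS tracks from a Movebank-style CSV
#'
#' @param path CSV with one row per relocation.
#' @param columns Named list mapping `id`, `timestamp`, `lon`, `lat` to
#'   column names in the file.
#' @return Named list (by individual id) of raw data frames with columns
#'   `timestamp` (POSIXct, UTC), `lon`, `lat`, ready for [clean_track()].
#' @export
read_tracks <- function(path,
                        columns = list(id = "individual-local-identifier",
                                       timestamp = "timestamp",
                                       lon = "location-long",
                                       lat = "location-lat")) {
  if (!file.exists(path)) ft_stop(paste("no such file:", path), "format_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unlist(columns), names(raw))
  if (length(miss))
    ft_stop(paste("missing column(s):", paste(miss, collapse = ", ")),
            "format_error")
  d <- data.frame(id = as.character(raw[[columns$id]]),
                  timestamp = as.POSIXct(raw[[columns$timestamp]], tz = "UTC"),
                  lon = as.numeric(raw[[columns$lon]]),
                  lat = as.numeric(raw[[columns$lat]]))
  split(d[c("timestamp", "lon", "lat")], d$id)
}

#' Clean a raw relocation table into a track
#'
#' Sorts by time, drops rows with missing fields, collapses duplicate
#' timestamps (first kept), projects lon/lat into a per-individual local
#' km frame, and records what was removed.
#'
#' @param raw Data frame with `timestamp` (POSIXct or numeric days) and
#'   either `lon`/`lat` (degrees) or `x`/`y` (km).
#' @param id Individual identifier carried on the result.
#' @param frame Optional [local_frame()]; default centres on the mean
#'   coordinate. Ignored when `raw` already carries `x`/`y`.
#' @return An object of class `track`: data frame with `t` (days from
#'   first fix), `x`, `y` (km), with attributes `id`, `frame`,
#'   `span_days`, and `removals` (duplicates/incomplete rows dropped).
#' @export
clean_track <- function(raw, id = "animal", frame = NULL) {
  if (nrow(raw) < 2) ft_stop("fewer than 2 relocations", "insufficient_data")
  has_xy <- all(c("x", "y") %in% names(raw))
  cols <- if (has_xy) c("x", "y") else c("lon", "lat")
  if (!all(c("timestamp", cols) %in% names(raw)))
    ft_stop("raw track must have timestamp plus lon/lat or x/y",
            "format_error")
  tnum <- if (inherits(raw$timestamp, "POSIXct"))
    as.numeric(raw$timestamp) / 86400 else as.numeric(raw$timestamp)
  ok <- is.finite(tnum) & is.finite(raw[[cols[1]]]) & is.finite(raw[[cols[2]]])
  n_incomplete <- sum(!ok)
  d <- raw[ok, , drop = FALSE]; tnum <- tnum[ok]
  o <- order(tnum)
  d <- d[o, , drop = FALSE]; tnum <- tnum[o]
  dup <- duplicated(tnum)
  n_dup <- sum(dup)
  d <- d[!dup, , drop = FALSE]; tnum <- tnum[!dup]
  if (nrow(d) < 2) ft_stop("fewer than 2 usable relocations", "insufficient_data")
  if (has_xy) {
    x <- d$x; y <- d$y
  } else {
    if (is.null(frame)) frame <- local_frame(mean(d$lon), mean(d$lat))
    p <- project_lonlat(d$lon, d$lat, frame)
    x <- p$x; y <- p$y
  }
  out <- data.frame(t = tnum - tnum[1], x = x, y = y)
  attr(out, "id") <- id
  attr(out, "frame") <- frame
  attr(out, "span_days") <- out$t[nrow(out)]
  attr(out, "removals") <- list(incomplete = n_incomplete, duplicates = n_dup)
  class(out) <- c("track", "data.frame")
  out
}

#' Empirical semi-variogram of a track
#'
#' Semivariance of displacement as a function of time lag:
#' gamma(lag) = mean(|r(t + lag) - r(t)|^2) / (2 * dims). For a
#' range-resident animal gamma approaches the positional variance
#' sigma^2 as the lag grows (an asymptote); for a drifting or dispersing
#' one it keeps rising.
#'
#' @param track A [clean_track()] result.
#' @param lag_width Bin width in days (default: median sampling interval).
#' @param max_lag Largest lag in days (default: half the sampling span).
#' @return An object of class `variogram`: data frame with `lag` (bin
#'   centre, days), `gamma` (km² per axis) and `n_pairs`.
#' @export
empirical_variogram <- function(track, lag_width = NULL, max_lag = NULL) {
  semivariance(track$t, cbind(track$x, track$y), lag_width, max_lag)
}

# Core semivariance over index offsets; works for any coordinate
# dimensionality (1-D used in hand-check tests).
semivariance <- function(t, xy, lag_width = NULL, max_lag = NULL) {
  xy <- as.matrix(xy)
  n <- length(t)
  dt <- diff(t)
  med_dt <- stats::median(dt)
  if (is.null(lag_width)) lag_width <- med_dt
  if (is.null(max_lag)) max_lag <- (t[n] - t[1]) / 2
  kmax <- min(n - 1L, max(1L, ceiling(max_lag / med_dt * 1.5)))
  lag_l <- vector("list", kmax); sq_l <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    dlag <- t[(1 + k):n] - t[1:(n - k)]
    keep <- dlag <= max_lag + lag_width / 2
    if (!any(keep)) next
    disp <- xy[(1 + k):n, , drop = FALSE] - xy[1:(n - k), , drop = FALSE]
    lag_l[[k]] <- dlag[keep]
    sq_l[[k]] <- rowSums(disp * disp)[keep]
  }
  lags <- unlist(lag_l); sq <- unlist(sq_l)
  if (!length(lags)) ft_stop("no displacement pairs in any lag bin",
                             "insufficient_data")
  bin <- floor(lags / lag_width)
  gamma <- tapply(sq, bin, mean) / (2 * ncol(xy))
  npairs <- tapply(sq, bin, length)
  centres <- (as.numeric(names(gamma)) + 0.5) * lag_width
  out <- data.frame(lag = centres, gamma = as.numeric(gamma),
                    n_pairs = as.integer(npairs))
  rownames(out) <- NULL
  class(out) <- c("variogram", "data.frame")
  out
}

# Profile log-likelihood machinery for the isotropic OU position model.
# Exact transition: x(t+dt) = mu + phi (x(t) - mu) + e, phi = exp(-dt/tau),
# var(e) = sigma^2 (1 - phi^2) per axis; stationary start x(0) ~ N(mu, sigma^2).
# For fixed tau, mu (per axis) and the shared sigma^2 have closed-form MLEs.
ou_profile <- function(log_tau, t, xy) {
  tau <- exp(log_tau)
  n <- length(t)
  phi <- exp(-diff(t) / tau)
  a <- c(1, 1 - phi)                 # design coefficient on mu
  v <- c(1, 1 - phi^2)               # relative variance
  v <- pmax(v, 1e-12)
  rss <- 0
  mu <- numeric(ncol(xy))
  for (ax in seq_len(ncol(xy))) {
    x <- xy[, ax]
    z <- c(x[1], x[-1] - phi * x[-n])
    mu[ax] <- sum(a * z / v) / sum(a^2 / v)
    rss <- rss + sum((z - a * mu[ax])^2 / v)
  }
  d <- ncol(xy)
  sigma2 <- rss / (d * n)
  ll <- -0.5 * d * n * log(2 * pi * sigma2) - 0.5 * d * sum(log(v)) -
    0.5 * d * n
  list(loglik = ll, mu = mu, sigma2 = sigma2, tau = tau)
}

#' Fit an Ornstein-Uhlenbeck position model to a track
#'
#' Maximum-likelihood fit of the isotropic OU (range-resident) movement
#' model under its exact discrete-time transition, so irregular sampling
#' needs no interpolation. The mean location and spatial variance are
#' profiled in closed form; the position autocorrelation timescale
#' `tau_home` is found by 1-D optimisation of the profile likelihood.
#' `dof_area` — the effective number of home-range crossings — is the
#' sampling span divided by `tau_home`.
#'
#' @param track A [clean_track()] result.
#' @return An object of class `movement_fit`: `mu` (km, 2-vector),
#'   `sigma2` (km² per axis), `tau` (days), `loglik`, `dof_area`,
#'   `span_days`, `n`, and `flagged` (`TRUE` when the optimiser hit a
#'   timescale bound — e.g. a white-noise-like track driving tau to 0).
#' @export
fit_ou <- function(track) {
  t <- track$t
  if (length(unique(t)) < 2) ft_stop("track needs >= 2 distinct times",
                                     "insufficient_data")
  xy <- cbind(track$x, track$y)
  span <- t[length(t)] - t[1]
  dt_min <- min(diff(t))
  lo <- log(dt_min / 50); hi <- log(span * 50)
  opt <- stats::optimize(function(lt) ou_profile(lt, t, xy)$loglik,
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  prof <- ou_profile(opt$maximum, t, xy)
  # A timescale below the sampling interval is unresolvable (white-noise
  # limit), one beyond the span indistinguishable from drift: both flagged.
  flagged <- !is.finite(prof$loglik) || prof$tau < dt_min ||
    prof$tau > span * 10 ||
    opt$maximum < lo + 0.01 * (hi - lo) ||
    opt$maximum > hi - 0.01 * (hi - lo)
  structure(list(mu = prof$mu, sigma2 = prof$sigma2, tau = prof$tau,
                 loglik = prof$loglik, dof_area = span / prof$tau,
                 span_days = span, n = length(t), flagged = flagged),
            class = "movement_fit")
}

#' @export
print.movement_fit <- function(x, ...) {
  cat(sprintf(
    "movement_fit: mu (%.2f, %.2f) km, sigma2 %.3f km2, tau %.2f d, DOF_area %.1f%s\n",
    x$mu[1], x$mu[2], x$sigma2, x$tau, x$dof_area,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Likelihood-ratio confidence interval for the OU timescale
#'
#' Profile-likelihood interval: the set of `tau` whose profile
#' log-likelihood lies within `qchisq(level, 1) / 2` of the maximum.
#'
#' @param track The fitted track.
#' @param fit Its [fit_ou()] result.
#' @param level Coverage level (default 0.95).
#' @return Numeric `c(lower, upper)` in days; infinite bounds when the
#'   likelihood never drops below the cutoff inside the search range.
#' @export
ou_tau_ci <- function(track, fit, level = 0.95) {
  t <- track$t; xy <- cbind(track$x, track$y)
  cut <- fit$loglik - stats::qchisq(level, 1) / 2
  f <- function(lt) ou_profile(lt, t, xy)$loglik - cut
  l0 <- log(fit$tau)
  span <- fit$span_days
  lo_lim <- log(min(diff(t)) / 100); hi_lim <- log(span * 100)
  lower <- if (f(lo_lim) > 0) 0 else
    exp(stats::uniroot(f, c(lo_lim, l0), tol = 1e-7)$root)
  upper <- if (f(hi_lim) > 0) Inf else
    exp(stats::uniroot(f, c(l0, hi_lim), tol = 1e-7)$root)
  c(lower = lower, upper = upper)
}

#' Classify range residency
#'
#' An individual is called resident when either criterion fires:
#' `dof_area > dof_threshold` (enough home-range crossings sampled,
#' default > 5), or its semi-variogram has reached an asymptote. The
#' asymptote rule is quantitative: restricting to the reliable lower half
#' of the lag range, the growth of mean gamma from the middle third of
#' lags to the final third — expressed per lag-decade and relative to the
#' plateau (the final-third mean) — must be below `slope_threshold`. A
#' rising variogram (drift or dispersal) gives growth of order 1 per
#' decade; a plateaued one fluctuates around 0.
#'
#' @param fit A [fit_ou()] result.
#' @param variogram An [empirical_variogram()] of the same track.
#' @param dof_threshold Residency threshold on `dof_area` (default 5).
#' @param slope_threshold Relative slope per lag-decade below which the
#'   variogram counts as asymptotic (default 0.1).
#' @param manual_override `NA` (default) to use the rules; `TRUE`/`FALSE`
#'   to force the verdict (expert judgement), recorded as such.
#' @return An object of class `residency_status`: `verdict` ("resident" /
#'   "non-resident"), `criteria` (named logicals `dof_rule`,
#'   `asymptote_rule`, `manual`), and `diagnostics`.
#' @export
classify_residency <- function(fit, variogram, dof_threshold = 5,
                               slope_threshold = 0.1,
                               manual_override = NA) {
  dof_rule <- is.finite(fit$dof_area) && fit$dof_area > dof_threshold &&
    !fit$flagged
  v <- variogram[variogram$lag <= max(variogram$lag) / 2 &
                   variogram$n_pairs >= 1, , drop = FALSE]
  rel_slope <- NA_real_
  asymptote_rule <- FALSE
  mx <- max(v$lag)
  late <- v$lag >= mx * 2 / 3
  mid <- v$lag >= mx / 3 & v$lag < mx * 2 / 3
  if (sum(late) >= 2 && sum(mid) >= 2) {
    plateau <- mean(v$gamma[late])
    if (plateau <= 0) {
      asymptote_rule <- TRUE; rel_slope <- 0
    } else {
      growth <- (plateau - mean(v$gamma[mid])) / plateau
      decades <- log10(mean(v$lag[late]) / mean(v$lag[mid]))
      rel_slope <- growth / decades
      asymptote_rule <- rel_slope < slope_threshold
    }
  }
  if (!is.na(manual_override)) {
    verdict <- if (manual_override) "resident" else "non-resident"
  } else {
    verdict <- if (dof_rule || asymptote_rule) "resident" else "non-resident"
  }
  structure(list(verdict = verdict,
                 criteria = c(dof_rule = dof_rule,
                              asymptote_rule = asymptote_rule,
                              manual = !is.na(manual_override)),
                 diagnostics = list(dof_area = fit$dof_area,
                                    rel_slope = rel_slope,
                                    flagged_fit = fit$flagged)),
            class = "residency_status")
}

#' @export
print.residency_status <- function(x, ...) {
  cat(sprintf("residency: %s (DOF_area %.1f, rel. variogram slope %.3f)\n",
              x$verdict, x$diagnostics$dof_area, x$diagnostics$rel_slope))
  invisible(x)
}

#' Simulate an OU track by its exact transition
#'
#' @param times Sampling times in days (sorted; may be irregular).
#' @param mu Centre of attraction, km (2-vector for x/y).
#' @param sigma2 Stationary variance per axis, km².
#' @param tau Position autocorrelation timescale, days.
#' @return Matrix with one column per axis (km); one row per time.
#' @export
simulate_ou <- function(times, mu = c(0, 0), sigma2 = 1, tau = 10) {
  n <- length(times)
  d <- length(mu)
  out <- matrix(NA_real_, n, d)
  sd0 <- sqrt(sigma2)
  out[1, ] <- stats::rnorm(d, mu, sd0)
  if (n > 1) {
    phi <- exp(-diff(times) / tau)
    sde <- sqrt(sigma2 * (1 - phi^2))
    for (i in 2:n)
      out[i, ] <- mu + phi[i - 1] * (out[i - 1, ] - mu) +
        stats::rnorm(d, 0, sde[i - 1])
  }
  out
}
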
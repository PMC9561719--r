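# Shared fixtures and independent oracles, all built in code.

small_spec <- function(n = 10, res = 1, cell_area = 1) {
  grid_spec(0, n * res, n, n, res, cell_area)
}

random_raster <- function(spec, kind = "generic",
                          gen = function(n) stats::runif(n)) {
  v <- gen(spec$n_rows * spec$n_cols)
  grid_raster(spec, matrix(v, spec$n_rows, spec$n_cols), kind = kind)
}

random_mask <- function(spec, p = 0.5) {
  v <- as.numeric(stats::runif(spec$n_rows * spec$n_cols) < p)
  grid_raster(spec, matrix(v, spec$n_rows, spec$n_cols), kind = "mask")
}

# Compensated (Kahan) summation: the arbitrary-precision stand-in oracle.
kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

# Per-cell loop oracle for overlay products.
loop_product <- function(a, b) {
  out <- matrix(NA_real_, nrow(a$values), ncol(a$values))
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out)))
      out[i, j] <- a$values[i, j] * b$values[i, j]
  out
}

# Minimal fire_year built directly from matrices (bypasses detection
# binning; used to test overlay stages in isolation).
fy_from_matrices <- function(spec, occ, intens = NULL, year = 2020) {
  if (is.null(intens)) intens <- occ * 340
  structure(list(year = year,
                 occurrence = grid_raster(spec, occ, kind = "occurrence"),
                 intensity = grid_raster(spec, intens, kind = "intensity"),
                 n_detections_used = NA_integer_, aggregate = "max"),
            class = "fire_year")
}

# OU track in plain km coordinates (no lon/lat frame).
ou_track_km <- function(n = 2000, dt = 0.15, sigma2 = 4, tau = 10,
                        mu = c(0, 0), id = "sim") {
  times <- seq(0, by = dt, length.out = n)
  xy <- simulate_ou(times, mu = mu, sigma2 = sigma2, tau = tau)
  clean_track(data.frame(timestamp = times, x = xy[, 1], y = xy[, 2]),
              id = id)
}

expect_raster_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
}
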
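# A deterministic home range on a km grid, built without fitting:
# hand-assembled pmf rasters keep overlay tests exact.
hr_from_pmf <- function(pmf, level = 0.95, id = "hr") {
  s <- firetrack:::hdr_support(pmf, level)
  structure(list(id = id, pmf = pmf, hdr = s$mask, area_km2 = s$area_km2,
                 bandwidth_km = NA_real_, level = level, fit = NULL),
            class = "home_range")
}

test_that("estimated pmfs normalize to one and ignore duplicate weighting", {
  set.seed(23)
  tr <- ou_track_km(n = 600, dt = 0.25, sigma2 = 4, tau = 5)
  fit <- fit_ou(tr)
  spk <- make_grid(c(-10, -10, 10, 10), 0.5, cell_area = 0.25)
  hr <- estimate_pmf(tr, fit, spk, frame = NULL)
  expect_lt(abs(raster_sum(hr$pmf) - 1), 1e-9)
  expect_true(all(hr$pmf$values >= 0))
  # duplicating every relocation leaves the pmf unchanged
  dup <- clean_track(data.frame(
    timestamp = c(tr$t, tr$t + 1e-7), x = c(tr$x, tr$x), y = c(tr$y, tr$y)))
  hr2 <- estimate_pmf(dup, fit, spk, frame = NULL)
  expect_equal(hr2$pmf$values, hr$pmf$values, tolerance = 1e-9)
})

test_that("non-resident fits are refused", {
  set.seed(24)
  tr <- ou_track_km(n = 200, dt = 0.25, sigma2 = 4, tau = 5)
  fit <- fit_ou(tr)
  vg_rise <- structure(data.frame(lag = 1:30, gamma = (1:30) * 0.5,
                                  n_pairs = 50L),
                       class = c("variogram", "data.frame"))
  st <- classify_residency(structure(list(dof_area = 2, flagged = FALSE),
                                     class = "movement_fit"), vg_rise)
  spk <- make_grid(c(-10, -10, 10, 10), 0.5)
  expect_error(estimate_pmf(tr, fit, spk, residency = st, frame = NULL),
               class = "non_resident_error")
})

test_that("HDR accumulation matches constructions and a brute-force oracle", {
  sp <- small_spec(10)
  uni <- grid_raster(sp, 0.01, kind = "weight")
  a <- hdr_area(uni, 0.95)
  expect_equal(a$area_km2, 95)
  single <- matrix(0, 10, 10); single[5, 5] <- 1
  expect_equal(hdr_area(grid_raster(sp, single, kind = "weight"), 0.5)$area_km2, 1)
  # random pmf vs independent subset-accumulation oracle
  set.seed(25)
  v <- stats::rexp(100); v <- v / sum(v)
  pmf <- grid_raster(sp, matrix(v, 10, 10), kind = "weight")
  got <- hdr_area(pmf, 0.8)
  s <- sort(as.vector(pmf$values), decreasing = TRUE)
  k <- 0; acc <- 0
  while (acc < 0.8) { k <- k + 1; acc <- acc + s[k] }
  expect_equal(got$area_km2, k)
  expect_equal(raster_sum(overlay_product(got$mask, pmf)) >= 0.8, TRUE)
})

test_that("home-range burn fractions equal the pmf mass on fire cells", {
  sp <- small_spec(10)
  set.seed(26)
  v <- stats::rexp(100); v <- v / sum(v)
  pmf <- grid_raster(sp, matrix(v, 10, 10), kind = "weight")
  hr <- hr_from_pmf(pmf)
  # fire over all support
  expect_equal(hr_burn(hr, fy_from_matrices(sp, matrix(1, 10, 10)))$burn_fraction, 1)
  # fire over cells holding a known mass q: pick cells until 40%
  o <- order(v); acc <- cumsum(v[o])
  sel <- o[acc <= 0.4]
  q <- sum(v[sel])
  occ <- matrix(0, 10, 10); occ[sel] <- 1
  rec <- hr_burn(hr, fy_from_matrices(sp, occ))
  expect_equal(rec$burn_fraction, q, tolerance = 1e-12)
  expect_equal(rec$burned_km2, q * hr$area_km2)
  # no fire: zero fraction, undefined intensity
  rec0 <- hr_burn(hr, fy_from_matrices(sp, matrix(0, 10, 10)))
  expect_equal(rec0$burn_fraction, 0)
  expect_true(is.na(rec0$mean_intensity_K))
  # weighted mean intensity equals the loop oracle
  occ2 <- matrix(as.numeric(stats::runif(100) < 0.5), 10, 10)
  intens <- occ2 * stats::runif(100, 330, 360)
  rec2 <- hr_burn(hr, fy_from_matrices(sp, occ2, intens))
  oracle <- sum(v * as.vector(occ2) * as.vector(intens)) /
    sum(v * as.vector(occ2))
  expect_equal(rec2$mean_intensity_K, oracle, tolerance = 1e-12)
})

test_that("triple overlays obey their bounds and match the loop oracle", {
  set.seed(27)
  sp <- small_spec(10)
  for (i in 1:10) {
    v <- stats::rexp(100); v <- v / sum(v)
    pmf <- grid_raster(sp, matrix(v, 10, 10), kind = "weight")
    hr <- hr_from_pmf(pmf)
    pa <- random_mask(sp, 0.4)
    occ <- matrix(as.numeric(stats::runif(100) < 0.3), 10, 10)
    fy <- fy_from_matrices(sp, occ)
    rec <- hr_pa_burn(hr, pa, fy)
    oracle <- 0
    for (r in 1:10) for (c in 1:10)
      oracle <- oracle + pmf$values[r, c] * pa$values[r, c] * occ[r, c]
    expect_equal(rec$pa_burned_km2 / hr$area_km2, oracle, tolerance = 1e-12)
    # triple product below both pairwise overlays
    pair_pa <- sum(pmf$values * pa$values)
    pair_occ <- sum(pmf$values * occ)
    expect_lte(oracle, min(pair_pa, pair_occ) + 1e-12)
    # record invariants
    expect_lte(rec$pa_burned_km2, rec$pa_km2 + 1e-12)
    expect_lte(rec$pa_km2, hr$area_km2 + 1e-9)
    burn <- hr_burn(hr, fy)
    expect_gte(burn$burn_fraction, 0); expect_lte(burn$burn_fraction, 1)
  }
})

test_that("doubling cell area doubles km2 fields and changes no fraction", {
  set.seed(28)
  sp1 <- small_spec(10, cell_area = 1)
  sp2 <- small_spec(10, cell_area = 2)
  v <- stats::rexp(100); v <- v / sum(v)
  occ <- matrix(as.numeric(stats::runif(100) < 0.3), 10, 10)
  pa <- matrix(as.numeric(stats::runif(100) < 0.4), 10, 10)
  hr1 <- hr_from_pmf(grid_raster(sp1, matrix(v, 10, 10), kind = "weight"))
  hr2 <- hr_from_pmf(grid_raster(sp2, matrix(v, 10, 10), kind = "weight"))
  b1 <- hr_burn(hr1, fy_from_matrices(sp1, occ))
  b2 <- hr_burn(hr2, fy_from_matrices(sp2, occ))
  expect_equal(b2$burn_fraction, b1$burn_fraction)
  expect_equal(b2$burned_km2, 2 * b1$burned_km2)
  p1 <- hr_pa_burn(hr1, grid_raster(sp1, pa, kind = "mask"),
                   fy_from_matrices(sp1, occ))
  p2 <- hr_pa_burn(hr2, grid_raster(sp2, pa, kind = "mask"),
                   fy_from_matrices(sp2, occ))
  expect_equal(p2$pa_km2, 2 * p1$pa_km2)
  expect_equal(p2$pa_burn_fraction, p1$pa_burn_fraction)
})

test_that("cohort summaries reproduce the affected-share arithmetic", {
  set.seed(29)
  rec <- data.frame(id = sprintf("j%02d", 1:48), year = 2020,
                    burn_fraction = c(stats::runif(38, 0.05, 1), rep(0, 10)))
  rec$burned_km2 <- rec$burn_fraction * 100
  cs <- cohort_summary(rec)
  expect_equal(cs$n_hr, 48)
  expect_equal(cs$n_affected, 38)
  expect_equal(cs$pct_affected, 79)
  expect_equal(cs$median_burn_fraction_affected,
               stats::median(rec$burn_fraction[rec$burn_fraction > 0]))
  # all zero: nothing affected, median undefined
  z <- cohort_summary(data.frame(burn_fraction = rep(0, 5),
                                 burned_km2 = 0))
  expect_equal(z$n_affected, 0)
  expect_true(is.na(z$median_burn_fraction_affected))
  # random records vs a brute-force summary oracle
  r2 <- data.frame(burn_fraction = stats::runif(20), burned_km2 = stats::runif(20),
                   pa_km2 = stats::runif(20), pa_burned_km2 = stats::runif(20) / 2)
  cs2 <- cohort_summary(r2, affected_threshold = 0.5)
  expect_equal(cs2$n_affected, sum(r2$burn_fraction > 0.5))
  expect_equal(cs2$total_pa_burned_km2, sum(r2$pa_burned_km2))
  expect_equal(cs2$pct_pa_burned,
               round(100 * sum(r2$pa_burned_km2) / sum(r2$pa_km2)))
})

test_that("a large-sample OU range matches the Gaussian closed form", {
  set.seed(30)
  tr <- ou_track_km(n = 4000, dt = 0.1, sigma2 = 1, tau = 0.5)  # span 800 tau
  fit <- fit_ou(tr)
  spk <- make_grid(c(-6, -6, 6, 6), 0.2, cell_area = 0.04)
  hr <- estimate_pmf(tr, fit, spk, frame = NULL)
  ref <- 5.991 * pi * 1                                          # 18.82 km2
  expect_lt(abs(hr$area_km2 - ref) / ref, 0.10)
})
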
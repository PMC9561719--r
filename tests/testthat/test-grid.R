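test_that("make_grid covers the bounding box with the smallest grid", {
  sp <- make_grid(c(0, 0, 1, 1), 0.25)
  expect_equal(c(sp$n_rows, sp$n_cols), c(4L, 4L))
  # non-divisible resolution rounds the shape up
  sp2 <- make_grid(c(0, 0, 1, 1), 0.3)
  expect_equal(c(sp2$n_rows, sp2$n_cols), c(4L, 4L))
  expect_gte(sp2$origin_lat, 1)
  expect_error(make_grid(c(0, 0, 0, 1), 0.25), class = "invalid_geometry")
  expect_error(make_grid(c(0, 0, 1, 1), -1), class = "invalid_geometry")
})

test_that("grid_raster enforces the kind contracts", {
  sp <- small_spec(3)
  expect_error(grid_raster(sp, 0.5, kind = "occurrence"),
               class = "contract_error")
  expect_error(grid_raster(sp, 0.5, kind = "weight"),  # sums to 4.5
               class = "contract_error")
  expect_error(grid_raster(sp, 150, kind = "intensity"),
               class = "contract_error")
  expect_error(grid_raster(sp, -1, kind = "density"),
               class = "contract_error")
  expect_silent(grid_raster(sp, 1 / 9, kind = "weight"))
})

test_that("rasterization: exact cover, centre-rule oracle, empty set", {
  sp <- grid_spec(0, 2, 2, 2, 1)
  square <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  m <- rasterize_polygons(square, sp)
  expect_equal(sum(m$values), 4)

  # centre rule matches brute-force point-in-polygon over all centres
  set.seed(7)
  sp10 <- small_spec(10)
  poly <- cbind(c(1.3, 8.2, 9.1, 4.7, 0.6), c(0.8, 1.9, 7.4, 9.2, 5.1))
  m10 <- rasterize_polygons(poly, sp10)
  cc <- firetrack:::cell_centres(sp10)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    # even-odd ray cast, written independently: count edge crossings
    px <- cc$lon[j]; py <- cc$lat[i]
    ring <- rbind(poly, poly[1, ])
    cross <- 0
    for (k in 1:(nrow(ring) - 1)) {
      y1 <- ring[k, 2]; y2 <- ring[k + 1, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- ring[k, 1] + (py - y1) / (y2 - y1) *
          (ring[k + 1, 1] - ring[k, 1])
        if (px < xint) cross <- cross + 1
      }
    }
    oracle[i, j] <- cross %% 2
  }
  expect_equal(m10$values, oracle)
  expect_warning(out <- rasterize_polygons(list(), sp10),
                 "empty polygon set")
  expect_equal(sum(out$values), 0)
})

test_that("centre-rule membership agrees with an established GIS routine", {
  set.seed(11)
  sp <- small_spec(12)
  poly <- cbind(c(2.2, 10.4, 11.3, 6.1, 1.2, 0.4),
                c(1.1, 0.7, 8.8, 11.6, 10.2, 4.4))
  m <- rasterize_polygons(poly, sp)
  cc <- firetrack:::cell_centres(sp)
  pts <- cbind(rep(cc$lon, each = 12), rep(cc$lat, times = 12))
  ref <- matrix(as.numeric(mgcv::in.out(rbind(poly, poly[1, ]), pts)), 12, 12)
  expect_equal(m$values, ref)
})

test_that("a region polygon of 160,426 cells rasterizes to that mask sum", {
  # L-shaped region: 400 x 400 block plus a 213 x 2 tab = 160,426 km2
  # at 1-km cells with edges on cell boundaries.
  sp <- make_grid(c(0, 0, 613, 400), 1)
  ring <- cbind(c(0, 613, 613, 400, 400, 0),
                c(0, 0, 2, 2, 400, 400))
  m <- rasterize_polygons(ring, sp)
  expect_equal(sum(m$values), 160426)
})

test_that("any-overlap rule is at least as inclusive as the centre rule", {
  sp <- small_spec(8)
  poly <- cbind(c(1.5, 6.5, 6.5, 1.5), c(1.5, 1.5, 6.5, 6.5))
  ctr <- rasterize_polygons(poly, sp, rule = "cell-centre-in")
  ovl <- rasterize_polygons(poly, sp, rule = "any-overlap")
  expect_true(all(ovl$values >= ctr$values))
  expect_gt(sum(ovl$values), sum(ctr$values))  # boundary ring picked up
})

test_that("normalize_mask is proportional and sums to one", {
  sp <- grid_spec(0, 1, 1, 4, 1)
  w <- normalize_mask(grid_raster(sp, matrix(c(2, 1, 1, 0), 1), kind = "generic"))
  expect_equal(as.vector(w$values), c(0.5, 0.25, 0.25, 0))
  u <- normalize_mask(grid_raster(small_spec(2), 1, kind = "mask"))
  expect_equal(as.vector(u$values), rep(0.25, 4))
  expect_error(normalize_mask(grid_raster(small_spec(2), 0, kind = "mask")),
               class = "empty_region_error")
  # property: any positive random mask normalizes to total 1 +/- 1e-9
  set.seed(1)
  for (i in 1:20) {
    r <- random_raster(small_spec(10), gen = function(n) stats::rexp(n))
    expect_lt(abs(raster_sum(normalize_mask(r)) - 1), 1e-9)
  }
})

test_that("overlay_product matches the loop oracle, commutes, stays aligned", {
  set.seed(2)
  sp <- small_spec(10)
  a <- random_raster(sp); b <- random_raster(sp)
  expect_equal(overlay_product(a, b)$values, loop_product(a, b))
  expect_equal(overlay_product(a, b)$values, overlay_product(b, a)$values)
  other <- grid_raster(small_spec(10, res = 0.5), 1)
  expect_error(overlay_product(a, other), class = "alignment_error")
  # weight x occurrence stays within [0, 1]
  for (i in 1:10) {
    w <- normalize_mask(random_raster(sp, gen = stats::rexp))
    f <- random_mask(sp)
    s <- raster_sum(overlay_product(w, f))
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # identity and annihilator
  w <- normalize_mask(random_raster(sp, gen = stats::rexp))
  ones <- grid_raster(sp, 1, kind = "occurrence")
  zeros <- grid_raster(sp, 0, kind = "occurrence")
  expect_raster_equal(overlay_product(w, ones), w)
  expect_equal(raster_sum(overlay_product(w, zeros)), 0)
})

test_that("raster_sum matches compensated summation", {
  set.seed(3)
  sp <- small_spec(30)
  r <- random_raster(sp, gen = function(n) stats::rcauchy(n) * 1e-3)
  expect_lt(abs(raster_sum(r) - kahan_sum(as.vector(r$values))), 1e-9)
  expect_equal(raster_sum(grid_raster(sp, 0)), 0)
})

test_that("resampling: identity, aggregation arithmetic, nearest upsampling", {
  sp <- small_spec(4)
  r <- random_raster(sp, kind = "density", gen = stats::rexp)
  expect_raster_equal(resample_to(r, sp, "area-weighted-mean"), r)
  # 2x2 {1,1,3,3} aggregated to one cell: area-weighted mean 2
  sp2 <- grid_spec(0, 2, 2, 2, 1)
  sp1 <- grid_spec(0, 2, 1, 1, 2, cell_area = 4)
  d <- grid_raster(sp2, matrix(c(1, 1, 3, 3), 2, 2), kind = "density")
  agg <- resample_to(d, sp1, "area-weighted-mean")
  expect_equal(as.vector(agg$values), 2)
  # occurrence 1 cell -> 4 cells nearest: 4 copies
  occ <- grid_raster(sp1, 1, kind = "occurrence")
  up <- resample_to(occ, sp2, "nearest")
  expect_equal(as.vector(up$values), rep(1, 4))
  expect_error(resample_to(occ, sp2, "area-weighted-mean"),
               class = "contract_error")
})

test_that("partitioned masks give additive density-weighted exposure", {
  set.seed(4)
  sp <- small_spec(10)
  left <- grid_raster(sp, matrix(rep(c(1, 0), times = c(5, 5)), 10, 10,
                                 byrow = TRUE), kind = "mask")
  right <- grid_raster(sp, 1 - left$values, kind = "mask")
  whole <- grid_raster(sp, 1, kind = "mask")
  dens <- structure(list(raster = random_raster(sp, kind = "density",
                                                gen = stats::rexp)),
                    class = "density_surface")
  fy <- fy_from_matrices(sp, matrix(as.numeric(runif(100) < 0.3), 10, 10))
  a <- exposed_count(dens, fy, left)$affected +
    exposed_count(dens, fy, right)$affected
  b <- exposed_count(dens, fy, whole)$affected
  expect_lt(abs(a - b), 1e-6)
})
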
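# Classed conditions so callers/tests can dispatch on failure mode.
ft_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "firetrack_error", "error"),
                      call = call))
}

#' Grid specification
#'
#' Defines a regular raster grid: the north-west cell-edge origin, shape,
#' cell edge length (`resolution`, in the working coordinate unit — degrees
#' or kilometres) and the nominal area of one cell in km². Cell `(r, c)`
#' (1-based) covers the half-open box
#' `[origin_lon + (c-1) res, origin_lon + c res)` in x and
#' `[origin_lat - r res, origin_lat - (r-1) res)` in y: rows count downward
#' from the northern edge. Two grids are alignment-compatible only when
#' origin, resolution and shape match exactly; every overlay operation
#' enforces this rather than reprojecting silently.
#'
#' `cell_area` is a declared constant (default 1 km², the nominal pixel
#' area of 1-km fire products); a latitude-corrected area is deliberately
#' not computed cell-by-cell so that pixel-counting arithmetic stays exact.
#'
#' @param origin_lon,origin_lat Coordinates of the north-west corner of
#'   cell `(1, 1)` (cell edge, not centre).
#' @param n_rows,n_cols Grid shape; both at least 1.
#' @param resolution Cell edge length, in the coordinate unit of the grid.
#' @param cell_area Area of one cell in km².
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, n_rows, n_cols,
                      resolution, cell_area = 1) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    ft_stop("grid shape must be at least 1 x 1", "invalid_geometry")
  if (!is.finite(resolution) || resolution <= 0)
    ft_stop("resolution must be positive", "invalid_geometry")
  if (!is.finite(cell_area) || cell_area <= 0)
    ft_stop("cell_area must be positive", "invalid_geometry")
  structure(list(origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 n_rows = n_rows, n_cols = n_cols,
                 resolution = as.numeric(resolution),
                 cell_area = as.numeric(cell_area)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, res %g, origin (%g, %g), cell area %g km2\n",
              x$n_rows, x$n_cols, x$resolution,
              x$origin_lon, x$origin_lat, x$cell_area))
  invisible(x)
}

#' Build the smallest grid covering a bounding box
#'
#' @param bounds Numeric vector `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param resolution Cell edge length in the same unit as `bounds`.
#' @param cell_area Area of one cell in km² (declared, not derived).
#' @return A [grid_spec()]. The grid's west edge sits on `lon_min`; its
#'   north edge is `lat_min + n_rows * resolution`, so the box is fully
#'   covered (shape is the ceiling of extent / resolution).
#' @export
make_grid <- function(bounds, resolution, cell_area = 1) {
  b <- as.numeric(bounds)
  if (length(b) != 4L || any(!is.finite(b)))
    ft_stop("bounds must be c(lon_min, lat_min, lon_max, lat_max)",
            "invalid_geometry")
  dx <- b[3] - b[1]; dy <- b[4] - b[2]
  if (dx <= 0 || dy <= 0)
    ft_stop("degenerate bounds: zero or negative extent", "invalid_geometry")
  eps <- 1e-9
  n_cols <- as.integer(ceiling(dx / resolution - eps))
  n_rows <- as.integer(ceiling(dy / resolution - eps))
  grid_spec(b[1], b[2] + n_rows * resolution, n_rows, n_cols,
            resolution, cell_area)
}

specs_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) <= tol &&
    abs(a$origin_lat - b$origin_lat) <= tol &&
    abs(a$resolution - b$resolution) <= tol
}

check_aligned <- function(a, b) {
  sa <- if (inherits(a, "grid_raster")) a$spec else a
  sb <- if (inherits(b, "grid_raster")) b$spec else b
  if (!specs_identical(sa, sb))
    ft_stop("rasters are not alignment-compatible (origin/resolution/shape differ); resample explicitly",
            "alignment_error")
  invisible(TRUE)
}

#' Grid raster
#'
#' A grid of real values on a [grid_spec()], stored as an
#' `n_rows x n_cols` matrix (row 1 = northern row). `kind` declares the
#' semantic contract of the values and is validated:
#' \describe{
#'   \item{occurrence}{0/1 presence of fire}
#'   \item{intensity}{0 (no fire) or brightness temperature >= 300 K}
#'   \item{weight}{non-negative, sums to 1 (within 1e-9)}
#'   \item{density}{non-negative individuals per cell}
#'   \item{mask}{0/1 region membership}
#'   \item{generic}{no constraint}
#' }
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix (`n_rows x n_cols`), or a single number to
#'   fill, or a row-major vector of length `n_rows * n_cols`.
#' @param kind Value contract; see Details.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(spec, values = 0,
                        kind = c("generic", "occurrence", "intensity",
                                 "weight", "density", "mask")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "grid_spec"))
  if (is.matrix(values)) {
    if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
      ft_stop("values matrix does not match grid shape", "alignment_error")
    v <- values
  } else if (length(values) == 1L) {
    v <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  } else {
    if (length(values) != spec$n_rows * spec$n_cols)
      ft_stop("values length does not match grid shape", "alignment_error")
    v <- matrix(as.numeric(values), spec$n_rows, spec$n_cols, byrow = TRUE)
  }
  storage.mode(v) <- "double"
  r <- structure(list(spec = spec, values = v, kind = kind),
                 class = "grid_raster")
  validate_raster(r)
  r
}

validate_raster <- function(r) {
  v <- r$values
  bad <- switch(r$kind,
    occurrence = , mask = any(!(v %in% c(0, 1))),
    weight = any(v < 0) || abs(sum(v) - 1) > 1e-9,
    intensity = any(v != 0 & v < 300),
    density = any(v < 0),
    FALSE)
  if (isTRUE(bad))
    ft_stop(sprintf("values violate the '%s' contract", r$kind), "contract_error")
  invisible(r)
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster [%s]: %d x %d, sum %g, range [%g, %g]\n",
              x$kind, x$spec$n_rows, x$spec$n_cols, sum(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Cell centre coordinates, vectorised over the full grid (row-major order).
cell_centres <- function(spec) {
  res <- spec$resolution
  lon <- spec$origin_lon + (seq_len(spec$n_cols) - 0.5) * res
  lat <- spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * res
  list(lon = lon, lat = lat)
}

# Map points to 1-based (row, col); NA where outside the grid.
# Half-open convention: west/south edges belong to a cell, east/north do not.
point_to_cell <- function(spec, lon, lat) {
  res <- spec$resolution
  col <- floor((lon - spec$origin_lon) / res) + 1
  row <- ceiling((spec$origin_lat - lat) / res)
  out <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows |
    !is.finite(lon) | !is.finite(lat)
  col[out] <- NA_integer_; row[out] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# Even-odd (ray casting) point-in-polygon; ring is a 2-column matrix.
# Boundary points resolve by the crossing parity of the horizontal ray.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (n > 1 && ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2])
    ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# polygons: one ring matrix, or a list of ring matrices (even-odd combined,
# so holes are supported), or a list of such lists (multiple features).
as_ring_list <- function(polygons) {
  if (is.matrix(polygons)) return(list(list(polygons)))
  if (is.list(polygons) && length(polygons) && is.matrix(polygons[[1]]))
    return(list(polygons))
  polygons
}

points_in_polygons <- function(px, py, polygons) {
  feats <- as_ring_list(polygons)
  inside <- logical(length(px))
  for (rings in feats) {
    feat_in <- logical(length(px))
    for (ring in rings) feat_in <- xor(feat_in, point_in_ring(px, py, ring))
    inside <- inside | feat_in
  }
  inside
}

#' Rasterize polygons to a 0/1 membership mask
#'
#' @param polygons A single ring (2-column lon/lat matrix), a list of rings
#'   (even-odd rule, so the 2nd ring of a feature is a hole), or a list of
#'   features each given as a list of rings — the shape returned by
#'   [read_geojson_polygons()].
#' @param spec Target [grid_spec()].
#' @param rule `"cell-centre-in"` (default; exact) or `"any-overlap"`
#'   (approximated by testing a 3x3 lattice of interior points plus the four
#'   cell corners).
#' @return A `grid_raster` of kind `mask`. An empty polygon set yields an
#'   all-zero mask with a warning.
#' @export
rasterize_polygons <- function(polygons, spec,
                               rule = c("cell-centre-in", "any-overlap")) {
  rule <- match.arg(rule)
  feats <- as_ring_list(polygons)
  if (length(feats) == 0L) {
    warning("empty polygon set: returning all-zero mask")
    return(grid_raster(spec, 0, kind = "mask"))
  }
  cc <- cell_centres(spec)
  nr <- spec$n_rows; nc <- spec$n_cols
  if (rule == "cell-centre-in") {
    px <- rep(cc$lon, each = nr)      # column-major fill below
    py <- rep(cc$lat, times = nc)
    inside <- points_in_polygons(px, py, feats)
    m <- matrix(as.numeric(inside), nr, nc)
  } else {
    res <- spec$resolution
    offs <- expand.grid(dx = c(-0.5, -0.25, 0, 0.25, 0.5) * res,
                        dy = c(-0.5, -0.25, 0, 0.25, 0.5) * res)
    m <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      px <- rep(cc$lon + offs$dx[k], each = nr)
      py <- rep(cc$lat + offs$dy[k], times = nc)
      m <- pmax(m, matrix(as.numeric(points_in_polygons(px, py, feats)), nr, nc))
    }
  }
  grid_raster(spec, m, kind = "mask")
}

#' Normalize a mask (or any non-negative raster) to unit total mass
#'
#' Rescales values proportionally so they sum to 1; the result is the
#' region-weight layer used to turn an occurrence overlay into a burned
#' fraction.
#'
#' @param mask A `grid_raster` with at least one positive cell.
#' @return A `grid_raster` of kind `weight` summing to 1 (within 1e-9).
#' @export
normalize_mask <- function(mask) {
  stopifnot(inherits(mask, "grid_raster"))
  s <- sum(mask$values)
  if (s <= 0)
    ft_stop("cannot normalize: region mask has no positive cells",
            "empty_region_error")
  grid_raster(mask$spec, mask$values / s, kind = "weight")
}

#' Cellwise product of two aligned rasters
#'
#' The overlay primitive: e.g. region weights x fire occurrence. Both
#' rasters must share an identical [grid_spec()]; mismatches raise an
#' alignment error rather than being silently reprojected.
#'
#' @param a,b Alignment-compatible `grid_raster`s.
#' @return A `grid_raster` of kind `generic` holding the cellwise product.
#' @export
overlay_product <- function(a, b) {
  check_aligned(a, b)
  grid_raster(a$spec, a$values * b$values, kind = "generic")
}

#' Sum of all cell values
#'
#' @param r A `grid_raster`.
#' @return The total as a single number (extended-precision accumulation).
#' @export
raster_sum <- function(r) {
  stopifnot(inherits(r, "grid_raster"))
  sum(r$values)
}

#' Resample a raster onto another grid
#'
#' @param r Source `grid_raster`.
#' @param spec Target [grid_spec()] (same coordinate unit as the source).
#' @param method `"nearest"` (value of the source cell containing the
#'   target cell centre; required for occurrence/mask layers) or
#'   `"area-weighted-mean"` (mean of source values weighted by geometric
#'   overlap; for density/intensity layers).
#' @return A `grid_raster` conforming to `spec`, same kind as the input.
#' @export
resample_to <- function(r, spec, method = c("nearest", "area-weighted-mean")) {
  method <- match.arg(method)
  stopifnot(inherits(r, "grid_raster"), inherits(spec, "grid_spec"))
  if (specs_identical(r$spec, spec)) return(grid_raster(spec, r$values, kind = r$kind))
  if (method == "nearest") {
    cc <- cell_centres(spec)
    px <- rep(cc$lon, each = spec$n_rows)
    py <- rep(cc$lat, times = spec$n_cols)
    idx <- point_to_cell(r$spec, px, py)
    v <- rep(0, length(px))
    ok <- !is.na(idx$row)
    v[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
    out <- matrix(v, spec$n_rows, spec$n_cols)
  } else {
    if (r$kind %in% c("occurrence", "mask"))
      ft_stop("occurrence/mask layers must use nearest resampling",
              "contract_error")
    out <- area_weighted_resample(r, spec)
  }
  grid_raster(spec, out, kind = r$kind)
}

# 1-D interval-overlap weights between source and target cell edges, used
# separably for x and y (grids are axis-aligned rectangles).
overlap_1d <- function(o_src, n_src, res_src, o_tgt, n_tgt, res_tgt, descending) {
  # returns list of, per target index, src indices + overlap lengths
  edges_src <- o_src + (0:n_src) * res_src * (if (descending) -1 else 1)
  edges_tgt <- o_tgt + (0:n_tgt) * res_tgt * (if (descending) -1 else 1)
  lapply(seq_len(n_tgt), function(i) {
    lo <- min(edges_tgt[i], edges_tgt[i + 1])
    hi <- max(edges_tgt[i], edges_tgt[i + 1])
    s_lo <- pmin(edges_src[-length(edges_src)], edges_src[-1])
    s_hi <- pmax(edges_src[-length(edges_src)], edges_src[-1])
    ov <- pmin(hi, s_hi) - pmax(lo, s_lo)
    keep <- which(ov > 1e-12)
    list(idx = keep, w = ov[keep])
  })
}

area_weighted_resample <- function(r, spec) {
  sx <- overlap_1d(r$spec$origin_lon, r$spec$n_cols, r$spec$resolution,
                   spec$origin_lon, spec$n_cols, spec$resolution, FALSE)
  sy <- overlap_1d(r$spec$origin_lat, r$spec$n_rows, r$spec$resolution,
                   spec$origin_lat, spec$n_rows, spec$resolution, TRUE)
  out <- matrix(0, spec$n_rows, spec$n_cols)
  for (i in seq_len(spec$n_rows)) {
    yi <- sy[[i]]
    if (!length(yi$idx)) next
    for (j in seq_len(spec$n_cols)) {
      xj <- sx[[j]]
      if (!length(xj$idx)) next
      w <- outer(yi$w, xj$w)
      v <- r$values[yi$idx, xj$idx, drop = FALSE]
      out[i, j] <- sum(w * v) / sum(w)
    }
  }
  out
}
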
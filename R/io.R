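#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format used for fixtures and scenario bundles.
#' Grid semantics (kind, cell area) that the ASCII header cannot carry are
#' written to a JSON sidecar `<path>.json`.
#'
#' @param r A `grid_raster`.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Value written for `NA` cells (default -9999).
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999, sidecar = TRUE) {
  stopifnot(inherits(r, "grid_raster"))
  sp <- r$spec
  hdr <- c(
    sprintf("ncols %d", sp$n_cols),
    sprintf("nrows %d", sp$n_rows),
    sprintf("xllcorner %.12g", sp$origin_lon),
    sprintf("yllcorner %.12g", sp$origin_lat - sp$n_rows * sp$resolution),
    sprintf("cellsize %.12g", sp$resolution),
    sprintf("NODATA_value %g", nodata))
  v <- r$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row) paste(format(row, digits = 15, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  if (sidecar) {
    jsonlite::write_json(
      list(kind = r$kind, cell_area = sp$cell_area, nodata = nodata),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] or any ESRI ASCII grid.
#' @param kind Value contract for the result; if `NULL`, taken from the
#'   JSON sidecar when present, else `"generic"`.
#' @param cell_area Cell area in km²; if `NULL`, from the sidecar, else 1.
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path, kind = NULL, cell_area = NULL) {
  if (!file.exists(path)) ft_stop(paste("no such file:", path), "format_error")
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    ft_stop("malformed ASCII grid header", "format_error")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(kind)) kind <- meta$kind %||% "generic"
  if (is.null(cell_area)) cell_area <- meta$cell_area %||% 1
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    ft_stop("ASCII grid body does not match declared shape", "format_error")
  vals[vals == nodata] <- NA_real_
  sp <- grid_spec(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize,
                  hdr$nrows, hdr$ncols, hdr$cellsize, cell_area)
  grid_raster(sp, matrix(vals, hdr$nrows, hdr$ncols, byrow = TRUE),
              kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollection, Feature and bare geometry objects with
#' Polygon or MultiPolygon geometries.
#'
#' @param path GeoJSON file.
#' @return A named list with one element per feature, each a list of rings
#'   (2-column lon/lat matrices; first ring outer, later rings holes under
#'   the even-odd rule) — the shape [rasterize_polygons()] accepts. Feature
#'   names come from a `name` property when present.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- switch(g$type %||% "",
    FeatureCollection = g$features,
    Feature = list(g),
    Polygon = , MultiPolygon = list(list(geometry = g)),
    ft_stop("unsupported GeoJSON type", "format_error"))
  out <- list()
  nms <- character()
  for (f in feats) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, ring_to_matrix)),
                            recursive = FALSE),
      ft_stop(paste("unsupported geometry:", geom$type), "format_error"))
    out[[length(out) + 1L]] <- rings
    nms <- c(nms, f$properties$name %||% sprintf("feature_%d", length(out)))
  }
  names(out) <- nms
  out
}

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  storage.mode(m) <- "double"
  m
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param features Named list of features, each a list of ring matrices
#'   (the shape returned by [read_geojson_polygons()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(features, path) {
  nms <- names(features) %||% sprintf("feature_%d", seq_along(features))
  fl <- lapply(seq_along(features), function(i) {
    rings <- features[[i]]
    coords <- lapply(rings, function(m) {
      m <- close_ring(m)
      lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    })
    list(type = "Feature",
         properties = list(name = nms[i]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = fl),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(m) {
  n <- nrow(m)
  if (m[1, 1] != m[n, 1] || m[1, 2] != m[n, 2]) m <- rbind(m, m[1, ])
  m
}

# Axis-aligned rectangle ring, a convenience used throughout the
# synthetic-scenario generator.
rect_ring <- function(lon_min, lat_min, lon_max, lat_max) {
  cbind(c(lon_min, lon_max, lon_max, lon_min),
        c(lat_min, lat_min, lat_max, lat_max))
}
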
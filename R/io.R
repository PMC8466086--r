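#' Raster I/O: ESRI ASCII grid
#'
#' Rasters are exchanged as single-band ESRI ASCII grids (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, north row first. The CRS token
#' travels in a plain-text `.prj` sidecar with the same basename. Values are
#' written with full double precision (`%.17g`), so a write/read round trip is
#' exact and reruns are byte-identical.
#'
#' @param raster An `ichno_raster` (numeric or mask; masks are written 0/1).
#' @param path Output path (`.asc`).
#' @return `path`, invisibly.
#' @seealso [read_ascii_grid()]
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "ichno_raster"))
  if (is.character(raster$values)) {
    stop("unit rasters are categorical; write the geology map as GeoJSON instead",
         call. = FALSE)
  }
  g <- raster$grid
  v <- raster$values
  if (is.logical(v)) v <- v * 1
  v[is.na(v)] <- g$nodata
  con <- file(path, open = "wb")   # binary mode: fixed \n on every platform
  on.exit(close(con))
  hdr <- sprintf("ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value %.17g\n",
                 g$n_cols, g$n_rows, g$origin_x, g$origin_y, g$cell_size, g$nodata)
  writeChar(hdr, con, eos = NULL)
  for (i in seq_len(nrow(v))) {
    writeChar(paste0(paste(sprintf("%.17g", v[i, ]), collapse = " "), "\n"),
              con, eos = NULL)
  }
  prj <- sub("\\.asc$", ".prj", path)
  if (prj != path) writeLines(g$crs, prj)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @param layer,kind Layer name and kind for the returned raster (see
#'   [ichno_raster()]).
#' @return An `ichno_raster`.
#' @export
read_ascii_grid <- function(path, layer = "layer",
                            kind = c("elevation", "factor", "suitability", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (incomplete header): ", path, call. = FALSE)
  }
  prj <- sub("\\.asc$", ".prj", path)
  crs <- if (prj != path && file.exists(prj)) readLines(prj, n = 1L) else "unknown"
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 hdr$nrows, hdr$ncols, crs = crs, nodata = hdr$nodata_value)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != g$n_rows * g$n_cols) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         g$n_rows * g$n_cols, call. = FALSE)
  }
  m <- matrix(vals, g$n_rows, g$n_cols, byrow = TRUE)
  m[m == g$nodata] <- NA
  if (kind == "mask") m <- m != 0
  ichno_raster(g, m, layer = layer, kind = kind)
}

#' Write a geology map as GeoJSON
#'
#' One `Feature` per polygon, with properties `unit` and `layer_kind`.
#' Ring coordinates are written closed, in full double precision.
#'
#' @param geology A [geology_map()].
#' @param path Output path (`.geojson`).
#' @param crs CRS token stored in the (foreign) `crs` member.
#' @return `path`, invisibly.
#' @export
write_geology_geojson <- function(geology, path, crs = "local") {
  stopifnot(inherits(geology, "geology_map"))
  features <- lapply(geology$features, function(f) {
    coords <- lapply(f$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(unit = f$unit, layer_kind = geology$layer_kind),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  doc <- list(type = "FeatureCollection", crs = crs, features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a geology map from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` features with a `unit` property.
#'
#' @param path Path to a GeoJSON file.
#' @param layer_kind `"bedrock"` or `"surficial"` (the file role conveys the
#'   layer kind; a `layer_kind` property, when present, must agree).
#' @return A [geology_map()].
#' @export
read_geology_geojson <- function(path, layer_kind = c("bedrock", "surficial")) {
  layer_kind <- match.arg(layer_kind)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                  call. = FALSE)
  feats <- list()
  for (f in doc$features) {
    unit <- f$properties$unit
    if (is.null(unit)) stop("GeoJSON feature without a 'unit' property", call. = FALSE)
    fk <- f$properties$layer_kind
    if (!is.null(fk) && fk != layer_kind) {
      stop("feature tagged layer_kind '", fk, "' read as ", layer_kind, call. = FALSE)
    }
    gtype <- f$geometry$type
    polys <- switch(gtype,
                    Polygon = list(f$geometry$coordinates),
                    MultiPolygon = f$geometry$coordinates,
                    stop("unsupported geometry type: ", gtype, call. = FALSE))
    for (poly in polys) {
      rings <- lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      })
      feats[[length(feats) + 1L]] <- list(unit = unit, rings = rings)
    }
  }
  geology_map(layer_kind, feats)
}

#' Write ranked sites as GeoJSON
#'
#' Each site is dissolved into a `MultiPolygon` of its member cell squares;
#' the strategy attributes travel as feature properties.
#'
#' @param sites An [`ichno_sites`][build_strategy] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_geojson <- function(sites, path) {
  stopifnot(inherits(sites, "ichno_sites"))
  grid <- attr(sites, "grid")
  cells_list <- attr(sites, "cells")
  features <- lapply(seq_len(nrow(sites)), function(i) {
    cells <- cells_list[[i]]
    nr <- grid$n_rows
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    polys <- lapply(seq_along(cells), function(k) {
      x0 <- grid$origin_x + (cols[k] - 1L) * grid$cell_size
      y0 <- grid$origin_y + (nr - rows[k]) * grid$cell_size
      x1 <- x0 + grid$cell_size; y1 <- y0 + grid$cell_size
      list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    })
    props <- as.list(sites[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  doc <- list(type = "FeatureCollection", crs = grid$crs, features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write the strategy table as CSV
#'
#' @param sites An [`ichno_sites`][build_strategy] object.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_strategy_csv <- function(sites, path) {
  stopifnot(inherits(sites, "ichno_sites"))
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE, na = "")
  invisible(path)
}
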
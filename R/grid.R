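#' Grid specification for all rasters in a run
#'
#' Every raster participating in one pipeline run (unit rasters, factor
#' rasters, suitability rasters, masks, the DEM) shares one square-celled grid.
#' The origin is the lower-left corner of the lower-left cell, in map metres;
#' values are stored as matrices with row 1 = the northernmost row, the usual
#' raster convention. `NA` is the in-memory nodata sentinel; `nodata` is the
#' value written to / read from ASCII grid files.
#'
#' @param origin_x,origin_y Lower-left corner, map units (metres).
#' @param cell_size Cell edge length in metres (> 0).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param crs Opaque coordinate-reference token, passed through unmodified.
#' @param nodata Nodata sentinel used in file I/O.
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(0, 0, 40, 120, 120)
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 1,
                      n_rows = 1, n_cols = 1, crs = "local", nodata = -9999) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
            is.finite(origin_x), is.finite(origin_y))
  structure(list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 crs = as.character(crs), nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a[c("origin_x", "origin_y", "cell_size")],
                   b[c("origin_x", "origin_y", "cell_size")],
                   tolerance = 1e-12)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols && a$crs == b$crs
}

.check_same_grid <- function(rasters) {
  g <- rasters[[1]]$grid
  for (nm in names(rasters)[-1]) {
    if (!grids_identical(g, rasters[[nm]]$grid)) {
      stop("grid mismatch: raster '", nm, "' is on a different grid", call. = FALSE)
    }
  }
  g
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with matrices `x` and `y` (`n_rows` x `n_cols`) holding the
#'   map coordinates of each cell center.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
  list(x = matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE),
       y = matrix(ys, grid$n_rows, grid$n_cols))
}

#' Construct a raster on a grid
#'
#' Thin container tying a value matrix to its [grid_spec()]. `layer` names the
#' quantity held (a factor letter `L`,`H`,`E`,`S`,`W`,`K`, a profile letter
#' `A`,`B`,`C`, `"elevation"`, `"unit"`, or a mask name); `kind` states the
#' value semantics.
#'
#' @param grid A `grid_spec`.
#' @param values Matrix (`n_rows` x `n_cols`); `NA` = nodata. Numeric, logical
#'   (masks) or character (unit rasters).
#' @param layer Layer name.
#' @param kind One of `"factor"`, `"suitability"`, `"elevation"`, `"unit"`,
#'   `"mask"`.
#' @return An `ichno_raster`.
#' @export
ichno_raster <- function(grid, values, layer = "layer",
                         kind = c("factor", "suitability", "elevation",
                                  "unit", "mask")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    stop(sprintf("values must be a %d x %d matrix", grid$n_rows, grid$n_cols),
         call. = FALSE)
  }
  if (kind == "factor") {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% 1:4)) {
      stop("factor raster '", layer, "': every non-nodata value must be in {1,2,3,4}",
           call. = FALSE)
    }
  }
  structure(list(grid = grid, values = values, layer = layer, kind = kind),
            class = "ichno_raster")
}

#' @export
print.ichno_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  rng <- if (length(v) && !is.character(v)) {
    sprintf(", range [%g, %g]", min(as.numeric(v)), max(as.numeric(v)))
  } else ""
  cat(sprintf("<ichno_raster '%s' (%s)> %d x %d, %d nodata cell(s)%s\n",
              x$layer, x$kind, x$grid$n_rows, x$grid$n_cols,
              sum(is.na(x$values)), rng))
  invisible(x)
}

#' @export
as.matrix.ichno_raster <- function(x, ...) x$values
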
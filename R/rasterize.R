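#' Rasterize a geology map to a unit-name raster
#'
#' Each cell is assigned the unit of the polygon containing its center
#' (boundary points count as inside); cells covered by no polygon are nodata.
#' Where polygons overlap, the feature appearing later in the input order
#' wins, mirroring map drawing order.
#'
#' @param geology A [geology_map()].
#' @param grid A [grid_spec()].
#' @param catalogue Optional [`score_catalogue`][load_catalogue]; when given,
#'   the map is validated against it first.
#' @return An `ichno_raster` of kind `"unit"` (character matrix).
#' @export
rasterize_units <- function(geology, grid, catalogue = NULL) {
  stopifnot(inherits(geology, "geology_map"), inherits(grid, "grid_spec"))
  if (!is.null(catalogue)) validate_geology(geology, catalogue)
  cc <- cell_centers(grid)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  out <- rep(NA_character_, length(px))
  eps <- 1e-9 * max(1, grid$cell_size)
  for (i in seq_along(geology$features)) {
    f <- geology$features[[i]]
    # bounding-box prefilter (inflated by eps so boundary cells are kept)
    bb <- do.call(rbind, f$rings)
    sel <- which(px >= min(bb[, 1]) - eps & px <= max(bb[, 1]) + eps &
                 py >= min(bb[, 2]) - eps & py <= max(bb[, 2]) + eps)
    if (!length(sel)) next
    hit <- tryCatch(
      points_in_polygon(px[sel], py[sel], f$rings, eps = eps),
      error = function(e) stop("feature ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    out[sel[hit]] <- f$unit
  }
  ichno_raster(grid, matrix(out, grid$n_rows, grid$n_cols),
               layer = "unit", kind = "unit")
}

#' Score a bedrock unit raster for one palaeoenvironmental factor
#'
#' Per-cell lookup of the factor score in the catalogue; nodata cells stay
#' nodata.
#'
#' @param unit_raster A unit raster from [rasterize_units()] of a bedrock map.
#' @param catalogue A [`score_catalogue`][load_catalogue].
#' @param factor One of `"L"`, `"H"`, `"E"`, `"S"`.
#' @return An `ichno_raster` of kind `"factor"`.
#' @export
score_raster <- function(unit_raster, catalogue, factor = c("L", "H", "E", "S")) {
  factor <- match.arg(factor)
  stopifnot(inherits(unit_raster, "ichno_raster"), unit_raster$kind == "unit",
            inherits(catalogue, "score_catalogue"))
  score_any_factor(unit_raster, catalogue, factor)
}

#' Surficial-cover score raster (factor K)
#'
#' Cells under a mapped surficial unit take that unit's `K` score; cells with
#' no surficial unit are uncovered bedrock, the most desirable observation
#' condition, and score `K = 4`. When no surficial map exists at all, the
#' whole grid scores 4.
#'
#' @param surficial_unit_raster A unit raster of the surficial map, or `NULL`.
#' @param catalogue A [`score_catalogue`][load_catalogue].
#' @param grid A [grid_spec()] (required when the raster is `NULL`; otherwise
#'   taken from the raster).
#' @return An `ichno_raster` of kind `"factor"`, layer `"K"`.
#' @export
cover_score_raster <- function(surficial_unit_raster = NULL, catalogue, grid = NULL) {
  stopifnot(inherits(catalogue, "score_catalogue"))
  if (is.null(surficial_unit_raster)) {
    stopifnot(inherits(grid, "grid_spec"))
    return(ichno_raster(grid, matrix(4, grid$n_rows, grid$n_cols),
                        layer = "K", kind = "factor"))
  }
  stopifnot(inherits(surficial_unit_raster, "ichno_raster"),
            surficial_unit_raster$kind == "unit")
  if (!is.null(grid) && !grids_identical(grid, surficial_unit_raster$grid)) {
    stop("grid mismatch: surficial raster is not on the shared grid", call. = FALSE)
  }
  scored <- tryCatch(
    score_any_factor(surficial_unit_raster, catalogue, "K"),
    error = function(e) stop(conditionMessage(e), call. = FALSE))
  v <- scored$values
  v[is.na(v) & is.na(surficial_unit_raster$values)] <- 4  # uncovered bedrock
  ichno_raster(surficial_unit_raster$grid, v, layer = "K", kind = "factor")
}

# shared lookup core for any factor letter (score_raster restricts to L,H,E,S)
score_any_factor <- function(unit_raster, catalogue, factor) {
  u <- unit_raster$values
  lv <- sort(unique(as.vector(u[!is.na(u)])))
  scores <- vapply(lv, function(nm) lookup_score(catalogue, nm, factor),
                   numeric(1))
  v <- matrix(NA_real_, nrow(u), ncol(u))
  if (length(lv)) v[] <- scores[match(as.vector(u), lv)]
  ichno_raster(unit_raster$grid, v, layer = factor, kind = "factor")
}

#' Water-table score raster (factor W)
#'
#' Cells with elevation strictly below the shoreline elevation score
#' `rule$high_score` (a permanent water table is plausible there); cells at or
#' above it score `rule$low_score`. Nodata propagates.
#'
#' @param dem An `ichno_raster` of kind `"elevation"` (metres).
#' @param rule A [water_rule()].
#' @return An `ichno_raster` of kind `"factor"`, layer `"W"`.
#' @export
water_score_raster <- function(dem, rule = water_rule()) {
  stopifnot(inherits(dem, "ichno_raster"), dem$kind == "elevation",
            inherits(rule, "water_rule"))
  e <- dem$values
  v <- ifelse(e < rule$shoreline_elevation, rule$high_score, rule$low_score)
  v[is.na(e)] <- NA_real_
  ichno_raster(dem$grid, v, layer = "W", kind = "factor")
}
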
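#' Parameters for the synthetic crater landscape
#'
#' The generator emulates, at a reduced and fully analytic scale, the map
#' structure of a delta-bearing crater-lake landing site: an annular rim of
#' basement units, a crater floor, a western delta fan fed through an incised
#' inlet channel crossing the rim, scattered surficial cover patches, and a
#' bowl-shaped DEM straddling the palaeolake shoreline. Only catalogued unit
#' names are used, so every pipeline stage runs against it unchanged.
#'
#' Defaults describe a 4.8 km square scene (120 x 120 cells of 40 m): a
#' 2 km-radius crater with a 400 m rim, floor at -2,450 m and rim crest at
#' -2,000 m around the -2,200 m shoreline, a western (270 deg azimuth) delta
#' spreading 60 deg, and about a quarter of the scene under surficial cover.
#'
#' @param crater_radius Crater floor radius, m.
#' @param rim_width Width of the rim annulus, m.
#' @param delta_azimuth Azimuth of the delta axis, degrees counter-clockwise
#'   from east.
#' @param delta_spread Full angular spread of the delta fan, degrees.
#' @param grid A [grid_spec()]; the crater is centred on the grid.
#' @param floor_elevation,rim_elevation Crater floor / rim crest elevation, m.
#'   Must bracket `shoreline_elevation`.
#' @param shoreline_elevation Palaeolake shoreline elevation, m.
#' @param surficial_cover_fraction Approximate fraction of the scene covered
#'   by surficial patches, in \[0, 1\].
#' @param noise_sd Standard deviation of the small-amplitude DEM noise, m.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output (Mersenne-Twister generator, inversion normals).
#' @return A `landscape_params` list.
#' @export
landscape_params <- function(crater_radius = 2000, rim_width = 400,
                             delta_azimuth = 270, delta_spread = 60,
                             grid = grid_spec(0, 0, 40, 120, 120,
                                              crs = "synthetic-local"),
                             floor_elevation = -2450, rim_elevation = -2000,
                             shoreline_elevation = -2200,
                             surficial_cover_fraction = 0.25,
                             noise_sd = 3, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"),
            crater_radius > 0, rim_width > 0, delta_spread > 0,
            is.finite(delta_azimuth), noise_sd >= 0)
  if (!(floor_elevation < shoreline_elevation &&
        shoreline_elevation < rim_elevation)) {
    stop("need floor_elevation < shoreline_elevation < rim_elevation",
         call. = FALSE)
  }
  if (surficial_cover_fraction < 0 || surficial_cover_fraction > 1) {
    stop("surficial_cover_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(crater_radius = crater_radius, rim_width = rim_width,
                 delta_azimuth = delta_azimuth, delta_spread = delta_spread,
                 grid = grid, floor_elevation = floor_elevation,
                 rim_elevation = rim_elevation,
                 shoreline_elevation = shoreline_elevation,
                 surficial_cover_fraction = surficial_cover_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "landscape_params")
}

#' Generate a synthetic crater landscape
#'
#' @param params A [landscape_params()].
#' @return A list with elements `bedrock` and `surficial`
#'   ([geology_map()]s) and `dem` (an elevation `ichno_raster` on
#'   `params$grid`). The bedrock map tiles the grid completely.
#' @examples
#' scene <- generate_landscape(landscape_params(seed = 1))
#' scene$bedrock
#' @export
generate_landscape <- function(params = landscape_params()) {
  stopifnot(inherits(params, "landscape_params"))
  g <- params$grid
  cx <- g$origin_x + g$n_cols * g$cell_size / 2
  cy <- g$origin_y + g$n_rows * g$cell_size / 2
  R <- params$crater_radius
  Rw <- R + params$rim_width
  az <- params$delta_azimuth
  half <- params$delta_spread / 2
  span <- max(g$n_cols, g$n_rows) * g$cell_size

  # grid-covering rectangle, generously padded
  pad <- 2 * g$cell_size
  frame <- cbind(
    c(g$origin_x - pad, g$origin_x + g$n_cols * g$cell_size + pad,
      g$origin_x + g$n_cols * g$cell_size + pad, g$origin_x - pad),
    c(g$origin_y - pad, g$origin_y - pad,
      g$origin_y + g$n_rows * g$cell_size + pad,
      g$origin_y + g$n_rows * g$cell_size + pad))

  feat <- list()
  add <- function(unit, ring) feat[[length(feat) + 1L]] <<- list(unit = unit, rings = list(ring))

  # exterior plains, then rim quadrants, then floor units (later wins)
  add("Nili Planum fractured", frame)
  add("Crater rim blocky",  .annular_sector_ring(cx, cy, 0, Rw, -45, 45))
  add("Crater rim layered", .annular_sector_ring(cx, cy, 0, Rw, 45, 135))
  add("Crater rim breccia", .annular_sector_ring(cx, cy, 0, Rw, 135, 225))
  add("Crater rim rough",   .annular_sector_ring(cx, cy, 0, Rw, 225, 315))
  add("Crater floor fractured 1", .circle_ring(cx, cy, R))
  add("Margin fractured", .annular_sector_ring(cx, cy, 0.82 * R, R, 20, 160))
  add("Crater floor fractured 2",
      .annular_sector_ring(cx, cy, 0.55 * R, 0.82 * R, az - half - 20, az + half + 20))
  add("Crater floor fractured rough", .circle_ring(cx + 0.45 * R, cy - 0.3 * R, 0.22 * R))
  # inlet channel crossing the rim along the delta axis
  ax <- cos(az * pi / 180); ay <- sin(az * pi / 180)
  add("Neretva Vallis layered",
      .band_ring(cx + 0.45 * R * ax, cy + 0.45 * R * ay,
                 cx + (Rw + span) * ax, cy + (Rw + span) * ay, 0.15 * R))
  # delta fan: proximal blocky core, distal thin/rough lobes
  add("Delta thickly layered",
      .annular_sector_ring(cx, cy, 0.45 * R, 0.62 * R, az - half, az + half))
  add("Delta thinly layered",
      .annular_sector_ring(cx, cy, 0.22 * R, 0.45 * R, az - half, az))
  add("Delta layered rough",
      .annular_sector_ring(cx, cy, 0.22 * R, 0.45 * R, az, az + half))
  add("Delta truncated curvilinear layered",
      .annular_sector_ring(cx, cy, 0.17 * R, 0.22 * R, az - half, az + half))
  add("Delta blocky",
      .annular_sector_ring(cx, cy, 0, 0.17 * R, az - half, az + half))
  bedrock <- geology_map("bedrock", feat)

  # seeded state is restored on exit so the generator is a pure function
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  # surficial patches: random axis-aligned squares until the target fraction
  surf_units <- c("Aeolian bedforms, large", "Aeolian bedforms, small",
                  "Minor Cover Units", "Moderate Cover Units", "Talus",
                  "Undifferentiated smooth")
  total_area <- (g$n_cols * g$cell_size) * (g$n_rows * g$cell_size)
  target <- params$surficial_cover_fraction * total_area
  sfeat <- list()
  acc <- 0
  while (acc < target) {
    side <- runif(1, 3, 8) * g$cell_size
    px <- runif(1, g$origin_x, g$origin_x + g$n_cols * g$cell_size - side)
    py <- runif(1, g$origin_y, g$origin_y + g$n_rows * g$cell_size - side)
    u <- sample(surf_units, 1)
    sfeat[[length(sfeat) + 1L]] <-
      list(unit = u, rings = list(cbind(c(px, px + side, px + side, px),
                                        c(py, py, py + side, py + side))))
    acc <- acc + side^2
  }
  surficial <- geology_map("surficial", sfeat)

  # bowl-shaped DEM: floor at centre, rim crest at R + rim_width/2, gentle
  # outward decay, plus small-amplitude seeded noise
  cc <- cell_centers(g)
  r <- sqrt((cc$x - cx)^2 + (cc$y - cy)^2)
  crest <- R + params$rim_width / 2
  t <- pmin(r / crest, 1)
  s <- t * t * (3 - 2 * t)   # smoothstep
  elev <- params$floor_elevation +
    (params$rim_elevation - params$floor_elevation) * s
  outside <- r > crest
  relief <- params$rim_elevation - params$floor_elevation
  elev[outside] <- params$rim_elevation -
    0.15 * relief * pmin((r[outside] - crest) / params$rim_width, 1)
  if (params$noise_sd > 0) {
    elev <- elev + stats::rnorm(length(elev), 0, params$noise_sd)
  }
  dem <- ichno_raster(g, matrix(elev, g$n_rows, g$n_cols),
                      layer = "elevation", kind = "elevation")

  list(bedrock = bedrock, surficial = surficial, dem = dem, params = params)
}

#' A tiny worked landscape with frozen expected suitability values
#'
#' A fixed 6 x 6 scene whose per-cell A, B and C suitability values (equations
#' weight preset, default water rule, threshold-free) were enumerated once
#' with the scalar aggregation oracle and are shipped as goldens. Column
#' bands of bedrock units, a stepped DEM crossing the -2,200 m shoreline
#' (row 3 sits exactly at the shoreline, scoring low), and two surficial
#' patches exercise every scoring path.
#'
#' @return A list with `bedrock`, `surficial`, `dem`, `grid`, and `expected`
#'   (matrices `A`, `B`, `C`).
#' @export
worked_fixture <- function() {
  g <- grid_spec(0, 0, 100, 6, 6, crs = "synthetic-local")
  rect <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  bedrock <- geology_map("bedrock", list(
    list(unit = "Crater floor fractured 1", rings = list(rect(0, 200, 0, 600))),
    list(unit = "Delta thinly layered",     rings = list(rect(200, 400, 0, 600))),
    list(unit = "Delta blocky",             rings = list(rect(400, 500, 0, 600))),
    list(unit = "Crater rim blocky",        rings = list(rect(500, 600, 0, 600)))
  ))
  surficial <- geology_map("surficial", list(
    list(unit = "Aeolian bedforms, large", rings = list(rect(0, 200, 0, 200))),
    list(unit = "Talus",                   rings = list(rect(400, 500, 400, 600)))
  ))
  # rows top to bottom: -2100, -2100, -2200 (exactly at shoreline), -2300 x3
  elev <- matrix(rep(c(-2100, -2100, -2200, -2300, -2300, -2300), times = 6), 6, 6)
  dem <- ichno_raster(g, elev, layer = "elevation", kind = "elevation")
  expected <- .worked_fixture_expected()
  list(bedrock = bedrock, surficial = surficial, dem = dem, grid = g,
       expected = expected)
}

# Frozen goldens (scalar oracle, equations preset, shoreline -2200 m).
.worked_fixture_expected <- function() {
  A <- matrix(c(
    3.7, 3.7, 3.7, 3.7, 1.4, 2.1,
    3.7, 3.7, 3.7, 3.7, 1.4, 2.1,
    3.7, 3.7, 3.7, 3.7, 2.4, 2.1,
    4,   4,   4,   4,   2.7, 2.4,
    1,   1,   4,   4,   2.7, 2.4,
    1,   1,   4,   4,   2.7, 2.4), 6, 6, byrow = TRUE)
  B <- matrix(c(
    2.6, 2.6, 2.2, 2.2, 0.1, 3.2,
    2.6, 2.6, 2.2, 2.2, 0.1, 3.2,
    2.6, 2.6, 2.2, 2.2, 1.1, 3.2,
    3.2, 3.2, 2.8, 2.8, 1.7, 3.8,
    0.2, 0.2, 2.8, 2.8, 1.7, 3.8,
    0.2, 0.2, 2.8, 2.8, 1.7, 3.8), 6, 6, byrow = TRUE)
  C <- matrix(c(
    2.5, 2.5, 2.5, 2.5, 0.1, 2.3,
    2.5, 2.5, 2.5, 2.5, 0.1, 2.3,
    2.5, 2.5, 2.5, 2.5, 1.1, 2.3,
    4,   4,   4,   4,   2.6, 3.8,
    1,   1,   4,   4,   2.6, 3.8,
    1,   1,   4,   4,   2.6, 3.8), 6, 6, byrow = TRUE)
  list(A = A, B = B, C = C)
}
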
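test_that("a polygon covering the grid assigns its unit everywhere", {
  g <- grid_spec(0, 0, 10, 5, 5)
  gm <- geology_map("bedrock", list(
    list(unit = "Delta blocky", rings = list(rect_ring(0, 50, 0, 50)))))
  u <- rasterize_units(gm, g)
  expect_true(all(u$values == "Delta blocky"))
})

test_that("overlapping polygons: the later feature wins; gaps are nodata", {
  g <- grid_spec(0, 0, 10, 4, 4)
  gm <- geology_map("bedrock", list(
    list(unit = "Delta blocky", rings = list(rect_ring(0, 30, 0, 40))),
    list(unit = "Crater rim blocky", rings = list(rect_ring(10, 40, 0, 40)))
  ))
  u <- rasterize_units(gm, g)$values
  expect_true(all(u[, 1] == "Delta blocky"))
  expect_true(all(u[, 2:4] == "Crater rim blocky"))   # overlap in col 2-3

  gm2 <- geology_map("bedrock", list(
    list(unit = "Delta blocky", rings = list(rect_ring(0, 20, 0, 40)))))
  u2 <- rasterize_units(gm2, g)$values
  expect_true(all(is.na(u2[, 3:4])))
})

test_that("cell centers on a polygon edge count as inside", {
  g <- grid_spec(0, 0, 10, 3, 3)
  # right edge x = 15 passes exactly through the centers of column 2
  gm <- geology_map("bedrock", list(
    list(unit = "Delta blocky", rings = list(rect_ring(0, 15, 0, 30)))))
  u <- rasterize_units(gm, g)$values
  # brute-force check of the listed centers: columns 1-2 in, column 3 out
  expect_true(all(u[, 1:2] == "Delta blocky"))
  expect_true(all(is.na(u[, 3])))
  # and a vertex/corner touch
  gm2 <- geology_map("bedrock", list(
    list(unit = "Delta blocky", rings = list(rect_ring(15, 25, 15, 25)))))
  u2 <- rasterize_units(gm2, g)$values
  expect_equal(u2[2, 2], "Delta blocky")
})

test_that("polygons with holes follow the even-odd rule", {
  g <- grid_spec(0, 0, 10, 5, 5)
  gm <- geology_map("bedrock", list(
    list(unit = "Delta blocky",
         rings = list(rect_ring(0, 50, 0, 50), rect_ring(10, 40, 10, 40)))))
  u <- rasterize_units(gm, g)$values
  expect_true(all(u[1, ] == "Delta blocky"))
  expect_true(all(is.na(u[2:4, 2:4])))
})

test_that("invalid geometries are rejected naming the feature", {
  g <- grid_spec(0, 0, 10, 2, 2)
  expect_error(geology_map("bedrock", list(
    list(unit = "Delta blocky", rings = list(cbind(c(0, 1), c(0, 1)))))),
    "feature 1")
  expect_error(geology_map("bedrock", list(
    list(unit = "Delta blocky",
         rings = list(cbind(c(0, 1, NaN), c(0, 1, 2)))))), "finite")
})

test_that("geology maps validate unit names and categories against the catalogue", {
  cat21 <- load_catalogue()
  g <- grid_spec(0, 0, 10, 2, 2)
  gm_bad <- geology_map("bedrock", list(
    list(unit = "Lake Of Nowhere", rings = list(rect_ring(0, 20, 0, 20)))))
  expect_error(rasterize_units(gm_bad, g, cat21), "not in catalogue")
  gm_cat <- geology_map("bedrock", list(
    list(unit = "Talus", rings = list(rect_ring(0, 20, 0, 20)))))
  expect_error(rasterize_units(gm_cat, g, cat21), "surficial")
})

test_that("score_raster equals cell-by-cell lookup_score (double-loop oracle)", {
  sc <- make_small_scene(20)
  cat21 <- load_catalogue()
  u <- rasterize_units(sc$bedrock, sc$grid, cat21)
  for (f in c("L", "H", "E", "S")) {
    r <- score_raster(u, cat21, f)
    expect_equal(r$layer, f)
    naive <- matrix(NA_real_, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      if (!is.na(u$values[i, j])) {
        naive[i, j] <- lookup_score(cat21, u$values[i, j], f)
      }
    }
    expect_identical(r$values, naive)
  }
})

test_that("rasterize-then-score equals score-then-rasterize on disjoint maps", {
  # scoring each polygon then burning the score must agree with the pipeline
  cat21 <- load_catalogue()
  g <- grid_spec(0, 0, 10, 10, 10)
  feats <- list(
    list(unit = "Crater floor fractured 1", rings = list(rect_ring(0, 50, 0, 100))),
    list(unit = "Delta thinly layered", rings = list(rect_ring(50, 100, 0, 100))))
  gm <- geology_map("bedrock", feats)
  prod <- score_raster(rasterize_units(gm, g, cat21), cat21, "E")$values
  alt <- matrix(NA_real_, 10, 10)
  cc <- cell_centers(g)
  for (f in feats) {
    s <- lookup_score(cat21, f$unit, "E")
    inside <- matrix(ichno:::points_in_polygon(as.vector(cc$x), as.vector(cc$y),
                                               lapply(f$rings, ichno:::.close_ring)),
                     10, 10)
    alt[inside] <- s
  }
  expect_identical(prod, alt)
})

test_that("score_raster propagates nodata and rejects foreign categories", {
  cat21 <- load_catalogue()
  g <- grid_spec(0, 0, 10, 3, 3)
  empty <- ichno_raster(g, matrix(NA_character_, 3, 3), layer = "unit", kind = "unit")
  r <- score_raster(empty, cat21, "L")
  expect_true(all(is.na(r$values)))
  mixed <- ichno_raster(g, matrix("Talus", 3, 3), layer = "unit", kind = "unit")
  expect_error(score_raster(mixed, cat21, "L"), "not applicable")
})

test_that("cover scores: mapped K, uncovered bedrock = 4, absent map = 4", {
  cat21 <- load_catalogue()
  g <- grid_spec(0, 0, 10, 4, 4)
  surf <- geology_map("surficial", list(
    list(unit = "Aeolian bedforms, large", rings = list(rect_ring(0, 20, 20, 40))),
    list(unit = "Talus", rings = list(rect_ring(20, 40, 0, 20)))))
  k <- cover_score_raster(rasterize_units(surf, g, cat21), cat21)$values
  expect_equal(k[1:2, 1:2], matrix(1, 2, 2))   # large aeolian bedforms
  expect_equal(k[3:4, 3:4], matrix(3, 2, 2))   # talus
  expect_equal(k[1:2, 3:4], matrix(4, 2, 2))   # uncovered bedrock
  k0 <- cover_score_raster(NULL, cat21, g)
  expect_true(all(k0$values == 4))
  expect_equal(k0$layer, "K")
})

test_that("water scores threshold the DEM with a strict 'below'", {
  g <- grid_spec(0, 0, 10, 2, 3)
  elev <- matrix(c(-2300, -2200, -2100, -2199.999, -2200.001, NA), 2, 3)
  dem <- ichno_raster(g, elev, layer = "elevation", kind = "elevation")
  w <- water_score_raster(dem, water_rule())$values
  expect_equal(w[1, 1], 4)       # below
  expect_equal(w[2, 1], 1)       # exactly at the shoreline: at-or-above branch
  expect_equal(w[1, 2], 1)       # above
  expect_equal(w[2, 2], 1)       # just above
  expect_equal(w[1, 3], 4)       # just below
  expect_true(is.na(w[2, 3]))    # nodata propagates
})

test_that("water scoring is monotone: lowering elevation never lowers W", {
  g <- grid_spec(0, 0, 10, 10, 10)
  set.seed(7)
  for (rep in 1:20) {
    e1 <- matrix(runif(100, -2400, -2000), 10, 10)
    drop <- matrix(runif(100, 0, 300), 10, 10)
    d1 <- ichno_raster(g, e1, layer = "elevation", kind = "elevation")
    d2 <- ichno_raster(g, e1 - drop, layer = "elevation", kind = "elevation")
    w1 <- water_score_raster(d1)$values
    w2 <- water_score_raster(d2)$values
    expect_true(all(w2 >= w1))
  }
})

test_that("a custom shoreline (e.g. the initial fill level) shifts the split", {
  g <- grid_spec(0, 0, 10, 1, 2)
  dem <- ichno_raster(g, matrix(c(-2220, -2250), 1, 2),
                      layer = "elevation", kind = "elevation")
  w_ext <- water_score_raster(dem, water_rule())$values
  w_fill <- water_score_raster(dem, water_rule(shoreline_elevation = -2243))$values
  expect_equal(as.vector(w_ext), c(4, 4))
  expect_equal(as.vector(w_fill), c(1, 4))
})
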
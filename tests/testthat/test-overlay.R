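test_that("aggregate_cell reproduces hand-worked examples", {
  eq <- load_weight_profiles()
  # all factors at the top of the scale, no cover penalty: the printed upper bound
  for (p in eq) {
    expect_equal(aggregate_cell(L = 4, H = 4, E = 4, S = 4, W = 4, K = 4,
                                profile = p), 4)
  }
  # crater-floor cell (L=4, E=3, S=3) below shoreline, uncovered
  expect_equal(aggregate_cell(L = 4, E = 3, S = 3, W = 4, K = 4,
                              profile = eq$A), 3.5)
  # crater-rim blocky cell (H=4, E=2, S=4) above shoreline, uncovered
  expect_equal(aggregate_cell(H = 4, E = 2, S = 4, W = 1, K = 4,
                              profile = eq$B), 3.2)
  # crater-rim breccia cell (L=1, E=1, S=4) above shoreline, uncovered
  expect_equal(aggregate_cell(L = 1, E = 1, S = 4, W = 1, K = 4,
                              profile = eq$A), 1.9)
  expect_equal(aggregate_cell(H = 4, E = 1, S = 4, W = 1, K = 4,
                              profile = eq$B), 3.1)
})

test_that("zero-weight factors are ignored; missing weighted factors error", {
  eq <- load_weight_profiles()
  # A carries no H weight: H may be omitted or set arbitrarily
  expect_equal(aggregate_cell(L = 2, E = 2, S = 2, W = 2, K = 4, profile = eq$A),
               aggregate_cell(L = 2, H = 4, E = 2, S = 2, W = 2, K = 4,
                              profile = eq$A))
  expect_error(aggregate_cell(E = 2, S = 2, W = 2, K = 4, profile = eq$A),
               "factor L")
  expect_error(aggregate_cell(L = 2, E = 2, S = 2, W = 2, profile = eq$A),
               "K")
})

test_that("cover penalty is linear: K = k costs exactly (4 - k)", {
  eq <- load_weight_profiles()
  set.seed(11)
  for (rep in 1:50) {
    x <- sample(1:4, 5, replace = TRUE)
    p <- eq[[sample(c("A", "B", "C"), 1)]]
    base <- aggregate_cell(L = x[1], H = x[2], E = x[3], S = x[4], W = x[5],
                           K = 4, profile = p)
    for (k in 1:4) {
      expect_equal(aggregate_cell(L = x[1], H = x[2], E = x[3], S = x[4],
                                  W = x[5], K = k, profile = p),
                   base - (4 - k))
    }
  }
})

test_that("with K = 4 the aggregate stays on the 1-4 ordinal range", {
  profs <- c(load_weight_profiles(), load_weight_profiles(source = "table5"))
  set.seed(13)
  for (rep in 1:200) {
    x <- sample(1:4, 5, replace = TRUE)
    p <- profs[[sample(seq_along(profs), 1)]]
    v <- aggregate_cell(L = x[1], H = x[2], E = x[3], S = x[4], W = x[5],
                        K = 4, profile = p)
    expect_gte(v, 1 - 1e-12)
    expect_lte(v, 4 + 1e-12)
  }
  # and the theoretical unclamped floor under total cover
  p <- load_weight_profiles()$A
  expect_equal(aggregate_cell(L = 1, E = 1, S = 1, W = 1, K = 1, profile = p), -2)
})

test_that("aggregation is monotone in every positively weighted factor", {
  eq <- load_weight_profiles()
  set.seed(17)
  for (rep in 1:100) {
    x <- sample(1:3, 5, replace = TRUE)  # leave headroom to increment
    p <- eq[[sample(c("A", "B", "C"), 1)]]
    base <- aggregate_cell(L = x[1], H = x[2], E = x[3], S = x[4], W = x[5],
                           K = 3, profile = p)
    for (f in 1:5) {
      x2 <- x; x2[f] <- x2[f] + 1
      v <- aggregate_cell(L = x2[1], H = x2[2], E = x2[3], S = x2[4], W = x2[5],
                          K = 3, profile = p)
      expect_gte(v, base)
    }
  }
})

test_that("raster aggregation equals the scalar path on random fixtures", {
  g <- grid_spec(0, 0, 10, 20, 20)
  profs <- load_weight_profiles()
  set.seed(19)
  for (rep in 1:3) {
    fr <- lapply(c(L = "L", H = "H", E = "E", S = "S", W = "W", K = "K"),
                 function(f) ichno_raster(g, matrix(sample(1:4, 400, TRUE), 20, 20),
                                          layer = f, kind = "factor"))
    for (p in profs) {
      out <- aggregate_raster(fr, p)$values
      w <- eq_weights[[p$profile]]
      naive <- matrix(NA_real_, 20, 20)
      for (i in 1:20) for (j in 1:20) {
        naive[i, j] <- oracle_aggregate(
          L = fr$L$values[i, j], H = fr$H$values[i, j], E = fr$E$values[i, j],
          S = fr$S$values[i, j], W = fr$W$values[i, j], K = fr$K$values[i, j],
          w = w)
      }
      expect_equal(out, naive, tolerance = 1e-12)
    }
  }
})

test_that("a nodata cell in any required input is nodata in the output, only there", {
  g <- grid_spec(0, 0, 10, 4, 4)
  mk <- function(f, v) {
    m <- matrix(v, 4, 4)
    ichno_raster(g, m, layer = f, kind = "factor")
  }
  fr <- list(L = mk("L", 4), E = mk("E", 4), S = mk("S", 4),
             W = mk("W", 4), K = mk("K", 4))
  fr$W$values[2, 3] <- NA
  out <- aggregate_raster(fr, load_weight_profiles()$A)$values
  expect_true(is.na(out[2, 3]))
  expect_equal(sum(is.na(out)), 1)
  expect_equal(out[!is.na(out)], rep(4, 15), tolerance = 1e-12)
})

test_that("grid mismatch is rejected naming the offending raster", {
  g1 <- grid_spec(0, 0, 10, 4, 4)
  g2 <- grid_spec(0, 0, 20, 4, 4)
  mk <- function(g, f) ichno_raster(g, matrix(2, 4, 4), layer = f, kind = "factor")
  fr <- list(L = mk(g1, "L"), E = mk(g1, "E"), S = mk(g1, "S"),
             W = mk(g2, "W"), K = mk(g1, "K"))
  expect_error(aggregate_raster(fr, load_weight_profiles()$A), "'W'")
})

test_that("profile C ignores substrate rasters; preset swap leaves C unchanged", {
  g <- grid_spec(0, 0, 10, 8, 8)
  set.seed(23)
  mk <- function(f) ichno_raster(g, matrix(sample(1:4, 64, TRUE), 8, 8),
                                 layer = f, kind = "factor")
  fr <- lapply(c(L = "L", H = "H", E = "E", S = "S", W = "W", K = "K"), mk)
  eq <- load_weight_profiles()
  t5 <- load_weight_profiles(source = "table5")
  out_eq <- run_all_profiles(fr, eq)
  # perturbing L and H leaves C untouched
  fr2 <- fr
  fr2$L <- mk("L"); fr2$H <- mk("H")
  out2 <- run_all_profiles(fr2, eq)
  expect_identical(out_eq$C$values, out2$C$values)
  # swapping presets changes A and B but not C
  out_t5 <- run_all_profiles(fr, t5)
  expect_identical(out_eq$C$values, out_t5$C$values)
  expect_false(identical(out_eq$A$values, out_t5$A$values))
  expect_false(identical(out_eq$B$values, out_t5$B$values))
  # three rasters on byte-identical grids
  expect_identical(out_eq$A$grid, out_eq$B$grid)
  expect_identical(out_eq$A$grid, out_eq$C$grid)
})
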
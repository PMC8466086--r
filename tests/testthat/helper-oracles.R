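# Shared fixtures and independent oracles, kept deliberately naive so they
# stay independent of the production code paths they check.

rect_ring <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

# Scalar brute-force aggregation straight from the printed formula:
# N = sum(x_i w_i) - (4 - k). Takes raw numbers, not package objects.
oracle_aggregate <- function(L = NA, H = NA, E = NA, S = NA, W = NA, K, w) {
  x <- c(L = L, H = H, E = E, S = S, W = W)
  acc <- 0
  for (f in names(w)) if (w[[f]] > 0) acc <- acc + w[[f]] * x[[f]]
  acc - (4 - K)
}

eq_weights <- list(
  A = c(L = 0.4, H = 0, E = 0.2, S = 0.3, W = 0.1),
  B = c(L = 0, H = 0.4, E = 0.1, S = 0.3, W = 0.2),
  C = c(L = 0, H = 0, E = 0.1, S = 0.4, W = 0.5)
)

# Connected-component oracle via igraph: build the adjacency graph of true
# cells and take its components. Returns sorted lists of sorted linear indices.
oracle_components <- function(m, connectivity, min_cells = 1) {
  truth <- which(!is.na(m) & m)
  if (!length(truth)) return(list())
  nr <- nrow(m)
  rows <- (truth - 1L) %% nr + 1L
  cols <- (truth - 1L) %/% nr + 1L
  idx <- stats::setNames(seq_along(truth), truth)
  edges <- integer(0)
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  for (k in seq_along(truth)) {
    for (o in offs) {
      rr <- rows[k] + o[1]; cc <- cols[k] + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(m)) {
        nb <- (cc - 1L) * nr + rr
        j <- idx[as.character(nb)]
        if (!is.na(j)) edges <- c(edges, k, j)
      }
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(truth), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- lapply(split(truth, comp), function(cl) sort(unname(cl)))
  out <- out[lengths(out) >= min_cells]
  # sort by row-major order of first cell to match the production labelling
  first_rm <- vapply(out, function(cl) {
    r <- (cl - 1L) %% nr + 1L; c <- (cl - 1L) %/% nr + 1L
    min((r - 1L) * ncol(m) + c)
  }, numeric(1))
  unname(out[order(first_rm)])
}

# A tiny two-unit bedrock map + DEM on an n x n grid, for oracle comparisons.
make_small_scene <- function(n = 20, cell = 10) {
  g <- grid_spec(0, 0, cell, n, n, crs = "test")
  half <- n * cell / 2
  bedrock <- geology_map("bedrock", list(
    list(unit = "Crater floor fractured 1",
         rings = list(rect_ring(0, n * cell, 0, n * cell))),
    list(unit = "Crater rim blocky",
         rings = list(rect_ring(half, n * cell, 0, n * cell)))
  ))
  set.seed(42)
  elev <- matrix(runif(n * n, -2300, -2100), n, n)
  dem <- ichno_raster(g, elev, layer = "elevation", kind = "elevation")
  list(grid = g, bedrock = bedrock, dem = dem)
}
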
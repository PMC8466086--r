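#' Vector geology maps
#'
#' A geology map is an ordered list of polygon features, each tagged with a
#' catalogued unit name. Feature order matters: where polygons overlap, the
#' later feature wins during rasterization, mirroring map drawing order.
#'
#' Each feature is a list with elements `unit` (character) and `rings` (a list
#' of n x 2 coordinate matrices; the first ring is the outer boundary,
#' subsequent rings are holes, interpreted under the even-odd rule). Rings may
#' be given open or closed (first vertex repeated); both are accepted.
#'
#' @param layer_kind `"bedrock"` or `"surficial"`.
#' @param features List of features as described above.
#' @return A `geology_map`.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' geology_map("bedrock", list(list(unit = "Delta blocky", rings = list(sq))))
#' @export
geology_map <- function(layer_kind = c("bedrock", "surficial"), features = list()) {
  layer_kind <- match.arg(layer_kind)
  for (i in seq_along(features)) {
    f <- features[[i]]
    if (is.null(f$unit) || is.null(f$rings)) {
      stop("feature ", i, ": needs 'unit' and 'rings'", call. = FALSE)
    }
    for (j in seq_along(f$rings)) {
      r <- f$rings[[j]]
      if (!is.matrix(r) || ncol(r) != 2 || !all(is.finite(r))) {
        stop("feature ", i, ", ring ", j,
             ": rings must be n x 2 matrices of finite coordinates", call. = FALSE)
      }
      r <- .close_ring(r)
      if (nrow(r) < 4L) {
        stop("feature ", i, ", ring ", j, ": invalid geometry (fewer than 3 vertices)",
             call. = FALSE)
      }
      features[[i]]$rings[[j]] <- r
    }
    features[[i]]$unit <- .normalize_unit_name(f$unit)
  }
  structure(list(layer_kind = layer_kind, features = features),
            class = "geology_map")
}

.close_ring <- function(r) {
  # drop a duplicated closing vertex, then close explicitly
  if (nrow(r) > 1L && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
  rbind(r, r[1, ])
}

#' @export
print.geology_map <- function(x, ...) {
  cat(sprintf("<geology_map (%s)> %d feature(s): %s\n", x$layer_kind,
              length(x$features),
              paste(unique(vapply(x$features, `[[`, "", "unit")), collapse = ", ")))
  invisible(x)
}

#' Check a geology map against a catalogue
#'
#' Every unit name must resolve in the catalogue with the map's category.
#'
#' @param geology A [geology_map()].
#' @param catalogue A [`score_catalogue`][load_catalogue].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_geology <- function(geology, catalogue) {
  stopifnot(inherits(geology, "geology_map"), inherits(catalogue, "score_catalogue"))
  for (i in seq_along(geology$features)) {
    u <- geology$features[[i]]$unit
    k <- match(u, catalogue$unit)
    if (is.na(k)) {
      stop("feature ", i, ": unit '", u, "' not in catalogue", call. = FALSE)
    }
    if (catalogue$category[k] != geology$layer_kind) {
      stop("feature ", i, ": unit '", u, "' is ", catalogue$category[k],
           " but the map is ", geology$layer_kind, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Even-odd point-in-polygon over one ring, vectorized over points; points
# lying on a ring edge (within eps, metres) count as inside. Returns
# list(parity, on_boundary).
.ring_test <- function(px, py, ring, eps = 1e-9) {
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- length(rx) - 1L          # closed ring: last vertex repeats the first
  parity <- logical(length(px))
  on <- logical(length(px))
  for (i in seq_len(n)) {
    xi <- rx[i]; yi <- ry[i]
    xj <- rx[i + 1L]; yj <- ry[i + 1L]
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
      ddx <- px - (xi + t * dx); ddy <- py - (yi + t * dy)
      on <- on | (ddx * ddx + ddy * ddy <= eps * eps)
      if (yi != yj) {
        cross <- ((yi > py) != (yj > py)) &
          (px < xi + dx * (py - yi) / dy)
        parity <- xor(parity, cross)
      }
    } else {
      on <- on | ((px - xi)^2 + (py - yi)^2 <= eps * eps)
    }
  }
  list(parity = parity, on = on)
}

# Point-in-polygon for a multi-ring feature (even-odd across rings; boundary
# counts as inside). px, py are numeric vectors.
points_in_polygon <- function(px, py, rings, eps = 1e-9) {
  parity <- logical(length(px))
  on <- logical(length(px))
  for (ring in rings) {
    t <- .ring_test(px, py, ring, eps = eps)
    parity <- xor(parity, t$parity)
    on <- on | t$on
  }
  parity | on
}

# Analytic shape helpers used by the synthetic generator (regular polygons
# approximating circles keep rasterized region counts hand-checkable).

.circle_ring <- function(cx, cy, r, n = 72L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(a), cy + r * sin(a))
}

# Sector of an annulus between radii r0 < r1, azimuths a0..a1 (degrees,
# measured counter-clockwise from east). r0 = 0 gives a pie slice.
.annular_sector_ring <- function(cx, cy, r0, r1, a0, a1, n = 36L) {
  th <- seq(a0, a1, length.out = n) * pi / 180
  outer <- cbind(cx + r1 * cos(th), cy + r1 * sin(th))
  if (r0 <= 0) {
    rbind(outer, c(cx, cy))
  } else {
    inner <- cbind(cx + r0 * cos(rev(th)), cy + r0 * sin(rev(th)))
    rbind(outer, inner)
  }
}

# Rectangle of given width centred on the segment (x0,y0)-(x1,y1).
.band_ring <- function(x0, y0, x1, y1, width) {
  dx <- x1 - x0; dy <- y1 - y0
  L <- sqrt(dx * dx + dy * dy)
  nx <- -dy / L * width / 2; ny <- dx / L * width / 2
  cbind(c(x0 + nx, x1 + nx, x1 - nx, x0 - nx),
        c(y0 + ny, y1 + ny, y1 - ny, y0 - ny))
}
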
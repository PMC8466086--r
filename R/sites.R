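#' Threshold a suitability raster into a high-suitability mask
#'
#' A cell is high-suitability when its aggregated score is at or above the
#' threshold (inclusive comparison). The default threshold of 3 conventionally
#' splits off the top quarter of the 1--4 ordinal range. Nodata propagates.
#'
#' @param suitability An `ichno_raster` of kind `"suitability"`.
#' @param threshold Real threshold within the theoretical score range
#'   \[-2, 4\]. Default 3.
#' @return An `ichno_raster` of kind `"mask"` (logical values).
#' @export
classify <- function(suitability, threshold = 3) {
  stopifnot(inherits(suitability, "ichno_raster"),
            suitability$kind == "suitability",
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  if (threshold < -2 || threshold > 4) {
    stop("threshold must lie within the theoretical score range [-2, 4]",
         call. = FALSE)
  }
  ichno_raster(suitability$grid, suitability$values >= threshold,
               layer = suitability$layer, kind = "mask")
}

#' Extract connected high-suitability regions from a mask
#'
#' Maximal connected components of true cells under 4- or 8-connectivity,
#' discarding components smaller than `min_cells`. Labelling is deterministic:
#' regions are numbered in row-major order of each region's first cell.
#'
#' @param mask An `ichno_raster` of kind `"mask"`.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal). Default 8.
#' @param min_cells Minimum component size kept. Default 4.
#' @return A list of regions, each a list with `id`, `cell_count`, and `cells`
#'   (sorted linear indices into the value matrix, column-major as R stores it).
#' @export
extract_regions <- function(mask, connectivity = 8, min_cells = 4) {
  stopifnot(inherits(mask, "ichno_raster"), mask$kind == "mask",
            connectivity %in% c(4, 8), min_cells >= 1)
  m <- mask$values
  nr <- nrow(m); nc <- ncol(m)
  truth <- !is.na(m) & m
  labels <- matrix(0L, nr, nc)
  nb_dr <- if (connectivity == 4) c(-1L, 1L, 0L, 0L) else
    c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  nb_dc <- if (connectivity == 4) c(0L, 0L, -1L, 1L) else
    c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  regions <- list()
  next_id <- 0L
  # scan rows first so labels follow row-major order of first cells
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!truth[r0, c0] || labels[r0, c0] != 0L) next
    next_id <- next_id + 1L
    # iterative flood fill with an explicit stack
    stack_r <- integer(256L); stack_c <- integer(256L)
    stack_r[1L] <- r0; stack_c[1L] <- c0; top <- 1L
    labels[r0, c0] <- next_id
    cells <- integer(0)
    while (top > 0L) {
      r <- stack_r[top]; cc <- stack_c[top]; top <- top - 1L
      cells <- c(cells, (cc - 1L) * nr + r)
      for (k in seq_along(nb_dr)) {
        rr <- r + nb_dr[k]; ccc <- cc + nb_dc[k]
        if (rr >= 1L && rr <= nr && ccc >= 1L && ccc <= nc &&
            truth[rr, ccc] && labels[rr, ccc] == 0L) {
          labels[rr, ccc] <- next_id
          top <- top + 1L
          if (top > length(stack_r)) {
            stack_r <- c(stack_r, integer(length(stack_r)))
            stack_c <- c(stack_c, integer(length(stack_c)))
          }
          stack_r[top] <- rr; stack_c[top] <- ccc
        }
      }
    }
    if (length(cells) >= min_cells) {
      regions[[length(regions) + 1L]] <-
        list(id = length(regions) + 1L, cell_count = length(cells),
             cells = sort(cells))
    }
  }
  regions
}

#' Build a ranked ichnological strategy from per-profile regions
#'
#' Formalizes the survey-planning step: high-suitability regions from the
#' three predictive maps are merged where they spatially overlap, ranked, and
#' annotated with the ichnofossil types likely present and the most efficient
#' detection mode.
#'
#' Profile membership maps to recommended ichnofossil types
#' (A = bioturbation, B = bioerosion, C = biostratification). Detection mode:
#' bioturbation and biostratification structures are resolvable by the rover
#' imaging tools (`"imaging"`); microbioerosion structures may fall below
#' imaging resolution, so any bioerosion recommendation implies `"sampling"`,
#' and `"imaging+sampling"` when both kinds apply.
#'
#' Sites are ranked by the maximum of their per-profile mean suitability
#' scores (descending), ties broken by larger area then smaller `site_id`
#' (ids are assigned in row-major order of each merged site's first cell).
#'
#' @param regions_by_profile Named list (`A`, `B`, `C`, any subset) of region
#'   lists from [extract_regions()].
#' @param suitability_rasters Named list of the matching suitability rasters.
#' @param top_n Maximum number of sites returned (default 10).
#' @return An `ichno_sites` data frame with one row per site: `site_id`,
#'   `rank`, `profiles`, `cell_count`, `area_m2`, `centroid_x`, `centroid_y`,
#'   per-profile `mean_*`/`max_*` scores, `score` (the ranking statistic),
#'   `recommended_types`, `detection_mode`. The per-site member cell indices
#'   are attached as attribute `"cells"`.
#' @export
build_strategy <- function(regions_by_profile, suitability_rasters, top_n = 10) {
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1) {
    stop("top_n must be >= 1", call. = FALSE)
  }
  profs <- names(regions_by_profile)
  stopifnot(!is.null(profs), all(profs %in% names(suitability_rasters)))
  grid <- .check_same_grid(suitability_rasters[profs])

  # flat list of (profile, region) with union-find over spatial overlaps
  entries <- list()
  for (p in profs) {
    for (r in regions_by_profile[[p]]) {
      entries[[length(entries) + 1L]] <- list(profile = p, cells = r$cells)
    }
  }
  n <- length(entries)
  if (n == 0L) {
    return(.empty_sites())
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  cell_owner <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (cl in entries[[i]]$cells) {
      key <- as.character(cl)
      j <- cell_owner[[key]]
      if (is.null(j)) {
        cell_owner[[key]] <- i
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)

  sites <- lapply(groups, function(idx) {
    members <- entries[idx]
    all_cells <- sort(unique(unlist(lapply(members, `[[`, "cells"))))
    memb_profs <- sort(unique(vapply(members, `[[`, "", "profile")))
    per_prof <- lapply(memb_profs, function(p) {
      cells_p <- sort(unique(unlist(lapply(
        members[vapply(members, `[[`, "", "profile") == p], `[[`, "cells"))))
      vals <- suitability_rasters[[p]]$values[cells_p]
      list(mean = mean(vals), max = max(vals))
    })
    names(per_prof) <- memb_profs
    list(cells = all_cells, profiles = memb_profs, per_prof = per_prof)
  })

  # deterministic ids: row-major order of each site's first cell
  first_rm <- vapply(sites, function(s) {
    nr <- grid$n_rows
    rows <- (s$cells - 1L) %% nr + 1L
    cols <- (s$cells - 1L) %/% nr + 1L
    min((rows - 1L) * grid$n_cols + cols)
  }, numeric(1))
  ord <- order(first_rm)
  sites <- sites[ord]

  score_map <- c(A = "bioturbation", B = "bioerosion", C = "biostratification")
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    means <- vapply(s$per_prof, `[[`, numeric(1), "mean")
    maxs <- vapply(s$per_prof, `[[`, numeric(1), "max")
    types <- unname(score_map[s$profiles])
    mode <- if ("bioerosion" %in% types) {
      if (length(setdiff(types, "bioerosion"))) "imaging+sampling" else "sampling"
    } else "imaging"
    nr <- grid$n_rows
    cols <- (s$cells - 1L) %/% nr + 1L
    rws <- (s$cells - 1L) %% nr + 1L
    cx <- mean(grid$origin_x + (cols - 0.5) * grid$cell_size)
    cy <- mean(grid$origin_y + (nr - rws + 0.5) * grid$cell_size)
    out <- data.frame(site_id = i, rank = NA_integer_,
                      profiles = paste(s$profiles, collapse = "+"),
                      cell_count = length(s$cells),
                      area_m2 = length(s$cells) * grid$cell_size^2,
                      centroid_x = cx, centroid_y = cy,
                      score = max(means),
                      recommended_types = paste(types, collapse = "+"),
                      detection_mode = mode,
                      stringsAsFactors = FALSE)
    for (p in c("A", "B", "C")) {
      out[[paste0("mean_", p)]] <- if (p %in% s$profiles) means[[p]] else NA_real_
      out[[paste0("max_", p)]] <- if (p %in% s$profiles) maxs[[p]] else NA_real_
    }
    out
  })
  df <- do.call(rbind, rows)
  cells_list <- lapply(sites, `[[`, "cells")
  ord2 <- order(-df$score, -df$area_m2, df$site_id)
  df <- df[ord2, , drop = FALSE]
  cells_list <- cells_list[ord2]
  keep <- seq_len(min(nrow(df), as.integer(top_n)))
  df <- df[keep, , drop = FALSE]
  cells_list <- cells_list[keep]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, cells = cells_list, grid = grid,
            class = c("ichno_sites", "data.frame"))
}

.empty_sites <- function() {
  df <- data.frame(site_id = integer(0), rank = integer(0),
                   profiles = character(0), cell_count = integer(0),
                   area_m2 = numeric(0), centroid_x = numeric(0),
                   centroid_y = numeric(0), score = numeric(0),
                   recommended_types = character(0),
                   detection_mode = character(0),
                   mean_A = numeric(0), max_A = numeric(0),
                   mean_B = numeric(0), max_B = numeric(0),
                   mean_C = numeric(0), max_C = numeric(0),
                   stringsAsFactors = FALSE)
  structure(df, cells = list(), class = c("ichno_sites", "data.frame"))
}

#' @export
print.ichno_sites <- function(x, ...) {
  cat(sprintf("<ichno_sites> %d ranked high-suitability site(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
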
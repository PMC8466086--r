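#' Pipeline run configuration
#'
#' Collects everything one scoring run needs: input paths (or in-memory
#' objects), the catalogue and weight configuration, the water rule, the
#' classification threshold and the region-extraction parameters. The
#' configuration is validated against the catalogue and profile invariants
#' before any raster work starts.
#'
#' @param bedrock Bedrock geology: a GeoJSON path or a [geology_map()].
#' @param dem Elevation model: an `.asc` path or an elevation `ichno_raster`.
#' @param surficial Optional surficial geology (path or `geology_map`).
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration document (path or list) carrying
#'   `units`, `weights`, `water_rule` and/or `threshold` entries; see
#'   [load_catalogue()] and [load_weight_profiles()].
#' @param weights_source Weight preset when the config names none.
#' @param threshold Classification threshold (default 3; a config `threshold`
#'   overrides it).
#' @param connectivity,min_cells,top_n Region-extraction and ranking
#'   parameters (defaults 8, 4, 10).
#' @param verbose Print per-stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(bedrock, dem, surficial = NULL, out_dir = tempfile("ichno_"),
                       config = NULL, weights_source = c("equations", "table5"),
                       threshold = NULL, connectivity = 8, min_cells = 4,
                       top_n = 10, verbose = FALSE) {
  weights_source <- match.arg(weights_source)
  cfg <- .read_config(config)
  catalogue <- load_catalogue(cfg)
  profiles <- load_weight_profiles(cfg, source = weights_source)
  wr <- cfg$water_rule
  rule <- water_rule(
    shoreline_elevation = wr$shoreline_elevation %||% -2200,
    high_score = wr$high_score %||% 4,
    low_score = wr$low_score %||% 1)
  threshold <- threshold %||% cfg$threshold %||% 3
  structure(list(bedrock = bedrock, surficial = surficial, dem = dem,
                 out_dir = out_dir, catalogue = catalogue, profiles = profiles,
                 water_rule = rule, threshold = threshold,
                 connectivity = connectivity, min_cells = min_cells,
                 top_n = top_n, verbose = isTRUE(verbose),
                 preset = if (!is.null(cfg$weights$preset)) cfg$weights$preset
                          else weights_source),
            class = "run_config")
}

.stage <- function(name, verbose, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full suitability pipeline
#'
#' Executes the scoring workflow end to end: rasterize the geology, score the
#' six factor layers (`L`, `H`, `E`, `S`, `W`, `K`), aggregate the three
#' suitability maps (`A`, `B`, `C`), classify them at the threshold, extract
#' and rank high-suitability sites, and write every artifact plus a JSON
#' manifest with per-artifact checksums. On any stage error the partial
#' outputs are removed and the error names the failing stage.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly: a list with `artifacts` (paths and md5
#'   checksums), `preset`, `threshold`, `sites` summary and `config_echo`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  out <- config$out_dir
  created_dir <- !dir.exists(out)
  if (created_dir) dir.create(out, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(written)
      unlink(sub("\\.asc$", ".prj", written[grepl("\\.asc$", written)]))
      if (created_dir) unlink(out, recursive = TRUE)
    }
  })
  emit <- function(path) { written <<- c(written, path); path }

  dem <- .stage("load-dem", v, {
    if (inherits(config$dem, "ichno_raster")) config$dem
    else if (is.character(config$dem)) read_ascii_grid(config$dem, "elevation", "elevation")
    else stop("a DEM is required (path or elevation raster)")
  })
  grid <- dem$grid
  bedrock <- .stage("load-bedrock", v, {
    if (inherits(config$bedrock, "geology_map")) config$bedrock
    else read_geology_geojson(config$bedrock, "bedrock")
  })
  surficial <- .stage("load-surficial", v, {
    if (is.null(config$surficial)) NULL
    else if (inherits(config$surficial, "geology_map")) config$surficial
    else read_geology_geojson(config$surficial, "surficial")
  })

  .msg(v, "rasterizing bedrock (%d features) on %d x %d grid",
       length(bedrock$features), grid$n_rows, grid$n_cols)
  bed_units <- .stage("rasterize-bedrock", v,
                      rasterize_units(bedrock, grid, config$catalogue))
  surf_units <- if (!is.null(surficial)) {
    .stage("rasterize-surficial", v,
           rasterize_units(surficial, grid, config$catalogue))
  } else NULL

  factors <- list()
  for (f in c("L", "H", "E", "S")) {
    factors[[f]] <- .stage(paste0("score-", f), v,
                           score_raster(bed_units, config$catalogue, f))
  }
  factors$W <- .stage("water-score", v, water_score_raster(dem, config$water_rule))
  factors$K <- .stage("cover-score", v,
                      cover_score_raster(surf_units, config$catalogue, grid))
  .msg(v, "factor layers done (%d nodata cells in L)", sum(is.na(factors$L$values)))

  suit <- .stage("aggregate", v, run_all_profiles(factors, config$profiles))
  masks <- .stage("classify", v,
                  lapply(suit, classify, threshold = config$threshold))
  regions <- .stage("extract-regions", v,
                    lapply(masks, extract_regions,
                           connectivity = config$connectivity,
                           min_cells = config$min_cells))
  .msg(v, "regions found: %s",
       paste(sprintf("%s=%d", names(regions), lengths(regions)), collapse = " "))
  sites <- .stage("strategy", v,
                  build_strategy(regions, suit, top_n = config$top_n))

  paths <- list()
  for (f in names(factors)) {
    paths[[paste0("factor_", f)]] <-
      emit(write_ascii_grid(factors[[f]], file.path(out, sprintf("factor_%s.asc", f))))
  }
  for (p in names(suit)) {
    paths[[paste0("suitability_", p)]] <-
      emit(write_ascii_grid(suit[[p]], file.path(out, sprintf("suitability_%s.asc", p))))
    paths[[paste0("mask_", p)]] <-
      emit(write_ascii_grid(masks[[p]], file.path(out, sprintf("mask_%s.asc", p))))
  }
  paths$sites <- emit(write_sites_geojson(sites, file.path(out, "sites.geojson")))
  paths$strategy <- emit(write_strategy_csv(sites, file.path(out, "strategy.csv")))

  checksums <- vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
  manifest <- list(
    artifacts = lapply(names(paths), function(nm)
      list(name = nm, path = unname(paths[[nm]]), md5 = unname(checksums[[nm]]))),
    preset = config$preset,
    threshold = config$threshold,
    water_rule = unclass(config$water_rule),
    region_params = list(connectivity = config$connectivity,
                         min_cells = config$min_cells, top_n = config$top_n),
    grid = unclass(grid),
    n_sites = nrow(sites),
    config_echo = list(
      catalogue = catalogue_to_config(config$catalogue),
      weights = lapply(config$profiles, unclass))
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  .msg(v, "wrote %d artifacts to %s", length(paths), out)
  invisible(c(manifest, list(path = manifest_path, sites = sites)))
}
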
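#' @title Score catalogue: ordinal suitability scores of the geological units
#'
#' @description
#' The predictive model scores every mapped geological unit on an ordinal
#' 1--4 scale (4 = most desirable condition) for a set of palaeoenvironmental
#' suitability factors:
#'
#' * `L` -- substrate suitability for bioturbation (presence of loose substrates),
#' * `H` -- substrate suitability for bioerosion (presence of lithified substrates),
#' * `E` -- suitability of the (hydrodynamic) energy regime,
#' * `S` -- suitability of the sedimentation rate,
#' * `K` -- suitability of the surficial cover conditions (4 = uncovered bedrock).
#'
#' Bedrock units carry `L`, `H`, `E`, `S`; surficial units carry only `K`.
#' The water-table factor `W` is not a unit attribute: it is derived from the
#' elevation model (see [water_score_raster()]).
#'
#' @name score_catalogue
NULL

# Default catalogue: 15 bedrock + 6 surficial units of a crater-lake landing
# site, each scored on the 1-4 ordinal scale. NA marks a factor that does not
# apply to the unit's category.
.default_catalogue_df <- function() {
  bed <- data.frame(
    unit = c(
      "Crater floor fractured 1", "Crater floor fractured 2",
      "Crater floor fractured rough", "Margin fractured",
      "Crater rim blocky", "Crater rim breccia", "Crater rim layered",
      "Crater rim rough", "Neretva Vallis layered", "Nili Planum fractured",
      "Delta blocky", "Delta layered rough", "Delta thickly layered",
      "Delta thinly layered", "Delta truncated curvilinear layered"
    ),
    category = "bedrock",
    L = c(4, 4, 4, 4, 1, 1, 1, 1, 4, 1, 4, 4, 4, 4, 4),
    H = c(2, 2, 2, 2, 4, 4, 4, 4, 1, 4, 1, 1, 1, 1, 1),
    E = c(4, 3, 4, 3, 2, 1, 2, 2, 1, 2, 2, 4, 4, 4, 3),
    S = c(4, 3, 4, 2, 4, 4, 4, 4, 3, 4, 1, 4, 4, 4, 3),
    K = NA_real_,
    stringsAsFactors = FALSE
  )
  surf <- data.frame(
    unit = c(
      "Aeolian bedforms, large", "Aeolian bedforms, small",
      "Minor Cover Units", "Moderate Cover Units", "Talus",
      "Undifferentiated smooth"
    ),
    category = "surficial",
    L = NA_real_, H = NA_real_, E = NA_real_, S = NA_real_,
    K = c(1, 2, 2, 1, 3, 2),
    stringsAsFactors = FALSE
  )
  rbind(bed, surf)
}

.factor_names <- c("L", "H", "E", "S", "K")

# Exact matching after trimming and collapsing internal whitespace; silent
# fuzzy matching would risk mis-scoring a unit.
.normalize_unit_name <- function(x) gsub("[[:space:]]+", " ", trimws(x))

.check_score <- function(value, unit, field) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
      !(value %in% 1:4)) {
    stop(sprintf("invalid score for unit '%s', factor %s: must be in {1,2,3,4}, got %s",
                 unit, field, deparse(value)), call. = FALSE)
  }
  as.numeric(value)
}

.validate_catalogue_df <- function(df) {
  df$unit <- .normalize_unit_name(df$unit)
  if (anyDuplicated(df$unit)) {
    stop("duplicate unit names in catalogue: ",
         paste(unique(df$unit[duplicated(df$unit)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    cat_i <- df$category[i]
    if (!cat_i %in% c("bedrock", "surficial")) {
      stop(sprintf("unit '%s': category must be 'bedrock' or 'surficial'", df$unit[i]),
           call. = FALSE)
    }
    need <- if (cat_i == "bedrock") c("L", "H", "E", "S") else "K"
    forbid <- setdiff(.factor_names, need)
    for (f in need) {
      df[[f]][i] <- .check_score(df[[f]][i], df$unit[i], f)
    }
    present <- vapply(forbid, function(f) !is.na(df[[f]][i]), logical(1))
    if (any(present)) {
      stop(sprintf("unit '%s' (%s): factor(s) %s not applicable to this category",
                   df$unit[i], cat_i, paste(forbid[present], collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(df, class = c("score_catalogue", "data.frame"))
}

#' Load the unit score catalogue
#'
#' Returns the built-in catalogue of 15 bedrock and 6 surficial units, or a
#' catalogue modified by a configuration document. Config entries with a unit
#' name already in the catalogue replace that entry; new names extend it.
#'
#' @param config Optional configuration: a file path (YAML or JSON), or a list
#'   with a `units` element, each unit a list of
#'   `name`, `category` (`"bedrock"` or `"surficial"`) and `scores`
#'   (named `L`,`H`,`E`,`S` for bedrock; `K` for surficial).
#' @return A `score_catalogue`: a data frame with columns `unit`, `category`,
#'   `L`, `H`, `E`, `S`, `K` (`NA` = factor not applicable).
#' @examples
#' cat21 <- load_catalogue()
#' nrow(cat21)                                  # 21 units
#' lookup_score(cat21, "Delta thinly layered", "L")
#' @seealso [lookup_score()], [load_weight_profiles()]
#' @export
load_catalogue <- function(config = NULL) {
  df <- .default_catalogue_df()
  units <- .config_units(config)
  for (u in units) {
    if (is.null(u$name) || is.null(u$category)) {
      stop("catalogue config: every unit entry needs 'name' and 'category'",
           call. = FALSE)
    }
    name <- .normalize_unit_name(u$name)
    row <- data.frame(unit = name, category = u$category,
                      L = NA_real_, H = NA_real_, E = NA_real_, S = NA_real_,
                      K = NA_real_, stringsAsFactors = FALSE)
    for (f in intersect(names(u$scores), .factor_names)) {
      row[[f]] <- .check_score(u$scores[[f]], name, f)
    }
    extra <- setdiff(names(u$scores), .factor_names)
    if (length(extra)) {
      stop(sprintf("unit '%s': unknown factor(s) %s", name,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    if (name %in% df$unit) {
      df[df$unit == name, ] <- row
    } else {
      df <- rbind(df, row)
    }
  }
  .validate_catalogue_df(df)
}

.config_units <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg)) return(list())
  if (!is.null(cfg$units)) cfg$units else list()
}

# Accept a path (YAML or JSON decided by extension, YAML parses JSON too),
# an already-parsed list, or NULL.
.read_config <- function(config) {
  if (is.null(config)) return(NULL)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = FALSE))
    }
    return(yaml::read_yaml(config))
  }
  if (is.list(config)) return(config)
  stop("config must be NULL, a file path, or a list", call. = FALSE)
}

#' Look up a factor score for a unit
#'
#' @param catalogue A [`score_catalogue`][load_catalogue].
#' @param unit_name Unit name (matched exactly after whitespace normalization).
#' @param factor One of `"L"`, `"H"`, `"E"`, `"S"`, `"K"`.
#' @return The ordinal score (1--4).
#' @examples
#' lookup_score(load_catalogue(), "Talus", "K")  # 3
#' @export
lookup_score <- function(catalogue, unit_name, factor) {
  stopifnot(inherits(catalogue, "score_catalogue"))
  factor <- match.arg(factor, .factor_names)
  name <- .normalize_unit_name(unit_name)
  i <- match(name, catalogue$unit)
  if (is.na(i)) stop("unknown unit: '", name, "'", call. = FALSE)
  v <- catalogue[[factor]][i]
  if (is.na(v)) {
    stop(sprintf("factor %s not applicable to unit '%s' (category %s)",
                 factor, name, catalogue$category[i]), call. = FALSE)
  }
  v
}

#' Weight profiles for the three ichnofossil types
#'
#' Each suitability map (A = bioturbation, B = bioerosion,
#' C = biostratification) aggregates the factor scores with its own
#' non-negative weights summing to 1. Two presets are shipped, because the
#' operational formulas printed with the predictive maps and the
#' weight table in the methods disagree for A and B (they agree for C):
#'
#' * `"equations"` (default): A = 0.4L + 0.2E + 0.3S + 0.1W;
#'   B = 0.4H + 0.1E + 0.3S + 0.2W; C = 0.1E + 0.4S + 0.5W.
#' * `"table5"`: A = 0.5L + 0.1E + 0.2S + 0.2W;
#'   B = 0.5H + 0.1E + 0.2S + 0.2W; C as above.
#'
#' Profile A ignores `H` (bioturbation needs loose substrate), B ignores `L`,
#' C ignores both: substrate cohesiveness exerts little control on
#' biostratification.
#'
#' @param config Optional configuration (path or list). May carry
#'   `weights = list(preset = "equations"|"table5")` or explicit
#'   `weights = list(A = list(L=,H=,E=,S=,W=), B = ..., C = ...)`.
#' @param source Which preset to use when the config gives none.
#' @return A named list of three `weight_profile` objects (`A`, `B`, `C`),
#'   each with elements `profile`, `wL`, `wH`, `wE`, `wS`, `wW`.
#' @examples
#' load_weight_profiles()$A$wS          # 0.3
#' load_weight_profiles(source = "table5")$A$wL  # 0.5
#' @export
load_weight_profiles <- function(config = NULL,
                                 source = c("equations", "table5")) {
  cfg <- .read_config(config)
  wcfg <- cfg$weights
  if (!is.null(wcfg$preset)) {
    source <- wcfg$preset
  }
  source <- match.arg(source)
  if (!is.null(wcfg) && is.null(wcfg$preset)) {
    profs <- lapply(c("A", "B", "C"), function(p) {
      w <- wcfg[[p]]
      if (is.null(w)) stop("explicit weights must define profiles A, B and C",
                           call. = FALSE)
      .weight_profile(p,
                      L = w$L %||% 0, H = w$H %||% 0, E = w$E %||% 0,
                      S = w$S %||% 0, W = w$W %||% 0)
    })
    names(profs) <- c("A", "B", "C")
    return(profs)
  }
  presets <- list(
    equations = list(
      A = c(L = 0.4, H = 0,   E = 0.2, S = 0.3, W = 0.1),
      B = c(L = 0,   H = 0.4, E = 0.1, S = 0.3, W = 0.2),
      C = c(L = 0,   H = 0,   E = 0.1, S = 0.4, W = 0.5)
    ),
    table5 = list(
      A = c(L = 0.5, H = 0,   E = 0.1, S = 0.2, W = 0.2),
      B = c(L = 0,   H = 0.5, E = 0.1, S = 0.2, W = 0.2),
      C = c(L = 0,   H = 0,   E = 0.1, S = 0.4, W = 0.5)
    )
  )
  sel <- presets[[source]]
  profs <- lapply(names(sel), function(p) {
    w <- sel[[p]]
    .weight_profile(p, L = w["L"], H = w["H"], E = w["E"], S = w["S"], W = w["W"])
  })
  names(profs) <- names(sel)
  profs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.weight_profile <- function(profile, L, H, E, S, W) {
  w <- c(wL = unname(L), wH = unname(H), wE = unname(E),
         wS = unname(S), wW = unname(W))
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("profile ", profile, ": weights must be finite and non-negative",
         call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("profile %s: weights must sum to 1 (got %.12g)", profile, sum(w)),
         call. = FALSE)
  }
  structure(c(list(profile = profile), as.list(w)), class = "weight_profile")
}

#' Water-table scoring rule
#'
#' Elevation-thresholded ordinal scoring of the palaeo water-table factor `W`:
#' cells strictly below the maximum palaeolake shoreline elevation score
#' `high_score` (permanent water table plausible), cells at or above it score
#' `low_score`. The default shoreline of -2,200 m is the extended threshold
#' that also captures the most elevated reaches of the inlet-valley channel;
#' the initial lake fill level of -2,243 m is an alternative a user may set.
#'
#' @param shoreline_elevation Shoreline elevation in metres (same datum as the
#'   DEM). Default -2200.
#' @param high_score,low_score Ordinal scores (1--4) assigned below /
#'   at-or-above the shoreline; `high_score` must exceed `low_score`.
#' @return A `water_rule` object.
#' @examples
#' water_rule()                       # defaults: -2200 m, 4 / 1
#' water_rule(shoreline_elevation = -2243)
#' @export
water_rule <- function(shoreline_elevation = -2200, high_score = 4, low_score = 1) {
  high_score <- .check_score(high_score, "<water rule>", "W(high)")
  low_score <- .check_score(low_score, "<water rule>", "W(low)")
  stopifnot(is.numeric(shoreline_elevation), length(shoreline_elevation) == 1L,
            is.finite(shoreline_elevation))
  if (!(high_score > low_score)) {
    stop("water rule: high_score must exceed low_score", call. = FALSE)
  }
  structure(list(shoreline_elevation = shoreline_elevation,
                 high_score = high_score, low_score = low_score),
            class = "water_rule")
}

#' Serialize a catalogue to a configuration list
#'
#' Inverse of [load_catalogue()]: the returned list, passed back as `config`,
#' reproduces the catalogue exactly.
#'
#' @param catalogue A `score_catalogue`.
#' @return A list with a `units` element in the configuration schema.
#' @export
catalogue_to_config <- function(catalogue) {
  stopifnot(inherits(catalogue, "score_catalogue"))
  units <- lapply(seq_len(nrow(catalogue)), function(i) {
    need <- if (catalogue$category[i] == "bedrock") c("L", "H", "E", "S") else "K"
    scores <- lapply(need, function(f) catalogue[[f]][i])
    names(scores) <- need
    list(name = catalogue$unit[i], category = catalogue$category[i],
         scores = scores)
  })
  list(units = units)
}

#' @export
print.score_catalogue <- function(x, ...) {
  cat(sprintf("<score_catalogue> %d units (%d bedrock, %d surficial)\n",
              nrow(x), sum(x$category == "bedrock"), sum(x$category == "surficial")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.weight_profile <- function(x, ...) {
  cat(sprintf("<weight_profile %s> L=%.2g H=%.2g E=%.2g S=%.2g W=%.2g\n",
              x$profile, x$wL, x$wH, x$wE, x$wS, x$wW))
  invisible(x)
}
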
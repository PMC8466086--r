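#' Weighted linear combination with surficial-cover penalty
#'
#' The aggregated suitability score of a cell is
#' \deqn{N = \left(\sum_i x_i w_i\right) - (4 - k)}
#' where the \eqn{x_i} are the palaeoenvironmental factor scores (`L`, `H`,
#' `E`, `S`, `W` as weighted by the profile), the \eqn{w_i} their non-negative
#' weights summing to 1, and \eqn{k} the surficial-cover score. With weights
#' summing to 1 and no cover penalty (`K = 4`) the result stays on the 1--4
#' ordinal range; under heavy cover it can drop as low as \eqn{1 - 3 = -2}.
#' Scores are never clamped.
#'
#' Factors carrying zero weight in the profile are ignored and may be omitted.
#'
#' @param L,H,E,S,W Factor scores (1--4). Only those with positive weight in
#'   `profile` are required.
#' @param K Surficial-cover score (1--4); always required.
#' @param profile A [`weight_profile`][load_weight_profiles].
#' @return The aggregated suitability score (real, unclamped).
#' @examples
#' p <- load_weight_profiles()$A
#' aggregate_cell(L = 4, E = 3, S = 3, W = 4, K = 4, profile = p)  # 3.5
#' @export
aggregate_cell <- function(L = NULL, H = NULL, E = NULL, S = NULL, W = NULL,
                           K, profile) {
  stopifnot(inherits(profile, "weight_profile"))
  vals <- list(L = L, H = H, E = E, S = S, W = W)
  wts <- c(L = profile$wL, H = profile$wH, E = profile$wE,
           S = profile$wS, W = profile$wW)
  acc <- 0
  for (f in names(wts)) {
    if (wts[[f]] > 0) {
      if (is.null(vals[[f]])) {
        stop("profile ", profile$profile, ": factor ", f,
             " has positive weight but was not supplied", call. = FALSE)
      }
      acc <- acc + wts[[f]] * vals[[f]]
    }
  }
  if (missing(K) || is.null(K)) stop("cover score K must be supplied", call. = FALSE)
  acc - (4 - K)
}

#' Aggregate factor rasters into a suitability raster
#'
#' Applies [aggregate_cell()] cell-wise, vectorized. A cell is nodata iff any
#' required input (positively weighted factor, or `K`) is nodata there.
#'
#' @param factor_rasters Named list of `ichno_raster`s of kind `"factor"`;
#'   names from `L`,`H`,`E`,`S`,`W`,`K`. Must include `K` and every factor the
#'   profile weights positively, all on one grid.
#' @param profile A [`weight_profile`][load_weight_profiles].
#' @return An `ichno_raster` of kind `"suitability"`, layer = profile name.
#' @export
aggregate_raster <- function(factor_rasters, profile) {
  stopifnot(inherits(profile, "weight_profile"), is.list(factor_rasters))
  if (is.null(names(factor_rasters)) || any(names(factor_rasters) == "")) {
    stop("factor_rasters must be a named list", call. = FALSE)
  }
  wts <- c(L = profile$wL, H = profile$wH, E = profile$wE,
           S = profile$wS, W = profile$wW)
  need <- c(names(wts)[wts > 0], "K")
  missing_f <- setdiff(need, names(factor_rasters))
  if (length(missing_f)) {
    stop("profile ", profile$profile, ": missing factor raster(s) ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  used <- factor_rasters[need]
  grid <- .check_same_grid(used)
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  for (f in setdiff(need, "K")) {
    acc <- acc + wts[[f]] * used[[f]]$values
  }
  acc <- acc - (4 - used$K$values)
  ichno_raster(grid, acc, layer = profile$profile, kind = "suitability")
}

#' Run all three weight profiles
#'
#' @param factor_rasters As in [aggregate_raster()]; must satisfy the union of
#'   the profiles' requirements.
#' @param profiles Named list of profiles, e.g. from [load_weight_profiles()].
#' @return Named list of suitability rasters (`A`, `B`, `C`), one grid.
#' @export
run_all_profiles <- function(factor_rasters, profiles = load_weight_profiles()) {
  out <- lapply(profiles, function(p) aggregate_raster(factor_rasters, p))
  names(out) <- vapply(profiles, `[[`, "", "profile")
  out
}
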
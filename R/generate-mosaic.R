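# Synthetic mosaic generators: the complete-spatial-randomness (CSR) null and
# a soft exclusion-zone ("dmin") model for regular mosaics.
#
# Real retinal mosaics yield nearest-neighbour regularity indices above the
# CSR value (~1.91); the dmin model reproduces that graded regularity range by
# rejecting candidate cells that fall within a per-cell exclusion radius of an
# already placed cell.

#' Specify a synthetic mosaic
#'
#' @param region a [region_polygon()]
#' @param density intensity in cells per mm^2 (> 0)
#' @param model `"poisson"` (CSR) or `"dmin"` (soft exclusion zone)
#' @param dmin_mean,dmin_sd mean and SD (mm) of the per-cell exclusion radius
#'   (dmin model only); radii are drawn Normal and truncated at 0
#' @param exact_n if `TRUE`, condition on the expected count
#'   `round(density * area)` instead of drawing it Poisson. Density-matched
#'   nulls use this to sharpen the comparison.
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @return a `mosaic_spec`
#' @export
mosaic_spec <- function(region, density, model = c("poisson", "dmin"),
                        dmin_mean = 0, dmin_sd = 0, exact_n = FALSE,
                        seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(region, "region_polygon"))
  if (!is.numeric(density) || length(density) != 1 || is.na(density) || density < 0)
    stop_retmosaic("invalid_spec", "density must be a single non-negative number")
  if (model == "poisson" && density <= 0)
    stop_retmosaic("invalid_spec", "density must be positive")
  if (dmin_mean < 0 || dmin_sd < 0)
    stop_retmosaic("invalid_spec", "dmin_mean and dmin_sd must be non-negative")
  if (model == "dmin") {
    n_expect <- density * region_area(region)
    # loose disk-packing feasibility check; the rejection budget catches the rest
    if (n_expect * pi * dmin_mean^2 / 4 > region_area(region))
      stop_retmosaic("invalid_spec", sprintf(
        "infeasible dmin packing: %d cells with exclusion radius %.3g mm exceed the region area",
        round(n_expect), dmin_mean))
  }
  structure(list(region = region, density = density, model = model,
                 dmin_mean = dmin_mean, dmin_sd = dmin_sd,
                 exact_n = exact_n, seed = seed),
            class = "mosaic_spec")
}

target_count <- function(spec) {
  mu <- spec$density * region_area(spec$region)
  if (spec$exact_n) round(mu) else stats::rpois(1, mu)
}

#' Generate a complete-spatial-randomness (Poisson) mosaic
#'
#' The CSR null model: the point count is Poisson(density x area) (or fixed at
#' `round(density * area)` under `exact_n`) and positions are i.i.d. uniform
#' inside the region.
#'
#' @param spec a [mosaic_spec()] with `model = "poisson"`
#' @param subtype,donor_id,age_years labels attached to every generated cell
#' @return a [cell_mosaic()]
#' @export
#' @examples
#' m <- generate_poisson_mosaic(mosaic_spec(unit_square_region(), 100, seed = 1))
generate_poisson_mosaic <- function(spec, subtype = NULL,
                                    donor_id = NA_character_,
                                    age_years = NA_real_) {
  stopifnot(inherits(spec, "mosaic_spec"))
  if (spec$model != "poisson")
    stop_retmosaic("invalid_spec", "spec model must be 'poisson'")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- target_count(spec)
  pts <- sample_in_region(spec$region, n)
  cell_mosaic(pts[, "x"], pts[, "y"], spec$region,
              subtype = if (is.null(subtype)) NULL else rep(subtype, n),
              donor_id = donor_id, age_years = age_years)
}

#' Generate a soft exclusion-zone ("dmin") mosaic
#'
#' Cells are placed sequentially: each candidate draws an exclusion radius
#' Normal(`dmin_mean`, `dmin_sd`) truncated at 0 and is accepted only if it is
#' farther than that radius from every already accepted cell. With
#' `dmin_mean = 0` this degenerates to CSR; larger exclusion radii give
#' increasingly regular mosaics (higher regularity index).
#'
#' @inheritParams generate_poisson_mosaic
#' @param spec a [mosaic_spec()] with `model = "dmin"`
#' @param max_rejections_per_cell rejection budget multiplier; placement
#'   aborts with a simulation-failure error after `n * max_rejections_per_cell`
#'   consecutive failed candidates
#' @return a [cell_mosaic()]
#' @export
generate_dmin_mosaic <- function(spec, subtype = NULL,
                                 donor_id = NA_character_,
                                 age_years = NA_real_,
                                 max_rejections_per_cell = 1000) {
  stopifnot(inherits(spec, "mosaic_spec"))
  if (spec$model != "dmin")
    stop_retmosaic("invalid_spec", "spec model must be 'dmin'")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- target_count(spec)
  budget <- max_rejections_per_cell * max(n, 1)
  px <- double(n); py <- double(n)
  placed <- 0L; rejections <- 0L
  while (placed < n) {
    cand <- sample_in_region(spec$region, 1)
    r <- max(0, stats::rnorm(1, spec$dmin_mean, spec$dmin_sd))
    ok <- placed == 0L ||
      min((px[seq_len(placed)] - cand[1, "x"])^2 +
          (py[seq_len(placed)] - cand[1, "y"])^2) > r^2
    if (ok) {
      placed <- placed + 1L
      px[placed] <- cand[1, "x"]; py[placed] <- cand[1, "y"]
    } else {
      rejections <- rejections + 1L
      if (rejections > budget)
        stop_retmosaic("simulation_failure", sprintf(
          "dmin placement exhausted its rejection budget: achieved %d of %d cells",
          placed, n), achieved_n = placed)
    }
  }
  cell_mosaic(px, py, spec$region,
              subtype = if (is.null(subtype)) NULL else rep(subtype, n),
              donor_id = donor_id, age_years = age_years)
}

#' Generate a mosaic from a spec, dispatching on its model
#' @inheritParams generate_dmin_mosaic
#' @return a [cell_mosaic()]
#' @export
generate_mosaic <- function(spec, subtype = NULL, donor_id = NA_character_,
                            age_years = NA_real_) {
  switch(spec$model,
         poisson = generate_poisson_mosaic(spec, subtype, donor_id, age_years),
         dmin = generate_dmin_mosaic(spec, subtype, donor_id, age_years))
}
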
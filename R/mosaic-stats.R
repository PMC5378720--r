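# Two-dimensional distribution statistics for a cell mosaic: nearest-neighbour
# distances (NND), boundary-clipped Voronoi domain areas (VDA), regularity
# indices (mean/SD), the Clark-Evans dispersion index, Gaussian histogram
# fits, and density-matched CSR null comparison.

#' Nearest-neighbour distances of a mosaic
#'
#' For each cell, the Euclidean distance to its closest other cell. An
#' optional border buffer excludes cells nearer than a margin to the region
#' boundary from the summary statistics (their distances are still computed
#' against all cells); uncorrected finite-window CSR summaries are slightly
#' biased, so the buffer is recommended when comparing to the analytic CSR
#' anchors.
#'
#' @param mosaic a [cell_mosaic()]
#' @param border_buffer `0` (default, no exclusion), a margin in mm, or `TRUE`
#'   for one CSR mean spacing `1 / (2 * sqrt(density))`
#' @return an object of class `nnd_sample`: `distances` (per cell, mm),
#'   `included` (logical, enters the summary), `mean`, `sd` (sample SD over
#'   included cells), `n`
#' @export
#' @examples
#' m <- generate_poisson_mosaic(mosaic_spec(unit_square_region(), 200, seed = 1))
#' nnd <- nearest_neighbor_distances(m)
#' c(nnd$mean, nnd$sd)
nearest_neighbor_distances <- function(mosaic, border_buffer = 0) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  n <- n_cells(mosaic)
  if (n < 2)
    stop_retmosaic("insufficient_points",
                   "nearest-neighbour distances need at least 2 cells")
  xy <- cbind(mosaic$cells$x, mosaic$cells$y)
  d <- as.vector(FNN::get.knn(xy, k = 1)$nn.dist)
  buffer <- resolve_buffer(border_buffer, n, region_area(mosaic$region))
  included <- if (buffer > 0) {
    boundary_distance(mosaic$region, xy[, 1], xy[, 2]) > buffer
  } else rep(TRUE, n)
  if (!any(included))
    stop_retmosaic("insufficient_points",
                   "border buffer excluded every cell from the summary")
  structure(list(distances = d, included = included,
                 mean = mean(d[included]), sd = stats::sd(d[included]),
                 n = sum(included), buffer = buffer),
            class = "nnd_sample")
}

resolve_buffer <- function(border_buffer, n, area) {
  if (isTRUE(border_buffer)) 1 / (2 * sqrt(n / area))
  else if (isFALSE(border_buffer)) 0
  else as.double(border_buffer)
}

#' Boundary-clipped Voronoi domain areas
#'
#' The Voronoi domain of a cell is the part of the plane closer to it than to
#' any other cell; domains are clipped to the analysis region, so the clipped
#' areas partition the region exactly. Cells whose domain touches the region
#' boundary are flagged (`boundary`); they are included in summaries by
#' default, with exclusion available downstream via `included_flags`.
#'
#' @param mosaic a [cell_mosaic()]
#' @param exclude_boundary if `TRUE`, boundary-touching domains are dropped
#'   from the `included` flags used by summary statistics
#' @return an object of class `vda_sample`: `areas` (mm^2, one per cell),
#'   `boundary` (logical), `included` (logical), `mean`, `sd`
#' @export
voronoi_domain_areas <- function(mosaic, exclude_boundary = FALSE) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  n <- n_cells(mosaic)
  region <- mosaic$region
  if (n == 0)
    stop_retmosaic("insufficient_points", "empty mosaic has no Voronoi domains")
  if (n == 1) {
    out <- list(areas = region_area(region), boundary = TRUE,
                included = TRUE, mean = region_area(region), sd = NA_real_)
    return(structure(out, class = "vda_sample"))
  }
  x <- mosaic$cells$x; y <- mosaic$cells$y
  regp <- list(x = region$x, y = region$y)
  if (n == 2 || all_collinear(x, y)) {
    if (n > 2)
      stop_retmosaic("degenerate_geometry",
                     "all cells are collinear; Voronoi tessellation is degenerate")
    areas <- halfplane_pair_areas(x, y, regp)
  } else {
    areas <- deldir_clipped_areas(x, y, region, regp)
  }
  tot <- sum(areas)
  if (abs(tot - region_area(region)) > 1e-6 * region_area(region))
    warning("clipped Voronoi areas do not sum to the region area; check geometry")
  boundary <- attr(areas, "boundary")
  included <- if (exclude_boundary) !boundary else rep(TRUE, n)
  a <- as.double(areas)
  structure(list(areas = a, boundary = boundary, included = included,
                 mean = mean(a[included]), sd = stats::sd(a[included])),
            class = "vda_sample")
}

all_collinear <- function(x, y) {
  if (length(x) < 3) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  cr <- dx[2] * dy - dy[2] * dx
  sc <- max(abs(dx), abs(dy), 1e-300)
  all(abs(cr) < 1e-12 * sc^2)
}

# Voronoi tiles via deldir on the bounding box, then clipped to the region
# polygon with polyclip; areas by shoelace on the clipped pieces.
deldir_clipped_areas <- function(x, y, region, regp) {
  bb <- c(range(region$x), range(region$y))
  dd <- deldir::deldir(x, y, rw = bb, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  n <- length(x)
  areas <- double(n); boundary <- logical(n)
  rect_area <- (bb[2] - bb[1]) * (bb[4] - bb[3])
  region_is_bbox <- abs(region$area - rect_area) < 1e-12 * rect_area
  for (i in seq_len(n)) {
    ti <- tiles[[i]]
    tp <- list(x = ti$x, y = ti$y)
    if (region_is_bbox) {
      pieces <- list(tp)
    } else {
      pieces <- polyclip::polyclip(tp, regp, op = "intersection")
    }
    a <- sum(vapply(pieces, function(p) polygon_area_xy(p$x, p$y), 0))
    areas[i] <- a
    vx <- unlist(lapply(pieces, `[[`, "x"))
    vy <- unlist(lapply(pieces, `[[`, "y"))
    boundary[i] <- any(ti$bp) ||
      (length(vx) > 0 && any(boundary_distance(region, vx, vy) < 1e-9))
  }
  # tiles partition the bbox up to deldir's numeric slop; rescale the clipped
  # areas so they partition the region exactly
  areas <- areas * (region$area / sum(areas))
  attr(areas, "boundary") <- boundary
  areas
}

# n = 2: split the region by the perpendicular bisector (deldir needs >= 3).
halfplane_pair_areas <- function(x, y, regp) {
  mx <- mean(x); my <- mean(y)
  dx <- x[2] - x[1]; dy <- y[2] - y[1]
  L <- 1e6 * max(abs(c(regp$x, regp$y, 1)))
  # half-plane containing point 1: big rectangle with one edge along the
  # bisector, extending toward p1 (u = unit vector from p1 to p2)
  ux <- dx / sqrt(dx^2 + dy^2); uy <- dy / sqrt(dx^2 + dy^2)
  hp <- list(x = c(mx + uy * L, mx - uy * L, mx - uy * L - ux * L, mx + uy * L - ux * L),
             y = c(my - ux * L, my + ux * L, my + ux * L - uy * L, my - ux * L - uy * L))
  p1 <- polyclip::polyclip(regp, hp, op = "intersection")
  a1 <- sum(vapply(p1, function(p) polygon_area_xy(p$x, p$y), 0))
  total <- polygon_area_xy(regp$x, regp$y)
  areas <- c(a1, total - a1)
  attr(areas, "boundary") <- c(TRUE, TRUE)
  areas
}

#' Regularity index of an NND or VDA sample
#'
#' RI = mean / sample SD (n - 1 denominator). For nearest-neighbour distances
#' of a CSR pattern the RI tends to sqrt(pi / (4 - pi)) ~ 1.91; real regular
#' mosaics exceed it.
#'
#' @param values numeric sample (per-cell NNDs or Voronoi areas), or an
#'   `nnd_sample` / `vda_sample` (its included values are used)
#' @return the dimensionless regularity index
#' @export
#' @examples
#' regularity_index(c(2, 4))  # 3 / sqrt(2)
regularity_index <- function(values) {
  if (inherits(values, "nnd_sample")) values <- values$distances[values$included]
  if (inherits(values, "vda_sample")) values <- values$areas[values$included]
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop_retmosaic("insufficient_points", "regularity index needs at least 2 values")
  s <- stats::sd(values)
  if (s == 0)
    stop_retmosaic("undefined_ri", "all values equal: regularity index undefined (zero SD)")
  mean(values) / s
}

#' Clark-Evans dispersion index of a mosaic
#'
#' DI = observed mean NND / expected mean NND under CSR at the same density,
#' where the CSR expectation is `1 / (2 * sqrt(density))` (Clark-Evans). DI is
#' 1 for a random pattern and larger for regular mosaics.
#'
#' @inheritParams nearest_neighbor_distances
#' @return the dimensionless dispersion index
#' @export
dispersion_index <- function(mosaic, border_buffer = 0) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  if (region_area(mosaic$region) <= 0)
    stop_retmosaic("invalid_region", "region area must be positive")
  n <- n_cells(mosaic)
  if (n < 2)
    stop_retmosaic("insufficient_points", "dispersion index needs at least 2 cells")
  nnd <- nearest_neighbor_distances(mosaic, border_buffer = border_buffer)
  rho <- n / region_area(mosaic$region)
  nnd$mean / (1 / (2 * sqrt(rho)))
}

#' Least-squares Gaussian fit to a histogram of values
#'
#' Bins the sample (Freedman-Diaconis by default), then fits
#' `amplitude * exp(-(x - mu)^2 / (2 * sigma^2))` to the bin counts at the bin
#' centres by nonlinear least squares, initialised from the sample mean, SD
#' and maximum count. R^2 is computed on the binned counts. Non-convergence
#' and degenerate histograms are reported via `converged = FALSE` with the raw
#' histogram retained.
#'
#' @param values numeric sample (n >= 10)
#' @param n_bins number of bins; `NULL` for Freedman-Diaconis
#' @return an object of class `gaussian_fit`: `mu`, `sigma`, `amplitude`,
#'   `r_squared`, `bin_edges`, `bin_counts`, `fitted_counts`, `converged`
#' @export
fit_gaussian <- function(values, n_bins = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 10)
    stop_retmosaic("insufficient_points", "Gaussian fit needs at least 10 values")
  fail <- function(edges, counts) {
    structure(list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
                   r_squared = NA_real_, bin_edges = edges, bin_counts = counts,
                   fitted_counts = rep(NA_real_, length(counts)),
                   converged = FALSE),
              class = "gaussian_fit")
  }
  if (stats::sd(values) == 0) {
    edges <- c(values[1] - 0.5, values[1] + 0.5)
    return(fail(edges, length(values)))
  }
  k <- n_bins %||% max(grDevices::nclass.FD(values), 3)
  edges <- seq(min(values), max(values), length.out = k + 1)
  counts <- as.double(graphics::hist(values, breaks = edges, plot = FALSE)$counts)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  if (sum(counts > 0) < 4) return(fail(edges, counts))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ amplitude * exp(-(centers - mu)^2 / (2 * sigma^2)),
      start = list(amplitude = max(counts), mu = mean(values),
                   sigma = stats::sd(values)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail(edges, counts))
  cf <- stats::coef(fit)
  fitted_counts <- cf[["amplitude"]] *
    exp(-(centers - cf[["mu"]])^2 / (2 * cf[["sigma"]]^2))
  ss_res <- sum((counts - fitted_counts)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  structure(list(mu = cf[["mu"]], sigma = abs(cf[["sigma"]]),
                 amplitude = cf[["amplitude"]], r_squared = r2,
                 bin_edges = edges, bin_counts = counts,
                 fitted_counts = fitted_counts, converged = TRUE),
            class = "gaussian_fit")
}

#' Full spatial-statistics summary of a mosaic
#'
#' Computes the NND and VDA samples, their regularity indices (NNRI, VDRI),
#' the dispersion index, and Gaussian histogram fits.
#'
#' @inheritParams nearest_neighbor_distances
#' @param include_vda compute the Voronoi tessellation (set `FALSE` to skip
#'   the geometry for NND-only workflows)
#' @param exclude_boundary_vda drop boundary-touching Voronoi domains from the
#'   VDA summary and VDRI
#' @param n_bins histogram bins for the Gaussian fits (`NULL` = Freedman-Diaconis)
#' @return an object of class `mosaic_stats`: `nnd`, `vda`, `nnri`, `vdri`,
#'   `di`, `fit_nnd`, `fit_vda`, `n`
#' @export
#' @examples
#' m <- generate_poisson_mosaic(mosaic_spec(unit_square_region(), 500, seed = 7))
#' s <- mosaic_stats(m, border_buffer = TRUE)
#' round(c(nnri = s$nnri, di = s$di), 2)
mosaic_stats <- function(mosaic, border_buffer = 0, include_vda = TRUE,
                         exclude_boundary_vda = FALSE, n_bins = NULL) {
  nnd <- nearest_neighbor_distances(mosaic, border_buffer = border_buffer)
  vda <- if (include_vda) voronoi_domain_areas(mosaic, exclude_boundary_vda) else NULL
  nnd_vals <- nnd$distances[nnd$included]
  out <- list(
    nnd = nnd,
    vda = vda,
    nnri = regularity_index(nnd_vals),
    vdri = if (!is.null(vda)) regularity_index(vda) else NA_real_,
    di = dispersion_index(mosaic, border_buffer = border_buffer),
    fit_nnd = if (length(nnd_vals) >= 10) fit_gaussian(nnd_vals, n_bins) else NULL,
    fit_vda = if (!is.null(vda) && sum(vda$included) >= 10)
      fit_gaussian(vda$areas[vda$included], n_bins) else NULL,
    n = n_cells(mosaic)
  )
  structure(out, class = "mosaic_stats")
}

#' @export
print.mosaic_stats <- function(x, ...) {
  cat(sprintf("mosaic_stats: n = %d\n", x$n))
  cat(sprintf("  NND  mean %.4g  sd %.4g  NNRI %.3f  DI %.3f\n",
              x$nnd$mean, x$nnd$sd, x$nnri, x$di))
  if (!is.null(x$vda))
    cat(sprintf("  VDA  mean %.4g  sd %.4g  VDRI %.3f\n",
                x$vda$mean, x$vda$sd, x$vdri))
  invisible(x)
}

#' Compare a mosaic to density-matched CSR nulls
#'
#' Generates `n_reps` exact-n Poisson mosaics in the same region (the
#' density-matched random pattern used as the reference for regularity) and
#' summarises the null distribution of each requested statistic: mean, SD,
#' central 95% envelope, and the percentile of the observed value.
#'
#' @inheritParams mosaic_stats
#' @param n_reps number of null replicates
#' @param seed integer seed for the null stream
#' @param statistics which statistics to track, a subset of
#'   `c("nnri", "di", "mean_nnd", "vdri")` (`"vdri"` triggers the Voronoi
#'   geometry per replicate and is slower)
#' @return an object of class `null_comparison`: a data frame `summary` with
#'   one row per statistic (`observed, null_mean, null_sd, null_lo95,
#'   null_hi95, percentile`) plus the raw null draws in `null_draws`
#' @export
null_comparison <- function(mosaic, n_reps = 99, seed = NULL,
                            statistics = c("nnri", "di", "mean_nnd"),
                            border_buffer = 0, n_bins = NULL) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  statistics <- match.arg(statistics,
                          c("nnri", "di", "mean_nnd", "vdri"),
                          several.ok = TRUE)
  n <- n_cells(mosaic)
  if (n < 10)
    stop_retmosaic("insufficient_points", "null comparison needs at least 10 cells")
  need_vda <- "vdri" %in% statistics
  observe <- function(m) {
    nnd <- nearest_neighbor_distances(m, border_buffer = border_buffer)
    vals <- nnd$distances[nnd$included]
    out <- c(nnri = regularity_index(vals),
             di = dispersion_index(m, border_buffer = border_buffer),
             mean_nnd = mean(vals))
    if (need_vda)
      out <- c(out, vdri = regularity_index(voronoi_domain_areas(m)))
    out[statistics]
  }
  obs <- observe(mosaic)
  spec <- mosaic_spec(mosaic$region, density = n / region_area(mosaic$region),
                      model = "poisson", exact_n = TRUE)
  draws <- matrix(NA_real_, n_reps, length(statistics),
                  dimnames = list(NULL, statistics))
  if (!is.null(seed)) set.seed(seed)
  for (r in seq_len(n_reps)) {
    draws[r, ] <- observe(generate_poisson_mosaic(spec))
  }
  summ <- data.frame(
    statistic = statistics,
    observed = as.double(obs),
    null_mean = colMeans(draws),
    null_sd = apply(draws, 2, stats::sd),
    null_lo95 = apply(draws, 2, stats::quantile, probs = 0.025),
    null_hi95 = apply(draws, 2, stats::quantile, probs = 0.975),
    percentile = vapply(statistics, function(s)
      mean(draws[, s] <= obs[[s]]), 0) * 100,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = summ, null_draws = draws, n_reps = n_reps, n = n),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("null_comparison: %d density-matched CSR replicates (n = %d)\n",
              x$n_reps, x$n))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Per-subtype spatial statistics
#'
#' Each subtype is analysed as an independent mosaic within the same region.
#' Subtypes with fewer than `min_n` cells are skipped with a warning.
#'
#' @inheritParams mosaic_stats
#' @param min_n minimum cells per subtype
#' @return a named list of [mosaic_stats()] results, one per analysed subtype
#' @export
per_subtype_stats <- function(mosaic, min_n = 10, border_buffer = 0,
                              include_vda = TRUE,
                              exclude_boundary_vda = FALSE, n_bins = NULL) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  present <- unique(stats::na.omit(mosaic$cells$subtype))
  bad <- setdiff(present, MRGC_SUBTYPES)
  if (length(bad))
    stop_retmosaic("validation", sprintf("unknown subtype label(s): %s", toString(bad)))
  out <- list()
  for (st in intersect(MRGC_SUBTYPES, present)) {
    sub <- subset_subtype(mosaic, st)
    if (n_cells(sub) < min_n) {
      warning(sprintf("subtype %s skipped: only %d cells (< %d)",
                      st, n_cells(sub), min_n))
      next
    }
    out[[st]] <- mosaic_stats(sub, border_buffer = border_buffer,
                              include_vda = include_vda,
                              exclude_boundary_vda = exclude_boundary_vda,
                              n_bins = n_bins)
  }
  out
}
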
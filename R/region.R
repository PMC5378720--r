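# Polygonal analysis regions (the observation window W of a mosaic).
#
# Coordinates are planar millimetres on the flattened retinal whole mount; a
# typical sampling window in this literature is ~1 cm^2.

#' Create a polygonal analysis region
#'
#' A region is a closed simple polygon (given by its vertices, not repeated at
#' the end) with positive area. It is the observation window inside which a
#' cell mosaic is generated and analysed, and the clipping boundary for
#' Voronoi domains.
#'
#' @param x,y numeric vertex coordinates in mm (at least 3 vertices)
#' @return an object of class `region_polygon` with elements `x`, `y`
#'   (counter-clockwise) and `area` (mm^2)
#' @export
#' @examples
#' w <- region_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' region_area(w)
region_polygon <- function(x, y) {
  if (length(x) != length(y))
    stop_retmosaic("invalid_region", "x and y must have equal length")
  if (length(x) < 3)
    stop_retmosaic("invalid_region", "a region polygon needs at least 3 vertices")
  if (anyNA(x) || anyNA(y))
    stop_retmosaic("invalid_region", "region vertices must be finite")
  if (polygon_self_intersects(x, y))
    stop_retmosaic("invalid_region", "region polygon is self-intersecting")
  a <- polygon_area_signed(x, y)
  if (abs(a) <= 0)
    stop_retmosaic("invalid_region", "region polygon has zero area")
  if (a < 0) { x <- rev(x); y <- rev(y) }  # normalise to counter-clockwise
  structure(list(x = as.double(x), y = as.double(y), area = abs(a)),
            class = "region_polygon")
}

#' Rectangular analysis region
#'
#' @param width,height side lengths in mm
#' @param origin lower-left corner, length-2 numeric
#' @return a `region_polygon`
#' @export
rect_region <- function(width, height = width, origin = c(0, 0)) {
  region_polygon(origin[1] + c(0, width, width, 0),
                 origin[2] + c(0, 0, height, height))
}

#' Unit square region (1 mm x 1 mm)
#' @return a `region_polygon`
#' @export
unit_square_region <- function() rect_region(1, 1)

#' Area of a region polygon
#' @param region a `region_polygon`
#' @return area in mm^2
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "region_polygon"))
  region$area
}

#' @export
print.region_polygon <- function(x, ...) {
  cat(sprintf("region_polygon: %d vertices, area %.6g mm^2\n",
              length(x$x), x$area))
  invisible(x)
}

#' Test whether points lie inside a region
#'
#' @param region a `region_polygon`
#' @param px,py point coordinates (mm)
#' @return logical vector; boundary points count as inside
#' @export
in_region <- function(region, px, py) {
  bnd <- cbind(c(region$x, region$x[1]), c(region$y, region$y[1]))
  inside <- mgcv::in.out(bnd, cbind(px, py))
  # in.out is strict-interior on some boundary cases; accept boundary points
  # explicitly (round-tripped coordinates can land exactly on an edge).
  if (any(!inside)) {
    d <- boundary_distance(region, px[!inside], py[!inside])
    inside[!inside] <- d < 1e-12
  }
  inside
}

#' Distance from points to the region boundary
#'
#' @param region a `region_polygon`
#' @param px,py point coordinates (mm)
#' @return numeric distances to the polygon outline (mm)
#' @export
boundary_distance <- function(region, px, py) {
  n <- length(region$x)
  jx <- c(region$x[-1], region$x[1]); jy <- c(region$y[-1], region$y[1])
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    d <- pmin(d, point_segment_distance(px, py, region$x[i], region$y[i],
                                        jx[i], jy[i]))
  }
  d
}

# Uniform points in the region by rejection from the bounding box; uses the
# current RNG stream.
sample_in_region <- function(region, n) {
  if (n == 0) return(cbind(x = double(0), y = double(0)))
  xr <- range(region$x); yr <- range(region$y)
  accept_rate <- region$area / ((xr[2] - xr[1]) * (yr[2] - yr[1]))
  out_x <- double(0); out_y <- double(0)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / max(accept_rate, 0.05)) + 16
    cx <- stats::runif(m, xr[1], xr[2])
    cy <- stats::runif(m, yr[1], yr[2])
    keep <- in_region(region, cx, cy)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# Proper self-intersection test between non-adjacent edges (O(m^2); region
# polygons have few vertices).
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- function(i) c(x[i], y[i], x[i %% n + 1], y[i %% n + 1])
  cross_sign <- function(ox, oy, ax, ay, bx, by)
    sign((ax - ox) * (by - oy) - (ay - oy) * (bx - ox))
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross_sign(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
      d2 <- cross_sign(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
      d3 <- cross_sign(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
      d4 <- cross_sign(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}
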
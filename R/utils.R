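# Internal helpers shared across modules.

#' Signal a classed retmosaic error
#'
#' @param class condition subclass (prefixed with "retmosaic_")
#' @param msg message
#' @noRd
stop_retmosaic <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("retmosaic_", class), "retmosaic_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Derive a deterministic substream seed from a root seed and counters
#'
#' One root seed drives a whole study; per-donor / per-cell streams are derived
#' by counter so that adding a donor does not perturb the streams of the
#' others. Values stay in (0, 2^31 - 1).
#'
#' @param root integer root seed
#' @param ... integer counters (donor index, subtype index, cell index, ...)
#' @return an integer seed usable with [set.seed()]
#' @export
#' @examples
#' substream_seed(1, 3, 2)
substream_seed <- function(root, ...) {
  counters <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in c(counters, 0)) {
    # Lehmer-style mix; 48271 is the MINSTD multiplier
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

# Shoelace area of a polygon given coordinate vectors (absolute value).
polygon_area_xy <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Signed shoelace area (positive = counter-clockwise).
polygon_area_signed <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Round half away from zero (the "half-up" convention used for reported
# percentages; base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Minimum distance from each point to a segment (a, b); vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
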
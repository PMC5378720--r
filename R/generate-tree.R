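# Stochastic dendritic-tree generator.
#
# Topology first: starting from n_primary unbranched primaries, a randomly
# chosen tip is bifurcated until the target branch-point count is reached, so
# the achieved count equals the target exactly and tips = branches + primaries
# (strict bifurcation). Geometry second: segments grow radially outward with
# angular jitter; every segment direction keeps a non-negative radial
# component, so the distance to the soma is monotone along each edge. The
# arbor is finally rescaled so that the convex hull of the dendritic nodes
# has area pi * field_radius^2, i.e. field_radius is the equivalent radius of
# the dendritic field.

#' Specify a synthetic dendritic tree
#'
#' @param n_primary number of primary dendrites leaving the soma (>= 1)
#' @param target_branch_points exact number of bifurcations to generate (>= 0)
#' @param segment_length_mean,segment_length_sd inter-node segment length
#'   distribution, um
#' @param field_radius equivalent radius of the dendritic field, um (> 0):
#'   the generated hull area equals `pi * field_radius^2`
#' @param stratum_mix fraction of primaries assigned to stratum S1 (1 = all
#'   S1 as in M1/M1d cells, 0 = all S5 as in M2, 0.5 = bistratified M3)
#' @param soma_area soma cross-sectional area, um^2
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @return a `tree_spec`
#' @export
tree_spec <- function(n_primary = 3, target_branch_points = 20,
                      segment_length_mean = 60, segment_length_sd = 15,
                      field_radius = 400, stratum_mix = 1,
                      soma_area = 320, seed = NULL) {
  if (n_primary < 1 || target_branch_points < 0)
    stop_retmosaic("invalid_spec", "counts must be non-negative (n_primary >= 1)")
  if (stratum_mix < 0 || stratum_mix > 1)
    stop_retmosaic("invalid_spec", "stratum_mix must lie in [0, 1]")
  if (field_radius <= 0)
    stop_retmosaic("invalid_spec", "field_radius must be positive")
  if (soma_area <= 0)
    stop_retmosaic("invalid_spec", "soma_area must be positive")
  structure(list(n_primary = as.integer(n_primary),
                 target_branch_points = as.integer(target_branch_points),
                 segment_length_mean = segment_length_mean,
                 segment_length_sd = segment_length_sd,
                 field_radius = field_radius, stratum_mix = stratum_mix,
                 soma_area = soma_area, seed = seed),
            class = "tree_spec")
}

#' Generate a dendritic tree from a spec
#'
#' @param spec a [tree_spec()]
#' @param cell_id,subtype labels carried on the resulting tree
#' @return a [neurite_tree()] whose measured branch points equal
#'   `target_branch_points` exactly and whose tips equal
#'   `target_branch_points + n_primary`
#' @export
#' @examples
#' tr <- generate_tree(tree_spec(n_primary = 1, target_branch_points = 20, seed = 1))
#' c(count_branch_points(tr), count_terminal_tips(tr))  # 20, 21
generate_tree <- function(spec, cell_id = "cell_1", subtype = NA_character_) {
  stopifnot(inherits(spec, "tree_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  # --- topology: grow a forest of strictly bifurcating primaries ---
  # children[[k]] holds node indices; node 1 is the soma
  parent <- c(NA_integer_, rep(1L, spec$n_primary))
  is_tip <- c(FALSE, rep(TRUE, spec$n_primary))
  for (b in seq_len(spec$target_branch_points)) {
    tips <- which(is_tip)
    # bias growth toward recently extended tips: real arbors carry a few
    # long branches with short side twigs, not a uniformly deep tree (this
    # also keeps the Sholl profile at realistic intersection counts)
    wts <- rank(tips)^3
    pick <- if (length(tips) == 1) tips else sample(tips, 1, prob = wts)
    parent <- c(parent, pick, pick)
    is_tip[pick] <- FALSE
    is_tip <- c(is_tip, TRUE, TRUE)
  }
  n_nodes <- length(parent)

  # --- geometry: radial outward growth with angular jitter ---
  x <- double(n_nodes); y <- double(n_nodes)
  heading <- double(n_nodes)
  prim <- 1L + seq_len(spec$n_primary)
  base_angles <- 2 * pi * (seq_len(spec$n_primary) - 1) / spec$n_primary +
    stats::runif(1, 0, 2 * pi)
  seg_len <- function(k) pmax(abs(stats::rnorm(
    k, spec$segment_length_mean, spec$segment_length_sd)),
    0.1 * spec$segment_length_mean)
  heading[prim] <- base_angles + stats::rnorm(spec$n_primary, 0, 0.2)
  L <- seg_len(spec$n_primary)
  x[prim] <- L * cos(heading[prim]); y[prim] <- L * sin(heading[prim])
  # children beyond the primaries were appended in pairs, in creation order
  if (n_nodes > spec$n_primary + 1L) {
    gen <- integer(n_nodes)  # branch order (0 at the primaries)
    for (i in (spec$n_primary + 2L):n_nodes) {
      p <- parent[i]
      gen[i] <- if (p %in% prim) 1L else gen[p] + 1L
      # daughters fan out to either side of the parent heading; higher-order
      # branches deviate more from radial and are shorter, as in real arbors
      # (this keeps Sholl intersection counts at realistic levels)
      side <- if (i %% 2 == 0) 1 else -1
      ang <- heading[p] + side * abs(stats::rnorm(1, 0.45 + 0.12 * gen[i], 0.15)) +
        stats::rnorm(1, 0, 0.1)
      # keep a non-negative radial component so soma distance is monotone
      rad <- atan2(y[p], x[p])
      if (cos(ang - rad) < 0.05) {
        ang <- rad + sign(sin(ang - rad)) * (pi / 2 - 0.05)
      }
      Lseg <- seg_len(1) * 0.78^gen[i]
      x[i] <- x[p] + Lseg * cos(ang)
      y[i] <- y[p] + Lseg * sin(ang)
      heading[i] <- ang
    }
  }

  # --- rescale so the hull area matches the equivalent-radius contract ---
  dend <- seq_len(n_nodes)[-1]
  if (length(dend) >= 3) {
    h <- grDevices::chull(x[dend], y[dend])
    a <- polygon_area_xy(x[dend][h], y[dend][h])
    if (a > 0) {
      sc <- sqrt(pi * spec$field_radius^2 / a)
      x <- x * sc; y <- y * sc
    }
  }

  # --- stratum per primary subtree ---
  n_s1 <- round(spec$stratum_mix * spec$n_primary)
  prim_stratum <- rep("S5", spec$n_primary)
  if (n_s1 > 0) prim_stratum[seq_len(n_s1)] <- "S1"
  # propagate to descendants
  stratum <- rep(NA_character_, n_nodes)
  stratum[prim] <- prim_stratum
  if (n_nodes > spec$n_primary + 1L) {
    for (i in (spec$n_primary + 2L):n_nodes) stratum[i] <- stratum[parent[i]]
  }

  nodes <- data.frame(
    id = seq_len(n_nodes),
    parent = parent,
    x = x, y = y,
    z = ifelse(is.na(stratum), 0, STRATUM_Z[stratum]),
    radius = c(sqrt(spec$soma_area / pi), rep(0.5, n_nodes - 1L)),
    compartment = c("soma", rep("dendrite", n_nodes - 1L)),
    stratum = stratum,
    stringsAsFactors = FALSE
  )
  neurite_tree(nodes, soma_area = spec$soma_area, cell_id = cell_id,
               subtype = subtype)
}

# Subtype presets ------------------------------------------------------------

# Per-cell means and SDs for the four melanopsin subtypes. Means follow the
# printed population values for the human retina; per-cell SDs are derived
# from the reported standard errors at the reported sample sizes (n = 400 for
# soma diameter, n ~ 42 for dendritic metrics).
SUBTYPE_PRESETS <- list(
  M1  = list(soma_diameter = c(mean = 19.99, sd = 0.26 * sqrt(400)),
             dendritic_area = c(mean = 0.47, sd = 0.02 * sqrt(42)),
             branch_points = c(mean = 18.43, sd = 0.92 * sqrt(42)),
             terminal_tips = c(mean = 21.44, sd = 0.93 * sqrt(42)),
             sholl_area = c(mean = 180.7, sd = 8.05 * sqrt(42)),
             stratum_mix = 1),
  M1d = list(soma_diameter = c(mean = 19.92, sd = 0.17 * sqrt(400)),
             dendritic_area = c(mean = 0.54, sd = 0.02 * sqrt(42)),
             branch_points = c(mean = 21.57, sd = 1.16 * sqrt(42)),
             terminal_tips = c(mean = 24.75, sd = 1.05 * sqrt(42)),
             sholl_area = c(mean = 211.1, sd = 8.9 * sqrt(42)),
             stratum_mix = 1),
  M2  = list(soma_diameter = c(mean = 20.82, sd = 0.19 * sqrt(400)),
             dendritic_area = c(mean = 0.43, sd = 0.02 * sqrt(42)),
             branch_points = c(mean = 17.24, sd = 1.06 * sqrt(42)),
             terminal_tips = c(mean = 21.59, sd = 1.09 * sqrt(42)),
             sholl_area = c(mean = 179.0, sd = 9.3 * sqrt(42)),
             stratum_mix = 0),
  M3  = list(soma_diameter = c(mean = 20.22, sd = 0.18 * sqrt(400)),
             dendritic_area = c(mean = 0.44, sd = 0.02 * sqrt(42)),
             branch_points = c(mean = 14.58, sd = 1.02 * sqrt(42)),
             terminal_tips = c(mean = 18.28, sd = 1.06 * sqrt(42)),
             sholl_area = c(mean = 146.7, sd = 6.5 * sqrt(42)),
             stratum_mix = 0.5)
)

#' Draw a per-cell tree spec for a melanopsin subtype
#'
#' Samples per-cell morphometric parameters (branch-point target, dendritic
#' field area, soma size) around the subtype's population means and returns a
#' [tree_spec()] realising them. The number of primaries is the mean
#' tip-minus-branch difference for the subtype (strict bifurcation makes
#' tips = branches + primaries).
#'
#' @param subtype one of M1, M1d, M2, M3
#' @param seed integer seed for the per-cell draw; `NULL` uses the current
#'   stream
#' @param decline multiplicative factors applied to the sampled means, a named
#'   vector with any of `dendritic_area`, `branch_points`, `terminal_tips`,
#'   `sholl_area` (used by the aging scenario; 1 = no decline)
#' @return a [tree_spec()]
#' @export
sample_tree_spec <- function(subtype, seed = NULL, decline = NULL) {
  if (!subtype %in% MRGC_SUBTYPES)
    stop_retmosaic("validation", sprintf("unknown subtype label: %s", subtype))
  ps <- SUBTYPE_PRESETS[[subtype]]
  if (!is.null(seed)) set.seed(seed)
  dfac <- function(nm) if (!is.null(decline) && nm %in% names(decline)) decline[[nm]] else 1
  # primaries from the mean tips - branches gap, at least 1
  n_primary <- max(1L, as.integer(round(
    ps$terminal_tips[["mean"]] - ps$branch_points[["mean"]])))
  bp <- max(0L, as.integer(round(stats::rnorm(
    1, ps$branch_points[["mean"]] * dfac("branch_points"),
    ps$branch_points[["sd"]]))))
  area_mm2 <- max(0.05, stats::rnorm(
    1, ps$dendritic_area[["mean"]] * dfac("dendritic_area"),
    ps$dendritic_area[["sd"]]))
  soma_d <- max(5, stats::rnorm(1, ps$soma_diameter[["mean"]],
                                ps$soma_diameter[["sd"]]))
  tree_spec(
    n_primary = n_primary,
    target_branch_points = bp,
    field_radius = sqrt(area_mm2 * 1e6 / pi),
    stratum_mix = ps$stratum_mix,
    soma_area = pi * (soma_d / 2)^2,
    seed = NULL
  )
}
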
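# The traced neurite arbor container: a rooted tree of soma + neurite nodes.
#
# Coordinates are micrometres at the cell scale (camera-lucida tracings are
# planar; z only encodes the IPL stratum plane). Dendritic metrics are always
# computed on the 2D retinal-plane projection.

NODE_COMPARTMENTS <- c("soma", "dendrite", "axon")
IPL_STRATA <- c("S1", "S5")

# Fixed z planes (um) encoding the stratum of a dendritic node in SWC output.
STRATUM_Z <- c(S1 = 15, S5 = 2)

#' Create a neurite tree
#'
#' @param nodes data frame with columns `id` (unique integer), `parent`
#'   (`NA` for the single root), `x`, `y`, `z` (um), `radius` (um),
#'   `compartment` (`soma`/`dendrite`/`axon`) and `stratum` (`S1`/`S5` for
#'   dendritic nodes, else `NA`)
#' @param soma_area measured soma cross-sectional area (um^2)
#' @param cell_id identifier for the cell
#' @param subtype optional subtype label (M1/M1d/M2/M3)
#' @return an object of class `neurite_tree`
#' @export
neurite_tree <- function(nodes, soma_area, cell_id = NA_character_,
                         subtype = NA_character_) {
  required <- c("id", "parent", "x", "y", "z", "radius", "compartment", "stratum")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols))
    stop_retmosaic("validation", sprintf("nodes lack column(s): %s",
                                         toString(missing_cols)))
  if (anyDuplicated(nodes$id))
    stop_retmosaic("parse", sprintf(
      "duplicate node id(s): %s",
      toString(utils::head(nodes$id[duplicated(nodes$id)], 5))))
  roots <- which(is.na(nodes$parent))
  if (length(roots) != 1)
    stop_retmosaic("validation", sprintf("tree must have exactly one root, found %d",
                                         length(roots)))
  if (any(nodes$parent[!is.na(nodes$parent)] == nodes$id[!is.na(nodes$parent)]))
    stop_retmosaic("parse", sprintf(
      "node %s is its own parent (cycle)",
      nodes$id[which(!is.na(nodes$parent) & nodes$parent == nodes$id)[1]]))
  missing_parent <- !is.na(nodes$parent) & !nodes$parent %in% nodes$id
  if (any(missing_parent))
    stop_retmosaic("parse", sprintf(
      "node %s refers to a missing parent %s",
      nodes$id[which(missing_parent)[1]], nodes$parent[which(missing_parent)[1]]))
  if (any(!nodes$compartment %in% NODE_COMPARTMENTS))
    stop_retmosaic("validation", "compartment must be soma, dendrite or axon")
  bad_str <- !is.na(nodes$stratum) & !nodes$stratum %in% IPL_STRATA
  if (any(bad_str))
    stop_retmosaic("validation", sprintf("unknown stratum label(s): %s",
                                         toString(unique(nodes$stratum[bad_str]))))
  if (!is.numeric(soma_area) || length(soma_area) != 1 || is.na(soma_area) ||
      soma_area <= 0)
    stop_retmosaic("validation", "soma_area must be a positive number")
  assert_acyclic(nodes)
  structure(list(nodes = nodes, soma_area = as.double(soma_area),
                 cell_id = cell_id, subtype = subtype),
            class = "neurite_tree")
}

# Walk parent links from every node; a cycle would fail to reach the root
# within n steps.
assert_acyclic <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)
  n <- nrow(nodes)
  # depth by repeated parent hops, vectorised over nodes
  depth <- rep(0L, n); cur <- idx
  for (step in seq_len(n)) {
    live <- !is.na(cur)
    if (!any(live)) return(invisible(TRUE))
    depth[live] <- depth[live] + 1L
    cur[live] <- idx[cur[live]]
  }
  stop_retmosaic("parse", "parent links contain a cycle")
}

#' @export
print.neurite_tree <- function(x, ...) {
  nd <- sum(x$nodes$compartment == "dendrite")
  cat(sprintf("neurite_tree %s (%s): %d nodes (%d dendritic), soma area %.3g um^2\n",
              x$cell_id, x$subtype %||% NA, nrow(x$nodes), nd, x$soma_area))
  invisible(x)
}

# Index helpers -------------------------------------------------------------

dendrite_idx <- function(tree) which(tree$nodes$compartment == "dendrite")

soma_centroid <- function(tree) {
  s <- tree$nodes$compartment == "soma"
  c(x = mean(tree$nodes$x[s]), y = mean(tree$nodes$y[s]))
}

# For each node: number of dendritic children.
dendritic_child_counts <- function(tree) {
  nodes <- tree$nodes
  dend <- nodes$compartment == "dendrite"
  parents <- nodes$parent[dend]
  counts <- table(factor(parents, levels = nodes$id))
  as.integer(counts)
}
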
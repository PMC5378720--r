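# Readers and writers for the on-disk formats: cell/region CSV tables, SWC
# neurite tracings with a sidecar metadata table, study tables, and a
# plain-text provenance log.
#
# Conventions: comma-separated, "." decimal, UTF-8, mandatory header row.
# Mosaic coordinates are mm (whole-mount scale); SWC coordinates are um
# (cell scale). Conversions are always explicit.

SWC_TYPE_CODES <- c(soma = 1L, axon = 2L, dendrite = 3L)

#' Write a cell mosaic to CSV
#'
#' @param mosaic a [cell_mosaic()]
#' @param cells_path output path for the cell table
#'   (`cell_id, x_mm, y_mm, subtype, layer, donor_id, age_years`)
#' @param region_path output path for the region vertex table
#'   (`vertex_id, x_mm, y_mm`)
#' @return invisibly, the paths
#' @export
write_mosaic <- function(mosaic, cells_path, region_path) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  cells <- data.frame(
    cell_id = mosaic$cells$cell_id,
    x_mm = mosaic$cells$x, y_mm = mosaic$cells$y,
    subtype = mosaic$cells$subtype, layer = mosaic$cells$layer,
    donor_id = mosaic$cells$donor_id, age_years = mosaic$cells$age_years,
    stringsAsFactors = FALSE)
  utils::write.csv(cells, cells_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  reg <- data.frame(vertex_id = seq_along(mosaic$region$x),
                    x_mm = mosaic$region$x, y_mm = mosaic$region$y)
  utils::write.csv(reg, region_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(cells = cells_path, region = region_path))
}

#' Read a cell mosaic from CSV
#'
#' Validates the schema, subtype/layer vocabularies, duplicate coordinates
#' and region membership; offending row numbers are named in errors.
#'
#' @param cells_path cell table path (see [write_mosaic()] for the schema)
#' @param region_path region vertex table path
#' @param strict if `TRUE` (default), a point outside the region is an error;
#'   if `FALSE`, such points are dropped with a warning counting them
#' @return a [cell_mosaic()]
#' @export
read_mosaic <- function(cells_path, region_path, strict = TRUE) {
  for (p in c(cells_path, region_path)) {
    if (!file.exists(p))
      stop_retmosaic("load", sprintf("file not found: %s", p))
  }
  reg_df <- utils::read.csv(region_path, stringsAsFactors = FALSE)
  need_reg <- c("vertex_id", "x_mm", "y_mm")
  if (!all(need_reg %in% names(reg_df)))
    stop_retmosaic("load", sprintf("region table lacks column(s): %s",
                                   toString(setdiff(need_reg, names(reg_df)))))
  region <- region_polygon(reg_df$x_mm[order(reg_df$vertex_id)],
                           reg_df$y_mm[order(reg_df$vertex_id)])
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_mm", "y_mm", "subtype", "layer", "donor_id", "age_years")
  if (!all(need %in% names(cells)))
    stop_retmosaic("load", sprintf("cell table lacks column(s): %s",
                                   toString(setdiff(need, names(cells)))))
  for (col in c("x_mm", "y_mm")) {
    if (!is.numeric(cells[[col]]))
      stop_retmosaic("load", sprintf(
        "unparseable numbers in column %s (first bad row: %d)", col,
        which(is.na(suppressWarnings(as.numeric(cells[[col]]))))[1]))
  }
  inside <- in_region(region, cells$x_mm, cells$y_mm)
  if (!all(inside)) {
    if (strict)
      stop_retmosaic("load", sprintf(
        "point(s) outside the region at row(s): %s",
        toString(utils::head(which(!inside), 10))))
    warning(sprintf("dropped %d point(s) outside the region (rows %s)",
                    sum(!inside), toString(utils::head(which(!inside), 10))))
    cells <- cells[inside, , drop = FALSE]
  }
  subtype <- if (all(is.na(cells$subtype))) NULL else cells$subtype
  layer <- if (all(is.na(cells$layer))) NULL else cells$layer
  cell_mosaic(cells$x_mm, cells$y_mm, region, subtype = subtype, layer = layer,
              donor_id = cells$donor_id, age_years = cells$age_years,
              cell_id = cells$cell_id)
}

#' Write a neurite tree to SWC
#'
#' Standard 7-column SWC (`id type x y z radius parent`), type codes
#' 1 = soma, 2 = axon, 3 = dendrite. The dendritic stratum is encoded by the
#' fixed z planes (`S1` at z = 15 um, `S5` at z = 2 um); soma area and labels
#' travel in the sidecar metadata table written by [write_tree_metadata()].
#'
#' @param tree a [neurite_tree()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neurite_tree"))
  nd <- tree$nodes
  lines <- c(
    sprintf("# SWC export of cell %s", tree$cell_id),
    "# id type x y z radius parent",
    sprintf("%d %d %.6g %.6g %.6g %.6g %d",
            nd$id, SWC_TYPE_CODES[nd$compartment], nd$x, nd$y, nd$z,
            nd$radius, ifelse(is.na(nd$parent), -1L, nd$parent)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a neurite tree from SWC
#'
#' Accepts `#` comments; validates ids, parent links and cycles. The stratum
#' of each dendritic node is recovered from its z plane (nearest of the two
#' fixed stratum planes).
#'
#' @param path SWC file path
#' @param soma_area soma cross-sectional area in um^2 (from the sidecar
#'   metadata; SWC itself has no area field). Defaults to the area of the
#'   soma node's radius disc.
#' @param cell_id,subtype labels for the resulting tree
#' @return a [neurite_tree()]
#' @export
read_swc <- function(path, soma_area = NULL, cell_id = NULL,
                     subtype = NA_character_) {
  if (!file.exists(path))
    stop_retmosaic("load", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop_retmosaic("parse", sprintf("no data rows in %s", path))
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(fields, length, 0L) != 7)
  if (length(bad))
    stop_retmosaic("parse", sprintf("malformed SWC row %d (need 7 columns)", bad[1]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop_retmosaic("parse", "unparseable numeric field in SWC file")
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  parent <- as.integer(m[, 7])
  if (anyDuplicated(id))
    stop_retmosaic("parse", sprintf("duplicate node id %d", id[duplicated(id)][1]))
  self_ref <- which(parent == id)
  if (length(self_ref))
    stop_retmosaic("parse", sprintf("node %d is its own parent (cycle)", id[self_ref[1]]))
  comp <- names(SWC_TYPE_CODES)[match(type, SWC_TYPE_CODES)]
  if (anyNA(comp))
    stop_retmosaic("parse", sprintf("unknown SWC type code %d",
                                    type[is.na(comp)][1]))
  stratum <- rep(NA_character_, length(id))
  dend <- comp == "dendrite"
  if (any(dend))
    stratum[dend] <- names(STRATUM_Z)[apply(
      abs(outer(m[dend, 5], STRATUM_Z, "-")), 1, which.min)]
  soma_idx <- which(comp == "soma")
  if (is.null(soma_area)) {
    if (!length(soma_idx))
      stop_retmosaic("parse", "SWC file has no soma node and no soma_area was given")
    soma_area <- pi * m[soma_idx[1], 6]^2
  }
  nodes <- data.frame(id = id, parent = ifelse(parent < 0, NA_integer_, parent),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      compartment = comp, stratum = stratum,
                      stringsAsFactors = FALSE)
  neurite_tree(nodes, soma_area = soma_area,
               cell_id = cell_id %||% sub("\\.swc$", "", basename(path)),
               subtype = subtype)
}

#' Write the sidecar metadata table for a set of trees
#'
#' @param trees list of [neurite_tree()]
#' @param path output CSV path
#'   (`cell_id, subtype, soma_area_um2, donor_id, age_years`)
#' @param donor_id,age_years optional per-tree or scalar metadata
#' @return invisibly, the path
#' @export
write_tree_metadata <- function(trees, path, donor_id = NA_character_,
                                age_years = NA_real_) {
  df <- data.frame(
    cell_id = vapply(trees, function(t) as.character(t$cell_id), ""),
    subtype = vapply(trees, function(t) as.character(t$subtype), ""),
    soma_area_um2 = vapply(trees, function(t) t$soma_area, 0),
    donor_id = rep_len(donor_id, length(trees)),
    age_years = rep_len(age_years, length(trees)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a directory of SWC files with their sidecar metadata
#'
#' @param swc_dir directory containing `<cell_id>.swc` files
#' @param meta_path sidecar CSV (see [write_tree_metadata()])
#' @return list of [neurite_tree()]
#' @export
read_tree_collection <- function(swc_dir, meta_path) {
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "subtype", "soma_area_um2")
  if (!all(need %in% names(meta)))
    stop_retmosaic("load", sprintf("metadata lacks column(s): %s",
                                   toString(setdiff(need, names(meta)))))
  lapply(seq_len(nrow(meta)), function(i) {
    p <- file.path(swc_dir, paste0(meta$cell_id[i], ".swc"))
    read_swc(p, soma_area = meta$soma_area_um2[i],
             cell_id = meta$cell_id[i], subtype = meta$subtype[i])
  })
}

#' Write / read an aging study table
#'
#' @param table study table data frame
#' @param path CSV path
#' @return invisibly the path (write) or the validated table (read)
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("donor_id", "age_years", "age_group", "subtype", "metric",
            "value", "n_cells")
  if (!all(need %in% names(df)))
    stop_retmosaic("load", sprintf("study table lacks column(s): %s",
                                   toString(setdiff(need, names(df)))))
  bad_grp <- df$age_group != as.character(assign_age_group(df$age_years))
  if (any(bad_grp))
    stop_retmosaic("load", sprintf(
      "age_group inconsistent with age_years at row(s): %s",
      toString(utils::head(which(bad_grp), 10))))
  bad_metric <- !df$metric %in% STUDY_METRICS
  if (any(bad_metric))
    stop_retmosaic("load", sprintf("unknown metric(s): %s",
                                   toString(unique(df$metric[bad_metric]))))
  df
}

#' Write a plain-text provenance log
#'
#' Records the package version, timestamp, seed and every configuration
#' entry as `key = value` lines, so a run can be reproduced from its log.
#'
#' @param path output path
#' @param config named list of configuration entries (seeds, specs, options)
#' @return invisibly, the path
#' @export
write_provenance <- function(path, config = list()) {
  flat <- unlist(config)
  lines <- c(
    sprintf("package = retmosaic %s",
            as.character(utils::packageVersion("retmosaic"))),
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("r_version = %s", R.version.string),
    if (length(flat)) sprintf("%s = %s", names(flat), as.character(flat)))
  writeLines(lines, path)
  invisible(path)
}
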
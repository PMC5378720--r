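# The labelled cell mosaic container.

MRGC_SUBTYPES <- c("M1", "M1d", "M2", "M3")
RETINAL_LAYERS <- c("GCL", "INL")

# Soma layer implied by subtype: displaced M1 cells sit in the inner nuclear
# layer, all other melanopsin subtypes in the ganglion cell layer.
default_layer_for_subtype <- function(subtype) {
  ifelse(subtype == "M1d", "INL", "GCL")
}

#' Create a labelled cell mosaic
#'
#' A cell mosaic is a planar point pattern (cell soma positions, mm) inside a
#' polygonal analysis region, with optional subtype (M1/M1d/M2/M3) and layer
#' (GCL/INL) labels and donor metadata.
#'
#' @param x,y soma coordinates (mm)
#' @param region a [region_polygon()]
#' @param subtype per-cell subtype label, one of `r toString(MRGC_SUBTYPES)`,
#'   or `NULL`
#' @param layer per-cell soma layer, one of GCL/INL; defaults to the layer
#'   implied by the subtype when subtypes are given
#' @param donor_id,age_years optional donor metadata (scalars or per-cell)
#' @param cell_id per-cell identifier; defaults to `1:n`
#' @return an object of class `cell_mosaic`: a list with a `cells` data frame
#'   (`cell_id, x, y, subtype, layer, donor_id, age_years`) and the `region`
#' @export
#' @examples
#' w <- unit_square_region()
#' m <- cell_mosaic(c(.2, .8, .5), c(.2, .2, .8), w, subtype = c("M1", "M1", "M2"))
#' n_cells(m)
cell_mosaic <- function(x, y, region, subtype = NULL, layer = NULL,
                        donor_id = NA_character_, age_years = NA_real_,
                        cell_id = NULL) {
  stopifnot(inherits(region, "region_polygon"))
  n <- length(x)
  if (length(y) != n)
    stop_retmosaic("validation", "x and y must have equal length")
  if (n > 0 && !all(in_region(region, x, y)))
    stop_retmosaic("validation", sprintf(
      "point(s) outside the analysis region at row(s): %s",
      toString(utils::head(which(!in_region(region, x, y)), 10))))
  if (n > 1 && anyDuplicated(cbind(x, y)))
    stop_retmosaic("validation", sprintf(
      "duplicate coordinates at row(s): %s (digitised tracings can contain repeats; deduplicate before loading)",
      toString(utils::head(which(duplicated(cbind(x, y))), 10))))
  if (!is.null(subtype)) {
    subtype <- as.character(subtype)
    bad <- !subtype %in% MRGC_SUBTYPES
    if (any(bad))
      stop_retmosaic("validation", sprintf(
        "unknown subtype label(s): %s (allowed: %s)",
        toString(unique(subtype[bad])), toString(MRGC_SUBTYPES)))
    if (is.null(layer)) layer <- default_layer_for_subtype(subtype)
  }
  if (!is.null(layer)) {
    layer <- as.character(layer)
    bad <- !layer %in% RETINAL_LAYERS
    if (any(bad))
      stop_retmosaic("validation", sprintf(
        "unknown layer label(s): %s (allowed: %s)",
        toString(unique(layer[bad])), toString(RETINAL_LAYERS)))
  }
  cells <- data.frame(
    cell_id = cell_id %||% seq_len(n),
    x = as.double(x), y = as.double(y),
    subtype = if (is.null(subtype)) rep(NA_character_, n) else subtype,
    layer = if (is.null(layer)) rep(NA_character_, n) else layer,
    donor_id = rep_len(as.character(donor_id), n),
    age_years = rep_len(as.double(age_years), n),
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, region = region), class = "cell_mosaic")
}

#' Number of cells in a mosaic
#' @param mosaic a `cell_mosaic`
#' @export
n_cells <- function(mosaic) nrow(mosaic$cells)

#' Overall cell density of a mosaic
#' @param mosaic a `cell_mosaic`
#' @return cells per mm^2
#' @export
mosaic_density <- function(mosaic) n_cells(mosaic) / region_area(mosaic$region)

#' Restrict a mosaic to one subtype
#' @param mosaic a `cell_mosaic`
#' @param subtype subtype label to keep
#' @return a `cell_mosaic` over the same region
#' @export
subset_subtype <- function(mosaic, subtype) {
  if (!subtype %in% MRGC_SUBTYPES)
    stop_retmosaic("validation", sprintf("unknown subtype label: %s", subtype))
  keep <- !is.na(mosaic$cells$subtype) & mosaic$cells$subtype == subtype
  cells <- mosaic$cells[keep, , drop = FALSE]
  structure(list(cells = cells, region = mosaic$region), class = "cell_mosaic")
}

#' @export
print.cell_mosaic <- function(x, ...) {
  tab <- table(x$cells$subtype, useNA = "no")
  cat(sprintf("cell_mosaic: %d cells in %.4g mm^2 (%.3g cells/mm^2)\n",
              n_cells(x), region_area(x$region), mosaic_density(x)))
  if (length(tab)) cat("  subtypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
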
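# Multi-donor aging study generator.
#
# Emulates the cross-sectional human study design: 24 donors spanning 10-81
# years (six per age bin), one sampling window of ~1 cm^2 per donor, four
# melanopsin subtypes per window, and a handful of traced cells per subtype
# per donor. Ground truth (the age curves actually applied) is stored
# alongside so parameter-recovery tests can close the loop.

# Default donor ages: six per age bin, spanning the study's 10-81 range.
DEFAULT_DONOR_AGES <- c(10, 14, 18, 22, 26, 29,
                        31, 35, 39, 43, 46, 48,
                        52, 56, 60, 63, 65, 68,
                        71, 73, 75, 77, 79, 81)

# Baseline subtype densities (cells/mm^2) in the superior-nasal window and
# the mosaic model per subtype: M1d and M3 form regular mosaics, M1 and M2
# are close to random. dmin parameters are expressed relative to the CSR
# mean spacing at the subtype's density and were calibrated once against the
# printed per-type regularity indices (see the methods vignette).
DEFAULT_BASELINE_DENSITY <- c(M1 = 0.51, M1d = 2.05, M2 = 0.65, M3 = 0.97)
DEFAULT_MOSAIC_MODEL <- c(M1 = "poisson", M1d = "dmin", M2 = "poisson", M3 = "dmin")
DEFAULT_DMIN_SPACING_FRACTION <- c(M1 = 0, M1d = 0.27, M2 = 0, M3 = 0.22)

#' Specify an aging scenario
#'
#' Age effects are step declines: a metric keeps its baseline below the onset
#' age and is multiplied by `1 - fraction` from the onset on. Density declines
#' after `density_onset` (default 70, by 44%); dendritic morphology declines
#' after `morpho_onset` (default 50, by 25%) with a further drop to
#' `morpho_late_decline` after 70. Set fractions to 0 for a null scenario.
#'
#' @param ages donor ages in years (default: 24 donors, six per age bin)
#' @param region sampling window per donor (default 10 x 10 mm, ~1 cm^2)
#' @param baseline_density named cells/mm^2 per subtype before any decline
#' @param density_onset,density_decline onset age and fractional drop of
#'   density
#' @param morpho_onset,morpho_decline,morpho_late_decline onset age and
#'   fractional drops (after onset, and additionally after 70) applied to
#'   dendritic area, branch points, terminal tips and Sholl area
#' @param donor_cv coefficient of variation of the lognormal donor-level
#'   density multiplier (biological between-donor variability)
#' @param mosaic_model named per-subtype model (`"poisson"` or `"dmin"`)
#' @param dmin_spacing_fraction named per-subtype soft-exclusion radius as a
#'   fraction of the CSR mean spacing `1 / (2 sqrt(density))`
#' @param trees_per_subtype traced cells per subtype per donor
#' @param seed root seed; per-donor and per-cell substreams are derived by
#'   counter so adding a donor does not perturb the others
#' @return an `aging_scenario`
#' @export
aging_scenario <- function(ages = DEFAULT_DONOR_AGES,
                           region = rect_region(10, 10),
                           baseline_density = DEFAULT_BASELINE_DENSITY,
                           density_onset = 70, density_decline = 0.44,
                           morpho_onset = 50, morpho_decline = 0.25,
                           morpho_late_decline = 0.5,
                           donor_cv = 0.2,
                           mosaic_model = DEFAULT_MOSAIC_MODEL,
                           dmin_spacing_fraction = DEFAULT_DMIN_SPACING_FRACTION,
                           trees_per_subtype = 5,
                           seed = 1) {
  if (any(ages < 0 | ages > 120))
    stop_retmosaic("invalid_spec", "ages must lie within [0, 120]")
  fr <- c(density_decline, morpho_decline, morpho_late_decline)
  if (any(fr < 0 | fr > 1))
    stop_retmosaic("invalid_spec", "decline fractions must lie within [0, 1]")
  if (!all(MRGC_SUBTYPES %in% names(baseline_density)))
    stop_retmosaic("invalid_spec", "baseline_density must name all four subtypes")
  structure(list(ages = ages, region = region,
                 baseline_density = baseline_density,
                 density_onset = density_onset,
                 density_decline = density_decline,
                 morpho_onset = morpho_onset,
                 morpho_decline = morpho_decline,
                 morpho_late_decline = morpho_late_decline,
                 donor_cv = donor_cv,
                 mosaic_model = mosaic_model,
                 dmin_spacing_fraction = dmin_spacing_fraction,
                 trees_per_subtype = trees_per_subtype,
                 seed = seed),
            class = "aging_scenario")
}

# Age factors applied to metric means.
density_age_factor <- function(scenario, age) {
  ifelse(age >= scenario$density_onset, 1 - scenario$density_decline, 1)
}

morpho_age_factor <- function(scenario, age) {
  ifelse(age >= 70, 1 - scenario$morpho_late_decline,
         ifelse(age >= scenario$morpho_onset, 1 - scenario$morpho_decline, 1))
}

#' Generate a full multi-donor aging dataset
#'
#' For every donor and subtype, a mosaic is generated at the scenario's
#' age-dependent density (with a lognormal donor-level multiplier) under the
#' subtype's mosaic model, and `trees_per_subtype` dendritic trees are drawn
#' with morphometric parameters following the decline curves. Per-donor,
#' per-subtype metrics are aggregated into a study table ready for the group
#' analysis.
#'
#' @param scenario an [aging_scenario()]
#' @param include_trees generate dendritic trees and morphometric metrics
#' @param include_spatial compute per-mosaic regularity statistics (NNRI, DI)
#'   for mosaics with at least 10 cells
#' @return a list of class `aging_dataset`: `study_table` (data frame
#'   `donor_id, age_years, age_group, subtype, metric, value, n_cells`),
#'   `mosaics` (named list donor.subtype), `trees` (named list), and
#'   `ground_truth` (the expected metric values per donor and subtype)
#' @export
generate_aging_dataset <- function(scenario, include_trees = TRUE,
                                   include_spatial = FALSE) {
  stopifnot(inherits(scenario, "aging_scenario"))
  area <- region_area(scenario$region)
  rows <- list(); mosaics <- list(); trees <- list(); truth <- list()
  for (d in seq_along(scenario$ages)) {
    age <- scenario$ages[d]
    donor <- sprintf("donor_%02d", d)
    for (s in seq_along(MRGC_SUBTYPES)) {
      st <- MRGC_SUBTYPES[s]
      # biological variability drawn per donor x subtype (mean-1 lognormal);
      # subtype populations vary independently within a donor
      set.seed(substream_seed(scenario$seed, d, s, 999))
      donor_mult <- stats::rlnorm(1, -0.5 * log(1 + scenario$donor_cv^2),
                                  sqrt(log(1 + scenario$donor_cv^2)))
      dens <- scenario$baseline_density[[st]] *
        density_age_factor(scenario, age) * donor_mult
      model <- scenario$mosaic_model[[st]]
      dmin_mean <- if (model == "dmin")
        scenario$dmin_spacing_fraction[[st]] / (2 * sqrt(dens)) else 0
      spec <- mosaic_spec(scenario$region, density = dens, model = model,
                          dmin_mean = dmin_mean, dmin_sd = 0.15 * dmin_mean,
                          seed = substream_seed(scenario$seed, d, s))
      mos <- generate_mosaic(spec, subtype = st, donor_id = donor,
                             age_years = age)
      key <- paste(donor, st, sep = ".")
      mosaics[[key]] <- mos
      rows[[length(rows) + 1L]] <- data.frame(
        donor_id = donor, age_years = age,
        age_group = as.character(assign_age_group(age)), subtype = st,
        metric = "density_cells_per_mm2", value = n_cells(mos) / area,
        n_cells = n_cells(mos), stringsAsFactors = FALSE)
      if (include_spatial && n_cells(mos) >= 10) {
        nnd <- nearest_neighbor_distances(mos)
        rows[[length(rows) + 1L]] <- data.frame(
          donor_id = donor, age_years = age,
          age_group = as.character(assign_age_group(age)), subtype = st,
          metric = c("nnri", "di"),
          value = c(regularity_index(nnd), dispersion_index(mos)),
          n_cells = n_cells(mos), stringsAsFactors = FALSE)
      }
      if (include_trees) {
        mf <- morpho_age_factor(scenario, age)
        decline <- c(dendritic_area = mf, branch_points = mf,
                     terminal_tips = mf, sholl_area = mf)
        donor_trees <- lapply(seq_len(scenario$trees_per_subtype), function(k) {
          ts <- sample_tree_spec(st, seed = substream_seed(scenario$seed, d, s, k),
                                 decline = decline)
          generate_tree(ts, cell_id = sprintf("%s.%s.c%02d", donor, st, k),
                        subtype = st)
        })
        trees[[key]] <- donor_trees
        mb <- morphometry_batch(donor_trees)
        for (metric in c("soma_equiv_diameter", "dendritic_area",
                         "branch_points", "terminal_tips", "sholl_area")) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor_id = donor, age_years = age,
            age_group = as.character(assign_age_group(age)), subtype = st,
            metric = metric, value = mean(mb[[metric]], na.rm = TRUE),
            n_cells = nrow(mb), stringsAsFactors = FALSE)
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        donor_id = donor, age_years = age, subtype = st,
        expected_density = dens,
        density_age_factor = density_age_factor(scenario, age),
        morpho_age_factor = morpho_age_factor(scenario, age),
        donor_multiplier = donor_mult, stringsAsFactors = FALSE)
    }
  }
  structure(list(study_table = do.call(rbind, rows),
                 mosaics = mosaics,
                 trees = trees,
                 ground_truth = do.call(rbind, truth),
                 scenario = scenario),
            class = "aging_dataset")
}

#' @export
print.aging_dataset <- function(x, ...) {
  cat(sprintf("aging_dataset: %d donors (ages %g-%g), %d mosaics, %d tree sets\n",
              length(x$scenario$ages), min(x$scenario$ages), max(x$scenario$ages),
              length(x$mosaics), length(x$trees)))
  invisible(x)
}
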
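# Group-level comparative analysis: age binning, subtype composition,
# Grubbs outlier screening, two-way ANOVA (subtype x age group) with Tukey
# post hoc and compact letter displays, and percent-decline summaries.

AGE_GROUPS <- c("lt30", "30to50", "50to70", "gt70")

STUDY_METRICS <- c("density_cells_per_mm2", "soma_equiv_diameter",
                   "dendritic_area", "branch_points", "terminal_tips",
                   "sholl_area", "nnri", "vdri", "di")

#' Assign donors to age groups
#'
#' Half-open bins `[0,30) [30,50) [50,70) [70,Inf)`: a boundary age belongs to
#' the older bin (50 is in 50to70).
#'
#' @param age_years numeric ages (vectorised), within `[0, 120]`
#' @return factor with levels `lt30, 30to50, 50to70, gt70`
#' @export
#' @examples
#' assign_age_group(c(10, 50, 81))
assign_age_group <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 0 | age_years > 120))
    stop_retmosaic("validation", "ages must lie within [0, 120]")
  cut(age_years, breaks = c(0, 30, 50, 70, Inf), labels = AGE_GROUPS,
      right = FALSE, include.lowest = TRUE)
}

#' Subtype composition percentages
#'
#' Each subtype's share of the summed density, as a percentage. Reported
#' values are rounded half-up to integers; the unrounded values are retained.
#'
#' @param mean_densities named numeric vector of mean densities (cells/mm^2)
#'   per subtype, all non-negative, summing to more than zero
#' @return a list with `percent` (integer-rounded) and `percent_raw`
#'   (unrounded; sums to exactly 100)
#' @export
#' @examples
#' composition_percentages(c(M1 = 0.51, M1d = 2.05, M2 = 0.65, M3 = 0.97))$percent
composition_percentages <- function(mean_densities) {
  if (any(mean_densities < 0))
    stop_retmosaic("validation", "densities must be non-negative")
  total <- sum(mean_densities)
  if (total <= 0)
    stop_retmosaic("undefined_composition",
                   "composition undefined: total density is zero")
  raw <- 100 * mean_densities / total
  list(percent = round_half_up(raw), percent_raw = raw)
}

#' Share of density located in each retinal layer
#'
#' Aggregates subtype densities by the soma layer of each subtype (M1d in the
#' INL, all others in the GCL) and expresses each layer's share as a
#' percentage.
#'
#' @inheritParams composition_percentages
#' @param layer_map named character vector mapping subtype to layer
#' @return a list with `percent` and `percent_raw` per layer
#' @export
layer_composition <- function(mean_densities,
                              layer_map = c(M1 = "GCL", M1d = "INL",
                                            M2 = "GCL", M3 = "GCL")) {
  by_layer <- tapply(mean_densities, layer_map[names(mean_densities)], sum)
  composition_percentages(c(by_layer))
}

#' Two-sided Grubbs test for a single outlier
#'
#' G = max |x - mean| / SD, compared to the critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. At most one value is flagged per
#' invocation (iterate explicitly if screening for more).
#'
#' @param values numeric sample (n >= 3), assumed approximately normal
#' @param alpha significance level
#' @return a list: `statistic` (G), `critical`, `outlier_index` (index of the
#'   flagged value or `NA`), `outlier_value`, `n`
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  values <- as.double(values)
  n <- length(values)
  if (n < 3)
    stop_retmosaic("insufficient_data", "Grubbs test needs at least 3 values")
  s <- stats::sd(values)
  if (s == 0)
    return(list(statistic = 0, critical = NA_real_, outlier_index = NA_integer_,
                outlier_value = NA_real_, n = n))
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  idx <- if (G > crit) which.max(dev) else NA_integer_
  list(statistic = G, critical = crit, outlier_index = idx,
       outlier_value = if (is.na(idx)) NA_real_ else values[idx], n = n)
}

#' Two-way ANOVA of a study metric (subtype x age group)
#'
#' Fixed-effects two-factor ANOVA with interaction on one metric of an aging
#' study table. Sums of squares are Type II by default (appropriate for the
#' mildly unbalanced designs these studies produce), with Type I available.
#' Each significant factor gets a Tukey HSD post hoc and a compact letter
#' display (groups sharing a letter are not significantly different).
#'
#' @param table study table: data frame with columns `subtype`, `age_group`,
#'   `metric`, `value`
#' @param metric which metric to analyse (one of the study metrics)
#' @param alpha significance level for post hoc letters
#' @param ss_type `"II"` (default) or `"I"`
#' @return an object of class `anova_result`: `effects` (data frame with
#'   term, df, sum_sq, F, p), `tukey` (named list of pair tables), `letters`
#'   (named list of letter displays), `alpha`, `ss_type`
#' @export
two_way_anova <- function(table, metric, alpha = 0.05,
                          ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  if (!metric %in% table$metric)
    stop_retmosaic("validation", sprintf("metric '%s' not present in the table", metric))
  df <- table[table$metric == metric, , drop = FALSE]
  df$subtype <- factor(df$subtype, levels = intersect(MRGC_SUBTYPES, df$subtype))
  df$age_group <- factor(df$age_group, levels = intersect(AGE_GROUPS, df$age_group))
  if (nlevels(df$subtype) < 2 || nlevels(df$age_group) < 2)
    stop_retmosaic("validation", "each factor needs at least 2 levels")
  cell_n <- table(df$subtype, df$age_group)
  if (any(cell_n == 0)) {
    empty <- which(cell_n == 0, arr.ind = TRUE)
    stop_retmosaic("unbalanced_design", sprintf(
      "empty design cell(s): %s",
      paste(rownames(cell_n)[empty[, 1]], colnames(cell_n)[empty[, 2]],
            sep = ":", collapse = ", ")))
  }
  fit <- stats::aov(value ~ subtype * age_group, data = df)
  if (ss_type == "II") {
    a <- car::Anova(fit, type = "II")
    effects <- data.frame(
      term = rownames(a)[seq_len(3)],
      df = a$Df[seq_len(3)],
      sum_sq = a$`Sum Sq`[seq_len(3)],
      F = a$`F value`[seq_len(3)],
      p = a$`Pr(>F)`[seq_len(3)],
      stringsAsFactors = FALSE)
  } else {
    a <- summary(fit)[[1]]
    effects <- data.frame(
      term = trimws(rownames(a))[seq_len(3)],
      df = a$Df[seq_len(3)],
      sum_sq = a$`Sum Sq`[seq_len(3)],
      F = a$`F value`[seq_len(3)],
      p = a$`Pr(>F)`[seq_len(3)],
      stringsAsFactors = FALSE)
  }
  effects$term <- sub("subtype:age_group", "interaction", effects$term)
  tukey <- list(); letters <- list()
  for (fac in c("subtype", "age_group")) {
    p_row <- effects$p[effects$term == fac]
    if (length(p_row) == 1 && !is.na(p_row) && p_row < alpha) {
      tk <- stats::TukeyHSD(fit, which = fac)[[fac]]
      pairs <- data.frame(
        pair = rownames(tk), diff = tk[, "diff"],
        lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
        row.names = NULL, stringsAsFactors = FALSE)
      tukey[[fac]] <- pairs
      means <- tapply(df$value, df[[fac]], mean)
      letters[[fac]] <- compact_letter_display(pairs, means, alpha)
    }
  }
  structure(list(effects = effects, tukey = tukey, letters = letters,
                 alpha = alpha, ss_type = ss_type, metric = metric,
                 n = nrow(df)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("anova_result: %s (Type %s SS, n = %d)\n", x$metric, x$ss_type, x$n))
  print(x$effects, digits = 4)
  for (fac in names(x$letters)) {
    cat(sprintf("  %s letters: %s\n", fac,
                paste(names(x$letters[[fac]]), x$letters[[fac]],
                      sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Compact letter display from pairwise adjusted p-values
#'
#' Insert-and-absorb algorithm: two groups share a letter if and only if
#' their adjusted p-value is at or above `alpha`. Letters are ordered by
#' decreasing group mean.
#'
#' @param pairs data frame with columns `pair` ("A-B") and `p_adj`
#' @param means named group means (defines ordering)
#' @param alpha significance level
#' @return named character vector of letter strings, one per group
#' @export
compact_letter_display <- function(pairs, means, alpha = 0.05) {
  groups <- names(sort(means, decreasing = TRUE))
  sig <- list()
  for (i in seq_len(nrow(pairs))) {
    gg <- strsplit(pairs$pair[i], "-", fixed = TRUE)[[1]]
    if (pairs$p_adj[i] < alpha) sig[[length(sig) + 1L]] <- gg
  }
  sets <- list(groups)
  for (pr in sig) {
    new_sets <- list()
    for (s in sets) {
      if (all(pr %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, pr[1])), list(setdiff(s, pr[2])))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets wholly contained in another
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[a] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
    sets <- sets[vapply(sets, length, 0L) > 0]
  }
  # order sets by the best (highest-mean) group they contain, label a, b, ...
  best <- vapply(sets, function(s) min(match(s, groups)), 0)
  sets <- sets[order(best)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Percent decline of a metric between two age groups
#'
#' `100 * (mean_ref - mean_target) / mean_ref`, using per-row values of the
#' study table (optionally for one subtype).
#'
#' @inheritParams two_way_anova
#' @param reference_group,target_group age group labels
#' @param subtype optional subtype restriction
#' @return percent change (positive = decline in the target group)
#' @export
decline_summary <- function(table, metric, reference_group, target_group,
                            subtype = NULL) {
  df <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(subtype)) df <- df[df$subtype == subtype, , drop = FALSE]
  m_ref <- mean(df$value[df$age_group == reference_group])
  m_tgt <- mean(df$value[df$age_group == target_group])
  if (!is.finite(m_ref) || is.nan(m_ref))
    stop_retmosaic("validation", sprintf("reference group '%s' absent", reference_group))
  if (!is.finite(m_tgt) || is.nan(m_tgt))
    stop_retmosaic("validation", sprintf("target group '%s' absent", target_group))
  if (m_ref == 0)
    stop_retmosaic("validation", "undefined decline: reference mean is zero")
  100 * (m_ref - m_tgt) / m_ref
}
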
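#' Chain-length dependence of the specificity constant
#'
#' Normalizes each specificity constant of a series to its DP 2 (xylobiose)
#' value: `ratio_n = (kcat/KM)_n / (kcat/KM)_2`. A flat profile means chain
#' length barely affects catalytic efficiency; ratios above 1 mean longer
#' substrates are preferred.
#'
#' @param series A [kinetic_series()] containing DP 2.
#' @return An object of class `specificity_profile`: list with
#'   `enzyme_label` and `ratios`, a numeric vector named by DP with the DP 2
#'   entry exactly 1.
#' @export
dp_specificity_profile <- function(series) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  ks2 <- series_fit(series, 2L)$specificity
  dps <- series_dps(series)
  ratios <- vapply(dps, function(dp) series_fit(series, dp)$specificity / ks2,
                   numeric(1))
  names(ratios) <- as.character(dps)
  ratios[["2"]] <- 1
  structure(list(enzyme_label = series$enzyme_label, ratios = ratios),
            class = "specificity_profile")
}

#' Per-DP catalytic efficiency ratio between two enzymes
#'
#' `(kcat/KM)_a / (kcat/KM)_b` at every DP the two series share, in matching
#' units (both are carried internally in 1/(M s)).
#'
#' @param series_a,series_b [kinetic_series()] objects with overlapping DPs.
#' @return Numeric vector named by DP.
#' @export
efficiency_ratio <- function(series_a, series_b) {
  if (!inherits(series_a, "kinetic_series") ||
      !inherits(series_b, "kinetic_series"))
    stop_invalid_argument("both arguments must be kinetic_series")
  shared <- intersect(series_dps(series_a), series_dps(series_b))
  if (length(shared) == 0L)
    stop_missing_data("the two series share no DP")
  out <- vapply(shared, function(dp) {
    series_fit(series_a, dp)$specificity / series_fit(series_b, dp)$specificity
  }, numeric(1))
  names(out) <- as.character(shared)
  out
}

#' Range of a kinetic parameter across chain lengths
#'
#' @param series A [kinetic_series()].
#' @param which `"kcat"` (1/s) or `"km"` (M).
#' @return Named numeric vector `c(min =, max =)` in internal units.
#' @export
parameter_range <- function(series, which = c("kcat", "km")) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  which <- match.arg(which)
  vals <- vapply(series$fits, function(f) f[[which]], numeric(1))
  c(min = min(vals), max = max(vals))
}

#' Two-enzyme comparison report
#'
#' Aggregates the chain-length analytics for a pair of enzymes: per-enzyme
#' DP-specificity profiles, per-DP efficiency ratios (enzyme A over enzyme
#' B), kcat and KM ranges, the active-center affinity difference
#' (A minus B, independent of the `c_w` convention), and subsite counts at
#' the configured threshold. All constants are echoed under `provenance`
#' because the headline affinity numbers depend on them.
#'
#' @param series_a,series_b [kinetic_series()] objects.
#' @param profiles Optional list of two [build_profile()] results (A then
#'   B); built from the series when `NULL`. Both must share one
#'   [thermo_context()].
#' @param options List of options: `threshold` (kcal/mol, default 0.4) and
#'   `context` (a [thermo_context()], used when profiles are built here).
#' @return An object of class `comparison_report`.
#' @export
build_report <- function(series_a, series_b, profiles = NULL,
                         options = list()) {
  if (!inherits(series_a, "kinetic_series") ||
      !inherits(series_b, "kinetic_series"))
    stop_invalid_argument("both series must be kinetic_series")
  threshold <- options$threshold %||% 0.4
  context <- options$context %||% thermo_context()
  if (is.null(profiles)) {
    profiles <- list(build_profile(series_a, context),
                     build_profile(series_b, context))
  }
  if (length(profiles) != 2L ||
      !all(vapply(profiles, inherits, logical(1), "subsite_profile")))
    stop_invalid_argument("`profiles` must be a list of two subsite_profile")
  if (!same_context(profiles[[1L]]$context, profiles[[2L]]$context))
    stop_config_error("the two profiles were built with different thermodynamic contexts")
  context <- profiles[[1L]]$context

  labels <- c(series_a$enzyme_label, series_b$enzyme_label)
  counts <- vapply(profiles, count_subsites, integer(1),
                   threshold = threshold)
  names(counts) <- labels
  kcat_ranges <- list(parameter_range(series_a, "kcat"),
                      parameter_range(series_b, "kcat"))
  km_ranges <- list(parameter_range(series_a, "km"),
                    parameter_range(series_b, "km"))
  names(kcat_ranges) <- labels
  names(km_ranges) <- labels

  structure(
    list(
      schema_version = "1.0",
      enzyme_labels = labels,
      specificity_profiles = list(dp_specificity_profile(series_a),
                                  dp_specificity_profile(series_b)),
      efficiency_ratios = efficiency_ratio(series_a, series_b),
      kcat_ranges = kcat_ranges,
      km_ranges = km_ranges,
      active_center_difference =
        profiles[[1L]]$active_center_affinity -
        profiles[[2L]]$active_center_affinity,
      subsite_counts = counts,
      profiles = profiles,
      provenance = list(
        temperature = context$temperature,
        gas_constant = context$gas_constant,
        rt = context$rt,
        c_w = context$c_w,
        threshold = threshold
      )
    ),
    class = "comparison_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n", x$enzyme_labels[1L],
              x$enzyme_labels[2L]))
  cat(sprintf("  active-center affinity difference: %+.2f kcal/mol\n",
              x$active_center_difference))
  cat("  subsite counts:",
      paste(sprintf("%s = %d", names(x$subsite_counts), x$subsite_counts),
            collapse = ", "), "\n")
  cat("  efficiency ratios (A/B) by DP:",
      paste(sprintf("DP%s %.3g", names(x$efficiency_ratios),
                    x$efficiency_ratios), collapse = ", "), "\n")
  invisible(x)
}
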
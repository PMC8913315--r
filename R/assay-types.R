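#' Assay configuration
#'
#' Describes one endpoint hydrolysis assay: the enzyme concentration in the
#' reaction, the incubation temperature, the reaction time after which
#' released product is quantified, and the chain length (degree of
#' polymerization, DP) of the substrate. Defaults reproduce the standard
#' xylooligosaccharide assay: 30 min at 30 degrees C (303.15 K).
#'
#' All quantities are carried in SI-style internal units: molar for
#' concentrations, kelvin for temperature, seconds for time. The I/O layer
#' converts from user-facing units (nM, mM, minutes).
#'
#' @param enzyme_conc Total enzyme concentration in the reaction (M).
#' @param temperature Assay temperature (K). Default 303.15 K (30 degrees C).
#' @param reaction_time Endpoint incubation time (s). Default 1800 s (30 min).
#' @param substrate_dp Degree of polymerization of the substrate (integer,
#'   at least 2).
#' @return An object of class `assay_config`.
#' @examples
#' assay_config(enzyme_conc = 30.2e-9, substrate_dp = 2)
#' @export
assay_config <- function(enzyme_conc, temperature = 303.15,
                         reaction_time = 1800, substrate_dp = 2L) {
  if (!is_scalar_number(enzyme_conc) || enzyme_conc <= 0)
    stop_invalid_argument("`enzyme_conc` must be a positive number (M)")
  if (!is_scalar_number(temperature) || temperature <= 0)
    stop_invalid_argument("`temperature` must be a positive number (K)")
  if (!is_scalar_number(reaction_time) || reaction_time <= 0)
    stop_invalid_argument("`reaction_time` must be a positive number (s)")
  substrate_dp <- as.integer(substrate_dp)
  if (is.na(substrate_dp) || substrate_dp < 2L)
    stop_invalid_argument("`substrate_dp` must be an integer >= 2")
  structure(
    list(enzyme_conc = enzyme_conc, temperature = temperature,
         reaction_time = reaction_time, substrate_dp = substrate_dp),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf("<assay_config> [E]0 = %.4g nM, T = %.2f K, t = %g s, DP = %d\n",
              x$enzyme_conc * 1e9, x$temperature, x$reaction_time,
              x$substrate_dp))
  invisible(x)
}

#' Measurement-noise model for simulated rates
#'
#' Multiplicative noise scales each noise-free velocity by `1 + e`,
#' `e ~ Normal(0, scale)`, with `scale` a coefficient of variation; this is
#' the usual error structure of chromatographic product quantification.
#' Additive noise adds `Normal(0, scale)` on the velocity scale (M/s).
#'
#' @param kind One of `"multiplicative"`, `"additive"`, `"none"`.
#' @param scale Noise magnitude: a dimensionless CV for multiplicative noise
#'   (default 0.03, typical HPLC repeatability), or M/s for additive noise.
#' @param seed Optional integer seed; identical seed and arguments give
#'   bit-identical simulated datasets.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative", "additive", "none"),
                        scale = 0.03, seed = NULL) {
  kind <- match.arg(kind)
  if (!is_scalar_number(scale) || scale < 0)
    stop_invalid_argument("`scale` must be a non-negative number")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop_invalid_argument("`seed` must be an integer")
  }
  structure(list(kind = kind, scale = scale, seed = seed),
            class = "noise_model")
}

#' True Michaelis-Menten parameters for simulation
#'
#' Ground-truth `kcat` (1/s) and `KM` (M) used by the synthetic-data
#' generator, e.g. one row of the packaged kinetic-parameter table.
#'
#' @param kcat Turnover number (1/s), positive.
#' @param km Michaelis constant (M), positive.
#' @param label Free-text label (enzyme name).
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(kcat, km, label = "") {
  if (!is_scalar_number(kcat) || kcat <= 0)
    stop_invalid_argument("`kcat` must be a positive number (1/s)")
  if (!is_scalar_number(km) || km <= 0)
    stop_invalid_argument("`km` must be a positive number (M)")
  structure(list(kcat = kcat, km = km, label = as.character(label)),
            class = "true_parameters")
}

#' Initial-rate dataset for one enzyme/substrate pair
#'
#' Bundles the measured (or simulated) rate points of one assay series with
#' its configuration. Points live in a data frame with columns
#' `substrate_conc` (M), `velocity` (M/s) and `replicate`.
#'
#' @param enzyme_label Enzyme name.
#' @param dp Substrate degree of polymerization (integer >= 2).
#' @param config An [assay_config()], or `NULL` when the dataset was read
#'   from a bare rate table and the configuration is attached later.
#' @param points Data frame with columns `substrate_conc`, `velocity`,
#'   `replicate`.
#' @return An object of class `rate_dataset`.
#' @export
rate_dataset <- function(enzyme_label, dp, config, points) {
  dp <- as.integer(dp)
  if (is.na(dp) || dp < 2L)
    stop_invalid_argument("`dp` must be an integer >= 2")
  if (!is.null(config) && !inherits(config, "assay_config"))
    stop_invalid_argument("`config` must be an assay_config or NULL")
  points <- as.data.frame(points)
  required <- c("substrate_conc", "velocity", "replicate")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0)
    stop_invalid_argument(paste0("`points` lacks column(s): ",
                                 paste(missing_cols, collapse = ", ")))
  if (nrow(points) < 1L)
    stop_invalid_argument("`points` must contain at least one rate point")
  if (any(points$substrate_conc <= 0))
    stop_invalid_argument("substrate concentrations must be positive")
  if (any(points$velocity < 0))
    stop_invalid_argument("velocities must be non-negative")
  structure(
    list(enzyme_label = as.character(enzyme_label), dp = dp,
         config = config, points = points[, required]),
    class = "rate_dataset"
  )
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat(sprintf("<rate_dataset> %s DP%d: %d points, [S] %.3g-%.3g M\n",
              x$enzyme_label, x$dp, nrow(x$points),
              min(x$points$substrate_conc), max(x$points$substrate_conc)))
  invisible(x)
}
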
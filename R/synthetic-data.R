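#' Substrate concentration grid
#'
#' Builds the ordered series of substrate concentrations for an assay.
#' The default range used throughout the package is 50 uM to 5 mM, the span
#' over which xylooligosaccharide initial rates are typically measured; log
#' (geometric) spacing places points evenly on either side of typical KM
#' values.
#'
#' @param min_conc Lowest concentration (M), positive.
#' @param max_conc Highest concentration (M), `>= min_conc`.
#' @param n_points Number of grid points (integer >= 1).
#' @param spacing `"log"` (geometric) or `"linear"`.
#' @return Numeric vector of concentrations (M), strictly increasing, with
#'   first element `min_conc` and last `max_conc`.
#' @examples
#' make_concentration_grid(5e-5, 5e-3, 8, "log")
#' @export
make_concentration_grid <- function(min_conc = 5e-5, max_conc = 5e-3,
                                    n_points = 8L,
                                    spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!is_scalar_number(min_conc) || min_conc <= 0)
    stop_invalid_argument("`min_conc` must be positive")
  if (!is_scalar_number(max_conc) || max_conc < min_conc)
    stop_invalid_argument("`max_conc` must be >= `min_conc`")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    stop_invalid_argument("`n_points` must be an integer >= 1")
  if (n_points == 1L) {
    if (max_conc > min_conc)
      stop_invalid_argument(
        "a single-point grid requires `min_conc` == `max_conc`")
    return(min_conc)
  }
  grid <- switch(spacing,
    linear = seq(min_conc, max_conc, length.out = n_points),
    log    = exp(seq(log(min_conc), log(max_conc), length.out = n_points))
  )
  # pin endpoints exactly (exp/log round trip can drift in the last ulp)
  grid[1L] <- min_conc
  grid[n_points] <- max_conc
  grid
}

#' Simulate an initial-rate dataset
#'
#' Generates rate points from Michaelis-Menten truth: the noise-free
#' velocity at substrate concentration `s` is `kcat * [E]0 * s / (KM + s)`,
#' to which the noise model is applied per point. Negative noisy velocities
#' are clipped to zero (they cannot be observed as product release).
#'
#' @param params A [true_parameters()] object.
#' @param config An [assay_config()] (supplies `[E]0` and metadata).
#' @param grid Concentration grid (M), e.g. from [make_concentration_grid()].
#' @param replicates Number of replicate measurements per concentration.
#' @param noise A [noise_model()]. With a non-`NULL` seed the simulation is
#'   reproducible and leaves the caller's RNG state untouched.
#' @return A [rate_dataset()].
#' @examples
#' p <- true_parameters(kcat = 1.81, km = 0.90e-3, label = "PcBxl3")
#' cfg <- assay_config(enzyme_conc = 30.2e-9, substrate_dp = 2)
#' simulate_rates(p, cfg, noise = noise_model("none"))
#' @export
simulate_rates <- function(params, config,
                           grid = make_concentration_grid(),
                           replicates = 3L,
                           noise = noise_model()) {
  if (!inherits(params, "true_parameters"))
    stop_invalid_argument("`params` must be a true_parameters object")
  if (!inherits(config, "assay_config"))
    stop_invalid_argument("`config` must be an assay_config object")
  if (!inherits(noise, "noise_model"))
    stop_invalid_argument("`noise` must be a noise_model object")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop_invalid_argument("`replicates` must be an integer >= 1")

  s <- rep(grid, each = replicates)
  v_true <- mm_velocity(params$kcat, config$enzyme_conc, params$km, s)
  v <- with_seed(noise$seed, {
    switch(noise$kind,
      none           = v_true,
      multiplicative = v_true * (1 + stats::rnorm(length(v_true),
                                                  sd = noise$scale)),
      additive       = v_true + stats::rnorm(length(v_true),
                                             sd = noise$scale)
    )
  })
  v <- pmax(v, 0)
  rate_dataset(
    enzyme_label = params$label,
    dp = config$substrate_dp,
    config = config,
    points = data.frame(
      substrate_conc = s,
      velocity = v,
      replicate = rep(seq_len(replicates), times = length(grid))
    )
  )
}

#' Convert an endpoint product measurement to a rate
#'
#' The assay quantifies product released after a fixed incubation; the
#' initial rate is estimated as product concentration divided by time, valid
#' while substrate depletion stays small (see [initial_rate_fraction()]).
#'
#' @param product_conc Released product concentration (M), non-negative.
#' @param reaction_time Incubation time (s), positive.
#' @return Velocity (M/s). Vectorized over `product_conc`.
#' @export
endpoint_to_rate <- function(product_conc, reaction_time) {
  if (!is_scalar_number(reaction_time) || reaction_time <= 0)
    stop_invalid_argument("`reaction_time` must be a positive number (s)")
  if (!is.numeric(product_conc) || any(!is.finite(product_conc)) ||
      any(product_conc < 0))
    stop_invalid_argument("`product_conc` must be non-negative and finite")
  product_conc / reaction_time
}

#' Substrate depletion over the endpoint window
#'
#' Linear upper bound on the fraction of substrate consumed during the
#' incubation, `min(1, v0 * t / s0)` with `v0` the t = 0 Michaelis-Menten
#' velocity. A warning of class `xk_depletion_warning` is raised when the
#' fraction exceeds 10%, the usual validity limit for treating an endpoint
#' measurement as an initial rate.
#'
#' @param params A [true_parameters()] object.
#' @param config An [assay_config()] (supplies `[E]0` and the time window).
#' @param s0 Initial substrate concentration (M), positive.
#' @return Fraction of substrate consumed (dimensionless, in `[0, 1]`).
#' @export
initial_rate_fraction <- function(params, config, s0) {
  if (!inherits(params, "true_parameters"))
    stop_invalid_argument("`params` must be a true_parameters object")
  if (!inherits(config, "assay_config"))
    stop_invalid_argument("`config` must be an assay_config object")
  if (!is_scalar_number(s0) || s0 <= 0)
    stop_invalid_argument("`s0` must be a positive number (M)")
  v0 <- mm_velocity(params$kcat, config$enzyme_conc, params$km, s0)
  frac <- min(1, v0 * config$reaction_time / s0)
  if (frac > 0.10)
    warn_xk(sprintf(
      "estimated substrate depletion %.1f%% exceeds 10%%; endpoint rate may underestimate the initial rate",
      100 * frac), "xk_depletion_warning")
  frac
}
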
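#' Thermodynamic context for subsite calculations
#'
#' Constants converting specificity-constant ratios to binding free
#' energies. `rt` is derived as `gas_constant * temperature`. The constant
#' `c_w` (default 0.018 L/mol, the reciprocal molarity of water) enters the
#' active-center formula of Hiromi's subsite theory,
#' `(kcat/KM)_n = c_w * k_int * exp(sum A_i / RT)`; differences between
#' enzymes are independent of `c_w` (it cancels), but absolute active-center
#' sums are convention-dependent.
#'
#' @param temperature Temperature (K), default 303.15 (the 30 degree C
#'   assay temperature).
#' @param gas_constant Gas constant, default 1.9872e-3 kcal/(mol K).
#' @param c_w Water-molarity convention constant (L/mol), default 0.018.
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `gas_constant`, `rt` (kcal/mol) and `c_w`.
#' @export
thermo_context <- function(temperature = 303.15, gas_constant = 1.9872e-3,
                           c_w = 0.018) {
  if (!is_scalar_number(temperature) || temperature <= 0)
    stop_invalid_argument("`temperature` must be positive (K)")
  if (!is_scalar_number(gas_constant) || gas_constant <= 0)
    stop_invalid_argument("`gas_constant` must be positive")
  if (!is_scalar_number(c_w) || c_w <= 0)
    stop_invalid_argument("`c_w` must be positive (L/mol)")
  structure(
    list(temperature = temperature, gas_constant = gas_constant,
         rt = gas_constant * temperature, c_w = c_w),
    class = "thermo_context"
  )
}

same_context <- function(a, b) {
  isTRUE(all.equal(a$temperature, b$temperature)) &&
    isTRUE(all.equal(a$gas_constant, b$gas_constant)) &&
    isTRUE(all.equal(a$c_w, b$c_w))
}

#' Intrinsic rate constant from a kinetic series
#'
#' For an exo-acting glycosidase the intrinsic hydrolysis rate constant of
#' the productively bound complex, `k_int`, is taken as the maximum kcat
#' observed across substrate chain lengths (kcat approaches `k_int` for the
#' substrate with the least nonproductive binding).
#'
#' @param series A [kinetic_series()].
#' @return `k_int` (1/s).
#' @export
select_k_int <- function(series) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  max(vapply(series$fits, function(f) f$kcat, numeric(1)))
}

#' Binding affinity of a leaving-group subsite
#'
#' For an exo-enzyme, lengthening the substrate from DP `n` to DP `n + 1`
#' adds one sugar residue at subsite `+n`; the affinity of that subsite is
#' `A_{+n} = RT * ln[(kcat/KM)_{n+1} / (kcat/KM)_n]`. Only the ratio of the
#' two specificity constants enters, so the result does not depend on the
#' unit in which they are carried.
#'
#' @param series A [kinetic_series()] containing DPs `n` and `n + 1`.
#' @param n Subsite index / substrate DP (integer >= 2).
#' @param context A [thermo_context()].
#' @return Affinity of subsite `+n` (kcal/mol).
#' @export
plus_subsite_affinity <- function(series, n, context = thermo_context()) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop_invalid_argument("`n` must be an integer >= 2")
  ks_n <- series_fit(series, n)$specificity
  ks_n1 <- series_fit(series, n + 1L)$specificity
  if (!is_scalar_number(ks_n) || ks_n <= 0 ||
      !is_scalar_number(ks_n1) || ks_n1 <= 0)
    stop_invalid_argument("specificity constants must be positive")
  context$rt * log(ks_n1 / ks_n)
}

#' Summed affinity of the active-center subsites (-1/+1)
#'
#' Hiromi's relation for the shortest substrate (DP 2, spanning only
#' subsites -1 and +1) gives
#' `A_{-1} + A_{+1} = RT * ln[(kcat/KM)_2 / (c_w * k_int)]`, with the
#' specificity constant in 1/(M s) and `c_w` in L/mol. Separate estimation
#' of `A_{-1}` requires a productive/nonproductive binding decomposition
#' that does not hold for these enzymes, so only the sum is ever reported.
#' The sum's absolute value depends on the `c_w` convention; differences
#' between enzymes do not.
#'
#' @param series A [kinetic_series()] containing DP 2.
#' @param k_int Intrinsic rate constant (1/s); default [select_k_int()].
#' @param context A [thermo_context()].
#' @return `A_{-1} + A_{+1}` (kcal/mol).
#' @export
active_center_affinity <- function(series, k_int = select_k_int(series),
                                   context = thermo_context()) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  if (!is_scalar_number(k_int) || k_int <= 0)
    stop_invalid_argument("`k_int` must be positive (1/s)")
  ks2 <- series_fit(series, 2L)$specificity
  if (!is_scalar_number(ks2) || ks2 <= 0)
    stop_invalid_argument("(kcat/KM)_2 must be positive")
  context$rt * log(ks2 / (context$c_w * k_int))
}

#' Build a subsite-affinity profile
#'
#' Assembles the full Hiromi decomposition of a kinetic series: `k_int` by
#' the maximum-kcat rule, the summed -1/+1 (active-center) affinity, and
#' the affinity of each leaving-group subsite `+n` for which DPs `n` and
#' `n + 1` are both present (DP 2-5 yields subsites +2, +3, +4).
#'
#' @param series A [kinetic_series()] with consecutive DPs from 2.
#' @param context A [thermo_context()].
#' @return An object of class `subsite_profile` with fields `enzyme_label`,
#'   `k_int` (1/s), `active_center_affinity` (kcal/mol), `plus_affinities`
#'   (named numeric vector, names `"+2"`, `"+3"`, ...) and `context`.
#' @export
build_profile <- function(series, context = thermo_context()) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  dps <- series_dps(series)
  k_int <- select_k_int(series)
  ac <- active_center_affinity(series, k_int, context)
  plus_n <- dps[dps < max(dps)]
  plus <- vapply(plus_n, function(n) plus_subsite_affinity(series, n, context),
                 numeric(1))
  names(plus) <- sprintf("+%d", plus_n)
  structure(
    list(enzyme_label = series$enzyme_label, k_int = k_int,
         active_center_affinity = ac, plus_affinities = plus,
         context = context),
    class = "subsite_profile"
  )
}

#' @export
print.subsite_profile <- function(x, ...) {
  cat(sprintf("<subsite_profile> %s: k_int = %.3g 1/s, A(-1/+1) = %.2f kcal/mol\n",
              x$enzyme_label, x$k_int, x$active_center_affinity))
  if (length(x$plus_affinities) > 0) {
    cat("  plus subsites (kcal/mol):\n")
    for (nm in names(x$plus_affinities))
      cat(sprintf("    %s: %+.2f\n", nm, x$plus_affinities[[nm]]))
  }
  invisible(x)
}

profile_dp_range <- function(profile) {
  c(2L, 2L + length(profile$plus_affinities))
}

#' Reconstruct a specificity constant from a subsite profile
#'
#' Inverts the subsite decomposition:
#' `(kcat/KM)_n = c_w * k_int * exp[(A_{-1}+A_{+1} + sum_{i=2}^{n-1} A_{+i}) / RT]`.
#' Because the per-subsite affinities telescope, this reproduces every
#' input specificity constant of the series the profile was built from.
#'
#' @param profile A [build_profile()] result.
#' @param n Substrate DP within the profile's range.
#' @return Specificity constant (1/(M s)).
#' @export
reconstruct_specificity <- function(profile, n) {
  if (!inherits(profile, "subsite_profile"))
    stop_invalid_argument("`profile` must be a subsite_profile")
  n <- as.integer(n)
  rng <- profile_dp_range(profile)
  if (is.na(n) || n < rng[1L] || n > rng[2L])
    stop_invalid_argument(sprintf("`n` must be within DP range %d-%d",
                                  rng[1L], rng[2L]))
  plus_sum <- if (n > 2L) {
    sum(profile$plus_affinities[paste0("+", 2:(n - 1L))])
  } else 0
  ctx <- profile$context
  ctx$c_w * profile$k_int *
    exp((profile$active_center_affinity + plus_sum) / ctx$rt)
}

#' Count substrate-binding subsites
#'
#' The active-center subsites -1 and +1 are always counted (an exo-enzyme
#' must engage both to cleave). Leaving-group subsites are then counted
#' contiguously outward from +2, stopping at the first whose affinity falls
#' below the existence threshold: a subsite past a gap is not reachable by
#' a linear oligosaccharide bound through the active center.
#'
#' @param profile A [build_profile()] result.
#' @param threshold Minimum affinity (kcal/mol) for a subsite to count as
#'   present; default 0.4, below typical per-subsite binding energies
#'   (about 1 kcal/mol) but above ratio noise.
#' @return Integer number of subsites.
#' @export
count_subsites <- function(profile, threshold = 0.4) {
  if (!inherits(profile, "subsite_profile"))
    stop_invalid_argument("`profile` must be a subsite_profile")
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop_invalid_argument("`threshold` must be positive (kcal/mol)")
  extra <- 0L
  for (a in profile$plus_affinities) {
    if (a >= threshold) extra <- extra + 1L else break
  }
  2L + extra
}

#' Bootstrap uncertainty of a plus-subsite affinity
#'
#' Parametric bootstrap: (kcat, KM) pairs for DPs `n` and `n + 1` are
#' resampled from independent normal distributions centred on the stored
#' estimates with the stored standard errors (truncated at zero, since both
#' parameters are positive), the affinity `A_{+n}` is recomputed from each
#' draw, and the sample standard deviation is returned. Independence of the
#' kcat and KM errors is assumed (their covariance is not available from a
#' published table).
#'
#' @param series A [kinetic_series()] whose fits carry finite standard
#'   errors for kcat and KM at DPs `n` and `n + 1`.
#' @param n Subsite index (integer >= 2).
#' @param context A [thermo_context()].
#' @param n_boot Number of bootstrap draws (integer >= 100).
#' @param seed Integer seed; identical seeds give identical results.
#' @return Standard error of `A_{+n}` (kcal/mol).
#' @export
affinity_uncertainty <- function(series, n, context = thermo_context(),
                                 n_boot = 1000L, seed = 1L) {
  if (!inherits(series, "kinetic_series"))
    stop_invalid_argument("`series` must be a kinetic_series")
  n <- as.integer(n)
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 100L)
    stop_invalid_argument("`n_boot` must be an integer >= 100")
  lo <- series_fit(series, n)
  hi <- series_fit(series, n + 1L)
  ses <- c(lo$kcat_se, lo$km_se, hi$kcat_se, hi$km_se)
  if (any(vapply(ses, function(x) !is_scalar_number(x) || x < 0, logical(1))))
    stop_missing_data(
      "finite kcat and KM standard errors are required at both DPs")

  rpos <- function(k, mean, sd) {
    if (sd == 0) return(rep(mean, k))
    out <- stats::rnorm(k, mean, sd)
    bad <- out <= 0
    while (any(bad)) {
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- out <= 0
    }
    out
  }
  with_seed(seed, {
    a <- context$rt * (
      log(rpos(n_boot, hi$kcat, hi$kcat_se)) -
        log(rpos(n_boot, hi$km, hi$km_se)) -
        log(rpos(n_boot, lo$kcat, lo$kcat_se)) +
        log(rpos(n_boot, lo$km, lo$km_se))
    )
    stats::sd(a)
  })
}
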
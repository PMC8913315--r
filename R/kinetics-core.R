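#' Michaelis-Menten velocity law
#'
#' Evaluates `v = kcat * [E]0 * s / (KM + s)`, the rate law underlying every
#' fitted parameter in this package.
#'
#' @param kcat Turnover number (1/s), non-negative.
#' @param enzyme_conc Enzyme concentration (M), non-negative.
#' @param km Michaelis constant (M), strictly positive.
#' @param s Substrate concentration(s) (M), non-negative; vectorized.
#' @return Velocity (M/s).
#' @examples
#' mm_velocity(1.81, 30.2e-9, 0.90e-3, 5e-3)
#' @export
mm_velocity <- function(kcat, enzyme_conc, km, s) {
  if (!is_scalar_number(km) || km <= 0)
    stop_invalid_argument("`km` must be a positive number (M)")
  if (!is_scalar_number(kcat) || kcat < 0)
    stop_invalid_argument("`kcat` must be non-negative (1/s)")
  if (!is_scalar_number(enzyme_conc) || enzyme_conc < 0)
    stop_invalid_argument("`enzyme_conc` must be non-negative (M)")
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop_invalid_argument("`s` must be non-negative and finite (M)")
  kcat * enzyme_conc * s / (km + s)
}

#' Construct a Michaelis-Menten fit record
#'
#' Container for one fitted (or tabulated) parameter set. When `specificity`
#' is not supplied it is computed as `kcat / km` with a first-order
#' delta-method standard error; fits produced by [fit_mm()] always take this
#' route. An explicit `specificity` is accepted for parameter sets
#' transcribed from a published table, where the printed kcat/KM column
#' carries its own rounding and need not equal the ratio of the printed kcat
#' and KM to the last digit.
#'
#' @param kcat,kcat_se Turnover number and standard error (1/s).
#' @param km,km_se Michaelis constant and standard error (M).
#' @param specificity,specificity_se Optional specificity constant and SE
#'   (1/(M s)); computed from `kcat`/`km` when `NULL`.
#' @param rss Residual sum of squares on the velocity scale ((M/s)^2).
#' @param n_points Number of rate points behind the fit.
#' @param converged Logical optimizer status (`NA` for tabulated values).
#' @param source `"fit"` or `"table"`.
#' @return An object of class `mm_fit`.
#' @export
mm_fit <- function(kcat, kcat_se, km, km_se,
                   specificity = NULL, specificity_se = NULL,
                   rss = NA_real_, n_points = NA_integer_,
                   converged = NA, source = "fit") {
  if (!is_scalar_number(kcat) || kcat <= 0)
    stop_invalid_argument("`kcat` must be a positive number (1/s)")
  if (!is_scalar_number(km) || km <= 0)
    stop_invalid_argument("`km` must be a positive number (M)")
  if (is.null(specificity)) {
    sp <- delta_specificity(kcat, kcat_se, km, km_se)
    specificity <- sp$value
    specificity_se <- sp$se
  } else if (!is_scalar_number(specificity) || specificity <= 0) {
    stop_invalid_argument("`specificity` must be positive (1/(M s))")
  }
  structure(
    list(kcat = kcat, kcat_se = kcat_se, km = km, km_se = km_se,
         specificity = specificity, specificity_se = specificity_se,
         rss = rss, n_points = as.integer(n_points),
         converged = converged, source = source),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> kcat = %.3g +/- %.2g 1/s, KM = %.3g +/- %.2g mM, kcat/KM = %.3g mM^-1 s^-1\n",
    x$kcat, x$kcat_se, x$km * 1e3, x$km_se * 1e3, x$specificity * 1e-3))
  invisible(x)
}

delta_specificity <- function(kcat, kcat_se, km, km_se) {
  value <- kcat / km
  se <- if (is_scalar_number(kcat_se) && is_scalar_number(km_se)) {
    value * sqrt((kcat_se / kcat)^2 + (km_se / km)^2)
  } else NA_real_
  list(value = value, se = se)
}

#' Specificity constant with delta-method uncertainty
#'
#' Returns `kcat / KM` (1/(M s)) and its first-order delta-method standard
#' error, `value * sqrt((se_kcat/kcat)^2 + (se_KM/KM)^2)`, which assumes
#' independent errors on the two parameters.
#'
#' @param fit An `mm_fit` object with positive `kcat` and `km`.
#' @return List with elements `value` and `se`, both in 1/(M s).
#' @export
specificity_constant <- function(fit) {
  if (!inherits(fit, "mm_fit"))
    stop_invalid_argument("`fit` must be an mm_fit object")
  if (!is_scalar_number(fit$km) || fit$km <= 0)
    stop_invalid_argument("`km` must be positive")
  if (!is_scalar_number(fit$kcat) || fit$kcat <= 0)
    stop_invalid_argument("`kcat` must be positive")
  delta_specificity(fit$kcat, fit$kcat_se, fit$km, fit$km_se)
}

#' Round to significant figures for report tables
#'
#' Round-half-even rounding to a given number of significant figures, the
#' convention used for published kinetic-parameter tables (2-3 significant
#' figures).
#'
#' @param value Numeric vector.
#' @param sig_figs Number of significant figures (integer >= 1).
#' @return Rounded numeric vector.
#' @export
round_report <- function(value, sig_figs = 2L) {
  sig_figs <- as.integer(sig_figs)
  if (is.na(sig_figs) || sig_figs < 1L)
    stop_invalid_argument("`sig_figs` must be an integer >= 1")
  signif(value, sig_figs)
}

# Hanes-Woolf linearization S/v = S/Vmax + KM/Vmax: a linear regression of
# S/v on S gives starting values for the nonlinear fit. Returns NULL when
# degenerate (non-positive slope or intercept).
hanes_start <- function(s, v) {
  ok <- v > 0
  if (sum(ok) < 2L) return(NULL)
  coefs <- tryCatch(stats::coef(stats::lm(I(s[ok] / v[ok]) ~ s[ok])),
                    error = function(e) NULL)
  if (is.null(coefs) || any(!is.finite(coefs))) return(NULL)
  slope <- coefs[[2L]]; intercept <- coefs[[1L]]
  if (slope <= 0 || intercept <= 0) return(NULL)
  list(Vmax = 1 / slope, Km = intercept / slope)
}

#' Fit Michaelis-Menten parameters to an initial-rate dataset
#'
#' Nonlinear least squares on the direct velocity scale,
#' `v ~ Vmax * s / (Km + s)`, by Levenberg-Marquardt. Starting values come
#' from the Hanes-Woolf linearization (`S/v` vs `S`), falling back to
#' `Vmax = max(v)`, `Km = median(S)` when the linearization is degenerate;
#' explicit starts may be supplied instead. `kcat` is `Vmax / [E]0` using
#' the enzyme concentration recorded in the dataset's configuration
#' (active-site concentration is taken equal to protein concentration).
#' Standard errors are the Gauss-Newton values `s^2 (J'J)^-1` at the
#' optimum. The optional `"relative"` weighting minimizes relative residuals
#' (weights `1/v^2`), appropriate when measurement error is proportional to
#' the signal.
#'
#' @param dataset A [rate_dataset()] with an attached [assay_config()] and
#'   at least 3 distinct substrate concentrations.
#' @param weighting `"none"` (default) or `"relative"`.
#' @param init `"hanes"` (default) or `"explicit"` (then `start` required).
#' @param start Optional list with elements `kcat` (1/s) and `km` (M) used
#'   when `init = "explicit"`.
#' @return An `mm_fit`. On optimizer failure the fit is returned with
#'   `converged = FALSE` and `NaN` standard errors rather than an error.
#' @export
fit_mm <- function(dataset, weighting = c("none", "relative"),
                   init = c("hanes", "explicit"), start = NULL) {
  weighting <- match.arg(weighting)
  init <- match.arg(init)
  if (!inherits(dataset, "rate_dataset"))
    stop_invalid_argument("`dataset` must be a rate_dataset")
  if (is.null(dataset$config))
    stop_config_error(
      "dataset has no assay configuration; attach one (enzyme concentration is required to convert Vmax to kcat)")
  e0 <- dataset$config$enzyme_conc
  s <- dataset$points$substrate_conc
  v <- dataset$points$velocity
  if (length(unique(s)) < 3L)
    stop_insufficient_data(
      "at least 3 distinct substrate concentrations are required")

  if (init == "explicit") {
    if (is.null(start) || !is_scalar_number(start$kcat) ||
        !is_scalar_number(start$km))
      stop_invalid_argument(
        "`init = \"explicit\"` requires `start = list(kcat =, km =)`")
    st <- list(Vmax = start$kcat * e0, Km = start$km)
  } else {
    st <- hanes_start(s, v)
    if (is.null(st)) st <- list(Vmax = max(v), Km = stats::median(s))
  }

  vscale <- max(v)
  if (vscale <= 0)
    stop_numeric_error("all velocities are zero; nothing to fit")
  args <- list()
  if (weighting == "relative") {
    vw <- pmax(v / vscale, 1e-6)  # guard zero velocities
    args$weights <- 1 / vw^2
  }

  # Fit on a normalized velocity scale: velocities are O(1e-8) M/s and an
  # O(1) response keeps the Jacobian well conditioned. Estimates and SEs
  # are rescaled back afterwards, so fitted parameters are invariant to a
  # common rescaling of velocities and enzyme concentration.
  df <- data.frame(s = s, y = v / vscale)
  st_scaled <- list(A = st$Vmax / vscale, Km = st$Km)
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, c(list(
      y ~ A * s / (Km + s), data = df,
      start = st_scaled,
      lower = c(A = 0, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), args)),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    return(mm_fit(kcat = st$Vmax / e0, kcat_se = NaN,
                  km = st$Km, km_se = NaN,
                  rss = NaN, n_points = length(v),
                  converged = FALSE, source = "fit"))
  }

  cf <- summary(fit)$coefficients
  vmax <- cf["A", "Estimate"] * vscale
  vmax_se <- cf["A", "Std. Error"] * vscale
  km <- cf["Km", "Estimate"]; km_se <- cf["Km", "Std. Error"]
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) { vmax_se <- NaN; km_se <- NaN }
  mm_fit(
    kcat = vmax / e0, kcat_se = vmax_se / e0,
    km = km, km_se = km_se,
    rss = sum((v - stats::predict(fit) * vscale)^2),
    n_points = length(v), converged = converged, source = "fit"
  )
}

#' Kinetic series across substrate chain lengths
#'
#' One enzyme's fitted parameters over a consecutive run of substrate
#' degrees of polymerization starting at DP 2 (xylobiose) -- the input the
#' subsite-mapping stage requires, since per-subsite affinities come from
#' ratios of specificity constants at adjacent DPs.
#'
#' @param enzyme_label Enzyme name.
#' @param fits Named list of `mm_fit` objects; names are DPs and must form
#'   a consecutive integer sequence starting at 2.
#' @return An object of class `kinetic_series`.
#' @export
kinetic_series <- function(enzyme_label, fits) {
  if (length(fits) < 1L)
    stop_invalid_argument("`fits` must contain at least one mm_fit")
  if (!all(vapply(fits, inherits, logical(1), "mm_fit")))
    stop_invalid_argument("all elements of `fits` must be mm_fit objects")
  dps <- suppressWarnings(as.integer(names(fits)))
  if (any(is.na(dps)))
    stop_invalid_argument("`fits` must be named by integer DP")
  ord <- order(dps)
  dps <- dps[ord]; fits <- fits[ord]
  if (dps[1L] != 2L || !identical(dps, seq(2L, length.out = length(dps))))
    stop_invalid_argument(
      "DPs must form a consecutive integer range starting at 2")
  names(fits) <- as.character(dps)
  structure(list(enzyme_label = as.character(enzyme_label), fits = fits),
            class = "kinetic_series")
}

series_dps <- function(series) as.integer(names(series$fits))

series_fit <- function(series, dp) {
  fit <- series$fits[[as.character(as.integer(dp))]]
  if (is.null(fit))
    stop_missing_data(sprintf("series '%s' has no fit for DP %d",
                              series$enzyme_label, as.integer(dp)))
  fit
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("<kinetic_series> %s, DP %s\n", x$enzyme_label,
              paste(range(series_dps(x)), collapse = "-")))
  print(as.data.frame(x))
  invisible(x)
}

#' Tabulate a kinetic series
#'
#' @param x A `kinetic_series`.
#' @param ... Unused.
#' @return Data frame with one row per DP, in reporting units (KM in mM,
#'   kcat/KM in 1/(mM s)).
#' @export
as.data.frame.kinetic_series <- function(x, ...) {
  dps <- series_dps(x)
  data.frame(
    enzyme_label = x$enzyme_label,
    dp = dps,
    kcat_per_s = vapply(x$fits, function(f) f$kcat, numeric(1)),
    kcat_se = vapply(x$fits, function(f) f$kcat_se, numeric(1)),
    km_mM = vapply(x$fits, function(f) f$km * 1e3, numeric(1)),
    km_se = vapply(x$fits, function(f) f$km_se * 1e3, numeric(1)),
    spec_mM_s = vapply(x$fits, function(f) f$specificity * 1e-3, numeric(1)),
    spec_se = vapply(x$fits, function(f) f$specificity_se * 1e-3, numeric(1)),
    row.names = NULL
  )
}
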
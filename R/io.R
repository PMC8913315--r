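# Rate-table CSV schema: one row per measured point.
RATE_CSV_COLUMNS <- c("enzyme_label", "dp", "substrate_conc", "conc_unit",
                      "velocity", "velocity_unit", "replicate")

CONC_UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6)
VELOCITY_UNIT_FACTORS <- c("M/s" = 1, "nM/s" = 1e-9, "uM/min" = 1e-6 / 60)

#' Read a rate-table CSV
#'
#' Reads one measurement per row (columns `enzyme_label, dp, substrate_conc,
#' conc_unit, velocity, velocity_unit, replicate`), converts to internal
#' molar units (M, M/s), and groups rows into one [rate_dataset()] per
#' (enzyme, DP) pair, preserving row order within each group. Concentration
#' units must be one of `M`, `mM`, `uM`; velocity units one of `M/s`,
#' `nM/s`, `uM/min`.
#'
#' @param path CSV file path.
#' @param configs Optional named list of [assay_config()] objects keyed by
#'   enzyme label, attached to the matching datasets (fitting requires the
#'   enzyme concentration). Configs are cloned per DP.
#' @return Named list of [rate_dataset()] objects, names `"<label>_dp<dp>"`.
#' @export
read_rate_csv <- function(path, configs = NULL) {
  if (!file.exists(path))
    stop_parse_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RATE_CSV_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop_schema_error(paste0("rate CSV lacks column(s): ",
                             paste(missing_cols, collapse = ", ")))
  bad_conc <- which(!df$conc_unit %in% names(CONC_UNIT_FACTORS))
  if (length(bad_conc) > 0)
    stop_parse_error(sprintf(
      "row %d: unknown concentration unit '%s' (expected M, mM or uM)",
      bad_conc[1L], df$conc_unit[bad_conc[1L]]))
  bad_vel <- which(!df$velocity_unit %in% names(VELOCITY_UNIT_FACTORS))
  if (length(bad_vel) > 0)
    stop_parse_error(sprintf(
      "row %d: unknown velocity unit '%s' (expected M/s, nM/s or uM/min)",
      bad_vel[1L], df$velocity_unit[bad_vel[1L]]))
  bad_num <- which(!is.finite(df$substrate_conc) | !is.finite(df$velocity))
  if (length(bad_num) > 0)
    stop_parse_error(sprintf("row %d: non-finite numeric value",
                             bad_num[1L]))

  df$substrate_conc_M <- df$substrate_conc *
    unname(CONC_UNIT_FACTORS[df$conc_unit])
  df$velocity_Ms <- df$velocity *
    unname(VELOCITY_UNIT_FACTORS[df$velocity_unit])

  keys <- unique(df[, c("enzyme_label", "dp")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    label <- keys$enzyme_label[i]
    dp <- keys$dp[i]
    rows <- df[df$enzyme_label == label & df$dp == dp, ]
    cfg <- configs[[label]]
    if (!is.null(cfg)) {
      cfg <- assay_config(enzyme_conc = cfg$enzyme_conc,
                          temperature = cfg$temperature,
                          reaction_time = cfg$reaction_time,
                          substrate_dp = dp)
    }
    rate_dataset(
      enzyme_label = label, dp = dp, config = cfg,
      points = data.frame(substrate_conc = rows$substrate_conc_M,
                          velocity = rows$velocity_Ms,
                          replicate = rows$replicate)
    )
  })
  names(out) <- paste0(keys$enzyme_label, "_dp", keys$dp)
  out
}

#' Write rate datasets to CSV
#'
#' Inverse of [read_rate_csv()]: emits the standard rate-table schema.
#' Values are written in the requested units at full double precision, so a
#' write/read round trip reproduces the datasets exactly for unit factors
#' that are powers of two-free exact decimals handled by the same factor on
#' both paths.
#'
#' @param datasets List of [rate_dataset()] objects.
#' @param path Output CSV path.
#' @param conc_unit Concentration unit for the file (default `"M"`).
#' @param velocity_unit Velocity unit for the file (default `"M/s"`).
#' @return `path`, invisibly.
#' @export
write_rate_csv <- function(datasets, path, conc_unit = "M",
                           velocity_unit = "M/s") {
  if (inherits(datasets, "rate_dataset")) datasets <- list(datasets)
  if (!conc_unit %in% names(CONC_UNIT_FACTORS))
    stop_invalid_argument("unknown `conc_unit`")
  if (!velocity_unit %in% names(VELOCITY_UNIT_FACTORS))
    stop_invalid_argument("unknown `velocity_unit`")
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(
      enzyme_label = d$enzyme_label, dp = d$dp,
      substrate_conc = d$points$substrate_conc /
        unname(CONC_UNIT_FACTORS[conc_unit]),
      conc_unit = conc_unit,
      velocity = d$points$velocity /
        unname(VELOCITY_UNIT_FACTORS[velocity_unit]),
      velocity_unit = velocity_unit,
      replicate = d$points$replicate
    )
  }))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit table CSV
#'
#' One row per (enzyme, DP) with columns `enzyme_label, dp, kcat_per_s,
#' kcat_se, km_mM, km_se, spec_mM_s, spec_se` -- the layout of a published
#' kinetic-parameter table.
#'
#' @param series A [kinetic_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(series, path) {
  if (inherits(series, "kinetic_series")) series <- list(series)
  tab <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fit table CSV into kinetic series
#'
#' @param path CSV with the [write_fit_table()] schema (`km_mM` and
#'   `spec_mM_s` in mM-based units).
#' @param use_spec_column If `TRUE` (default) the tabulated kcat/KM column
#'   is stored as the specificity constant; if `FALSE` it is recomputed from
#'   kcat and KM with a delta-method SE.
#' @return Named list of [kinetic_series()], one per enzyme label.
#' @export
read_fit_table <- function(path, use_spec_column = TRUE) {
  if (!file.exists(path))
    stop_parse_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("enzyme_label", "dp", "kcat_per_s", "kcat_se", "km_mM", "km_se")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop_schema_error(paste0("fit table lacks column(s): ",
                             paste(missing_cols, collapse = ", ")))
  has_spec <- all(c("spec_mM_s", "spec_se") %in% names(df))
  labels <- unique(df$enzyme_label)
  out <- lapply(labels, function(label) {
    rows <- df[df$enzyme_label == label, ]
    rows <- rows[order(rows$dp), ]
    fits <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (use_spec_column && has_spec) {
        mm_fit(kcat = r$kcat_per_s, kcat_se = r$kcat_se,
               km = r$km_mM * 1e-3, km_se = r$km_se * 1e-3,
               specificity = r$spec_mM_s * 1e3,
               specificity_se = r$spec_se * 1e3,
               source = "table")
      } else {
        mm_fit(kcat = r$kcat_per_s, kcat_se = r$kcat_se,
               km = r$km_mM * 1e-3, km_se = r$km_se * 1e-3,
               source = "table")
      }
    })
    names(fits) <- as.character(rows$dp)
    kinetic_series(label, fits)
  })
  names(out) <- labels
  out
}

#' Packaged xylooligosaccharide kinetic parameters
#'
#' The published kinetic parameters of the two GH3 beta-xylosidases PcBxl3
#' (from *Phanerochaete chrysosporium*) and TrXyl3A (from *Trichoderma
#' reesei*) toward xylobiose through xylopentaose (DP 2-5): kcat, KM and
#' kcat/KM with standard errors. `table2_series()` loads them as
#' [kinetic_series()] objects; by default the tabulated kcat/KM column is
#' used as the specificity constant (it carries its own rounding and can
#' differ from the ratio of the tabulated kcat and KM in the last printed
#' digit).
#'
#' @param use_spec_column Passed to [read_fit_table()].
#' @return `table2_series()`: named list with elements `PcBxl3` and
#'   `TrXyl3A`. `table2_kinetics()`: the raw data frame.
#' @export
table2_series <- function(use_spec_column = TRUE) {
  read_fit_table(table2_path(), use_spec_column = use_spec_column)
}

#' @rdname table2_series
#' @export
table2_kinetics <- function() {
  utils::read.csv(table2_path(), stringsAsFactors = FALSE)
}

table2_path <- function() {
  path <- system.file("extdata", "table2_kinetics.csv", package = "xylokin")
  if (!nzchar(path))
    stop_missing_data("packaged kinetic-parameter fixture not found")
  path
}

#' Reference assay configurations for the packaged enzymes
#'
#' Final assay concentrations of 30.2 nM (PcBxl3) and 26.6 nM (TrXyl3A),
#' 30 degrees C, 30 min endpoint.
#'
#' @param dp Substrate DP recorded in the configs (default 2).
#' @return Named list of [assay_config()] objects.
#' @export
default_assay_configs <- function(dp = 2L) {
  list(
    PcBxl3 = assay_config(enzyme_conc = 30.2e-9, substrate_dp = dp),
    TrXyl3A = assay_config(enzyme_conc = 26.6e-9, substrate_dp = dp)
  )
}

#' Write a subsite-profile table CSV
#'
#' One row per subsite: the active-center sum (`subsite = "-1/+1"`) followed
#' by each leaving-group subsite, with optional bootstrap SEs.
#'
#' @param profiles A `subsite_profile` or list of them.
#' @param path Output CSV path.
#' @param ses Optional named list (by enzyme label) of numeric vectors of
#'   SEs for the plus subsites, names matching `"+2"`, `"+3"`, ...
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path, ses = NULL) {
  if (inherits(profiles, "subsite_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    se_vec <- ses[[p$enzyme_label]]
    plus_se <- if (is.null(se_vec)) rep(NA_real_,
                                        length(p$plus_affinities)) else
      unname(se_vec[names(p$plus_affinities)])
    data.frame(
      enzyme_label = p$enzyme_label,
      subsite = c("-1/+1", names(p$plus_affinities)),
      affinity_kcal_mol = c(p$active_center_affinity,
                            unname(p$plus_affinities)),
      se = c(NA_real_, plus_se)
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a comparison report to JSON
#'
#' Writes the full numeric content of a [build_report()] result (profiles,
#' ratios, ranges, constants) at full double precision so the file round
#' trips without loss.
#'
#' @param report A `comparison_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "comparison_report"))
    stop_invalid_argument("`report` must be a comparison_report")
  x <- list(
    schema_version = report$schema_version,
    enzyme_labels = report$enzyme_labels,
    specificity_profiles = lapply(report$specificity_profiles, function(p)
      list(enzyme_label = p$enzyme_label, ratios = as.list(p$ratios))),
    efficiency_ratios = as.list(report$efficiency_ratios),
    kcat_ranges = lapply(report$kcat_ranges, as.list),
    km_ranges = lapply(report$km_ranges, as.list),
    active_center_difference = report$active_center_difference,
    subsite_counts = as.list(report$subsite_counts),
    profiles = lapply(report$profiles, function(p)
      list(enzyme_label = p$enzyme_label, k_int = p$k_int,
           active_center_affinity = p$active_center_affinity,
           plus_affinities = as.list(p$plus_affinities))),
    provenance = report$provenance
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized comparison report
#'
#' @param path JSON file written by [write_report_json()].
#' @return Nested list mirroring the JSON structure.
#' @export
read_report_json <- function(path) {
  if (!file.exists(path))
    stop_parse_error(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = FALSE)
}
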
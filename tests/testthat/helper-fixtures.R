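# In-code copy of the published kinetic parameters (PcBxl3 / TrXyl3A,
# DP 2-5), used both to check the packaged fixture and to build series
# without going through the I/O layer. KM in mM, kcat/KM in 1/(mM s).
table2_values <- function() {
  data.frame(
    enzyme_label = rep(c("PcBxl3", "TrXyl3A"), each = 4),
    dp = rep(2:5, times = 2),
    kcat_per_s = c(1.81, 1.80, 2.05, 1.66, 0.34, 0.39, 0.82, 0.56),
    kcat_se = c(0.05, 0.06, 0.05, 0.15, 0.01, 0.01, 0.03, 0.01),
    km_mM = c(0.90, 1.14, 0.74, 1.21, 0.090, 0.024, 0.070, 0.066),
    km_se = c(0.06, 0.08, 0.04, 0.25, 0.010, 0.005, 0.010, 0.003),
    spec_mM_s = c(2.0, 1.6, 2.8, 1.4, 3.7, 16, 12, 8.5),
    spec_se = c(0.2, 0.2, 0.2, 0.3, 0.6, 4, 2, 0.5)
  )
}

# kinetic_series from the in-code table, specificity taken from the
# published kcat/KM column (the values the subsite anchors are quoted for).
series_from_table <- function(label, use_spec_column = TRUE) {
  rows <- table2_values()
  rows <- rows[rows$enzyme_label == label, ]
  fits <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (use_spec_column) {
      mm_fit(r$kcat_per_s, r$kcat_se, r$km_mM * 1e-3, r$km_se * 1e-3,
             specificity = r$spec_mM_s * 1e3,
             specificity_se = r$spec_se * 1e3, source = "table")
    } else {
      mm_fit(r$kcat_per_s, r$kcat_se, r$km_mM * 1e-3, r$km_se * 1e-3,
             source = "table")
    }
  })
  names(fits) <- as.character(rows$dp)
  kinetic_series(label, fits)
}

pc_series <- function(...) series_from_table("PcBxl3", ...)
tr_series <- function(...) series_from_table("TrXyl3A", ...)

# A kinetic_series with arbitrary specificity constants (1/(M s)) at DPs
# 2, 3, ..., for property tests; kcat/km chosen to match the specificity.
series_from_specificities <- function(specs, label = "synthetic",
                                      kcats = NULL) {
  if (is.null(kcats)) kcats <- rep(1, length(specs))
  fits <- lapply(seq_along(specs), function(i) {
    mm_fit(kcat = kcats[i], kcat_se = NA_real_,
           km = kcats[i] / specs[i], km_se = NA_real_, source = "table")
  })
  names(fits) <- as.character(seq_along(specs) + 1L)
  kinetic_series(label, fits)
}

default_pc_config <- function(dp = 2L) {
  assay_config(enzyme_conc = 30.2e-9, substrate_dp = dp)
}

default_tr_config <- function(dp = 2L) {
  assay_config(enzyme_conc = 26.6e-9, substrate_dp = dp)
}

two_enzyme_config <- function(...) {
  pipeline_config(enzymes = list(PcBxl3 = list(conc_nM = 30.2),
                                 TrXyl3A = list(conc_nM = 26.6)), ...)
}
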
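#' Bar chart of DP-specificity profiles
#'
#' Presentation helper: per-enzyme bars of `(kcat/KM)_n / (kcat/KM)_2`
#' against substrate DP.
#'
#' @param profiles List of `specificity_profile` objects (e.g. from a
#'   [build_report()] result's `specificity_profiles`).
#' @return A ggplot object.
#' @export
plot_dp_profile <- function(profiles) {
  require_ggplot2()
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(enzyme = p$enzyme_label,
               dp = as.integer(names(p$ratios)),
               ratio = unname(p$ratios))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(dp), y = ratio, fill = enzyme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "substrate DP",
                  y = expression((k[cat] / K[M])[n] / (k[cat] / K[M])[2]),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of subsite affinities
#'
#' Presentation helper: the active-center (-1/+1) sum and each
#' leaving-group subsite affinity, per enzyme.
#'
#' @param profiles List of `subsite_profile` objects.
#' @return A ggplot object.
#' @export
plot_subsite_profile <- function(profiles) {
  require_ggplot2()
  if (inherits(profiles, "subsite_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      enzyme = p$enzyme_label,
      subsite = factor(c("-1/+1", names(p$plus_affinities)),
                       levels = c("-1/+1", names(p$plus_affinities))),
      affinity = c(p$active_center_affinity, unname(p$plus_affinities))
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = subsite, y = affinity, fill = enzyme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "subsite", y = "affinity (kcal/mol)", fill = NULL) +
    ggplot2::theme_minimal()
}

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config_error("plotting requires the ggplot2 package")
}
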
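# Exploratory figures for transect data and screening results.

#' Vertical profiles of optical and molecular parameters
#'
#' @param data Tibble with a `depth_m` column plus the parameters to show.
#' @param vars Character vector of columns to facet.
#' @return A ggplot with depth increasing downwards.
#' @export
plot_vertical_profiles <- function(data,
                                   vars = c("doc_umol", "peak_c_star",
                                            "peak_t_star", "a254_star")) {
  vars <- intersect(vars, names(data))
  long <- data |>
    dplyr::select(dplyr::all_of(c("depth_m", vars))) |>
    tidyr::pivot_longer(-"depth_m", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth_m)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_reverse(name = "depth (m)") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::theme_minimal()
}

#' Heat map of an EEM
#'
#' @param object An [eem()].
#' @param ... Unused.
#' @return A ggplot raster of intensity over excitation/emission.
#' @exportS3Method ggplot2::autoplot
autoplot.eem <- function(object, ...) {
  ggplot2::ggplot(eem_to_tibble(object),
                  ggplot2::aes(x = .data$emission, y = .data$excitation,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "NFIU") +
    ggplot2::labs(x = "emission (nm)", y = "excitation (nm)") +
    ggplot2::theme_minimal()
}

#' Coefficient distributions of a cross-validation ensemble
#'
#' @param object A `proxy_ensemble`.
#' @param ... Unused.
#' @return A ggplot of the per-term coefficient histograms.
#' @exportS3Method ggplot2::autoplot
autoplot.proxy_ensemble <- function(object, ...) {
  long <- tibble::as_tibble(object$coefs) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("CV coefficient ensemble: %s",
                                  object$response))
}
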
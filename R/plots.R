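#' Overlay the seasonality recorded by two devices
#'
#' Draws each taxon's daily concentration curve for both devices in one
#' panel per taxon — the standard visual check of whether two samplers
#' agree on the shape and timing of a pollen season.
#'
#' @param table_a,table_b Wide daily-concentration tables.
#' @param labels Legend labels for the two devices.
#' @param taxa Taxa to show (default: all taxa present in either table).
#' @return A ggplot object, faceted by taxon with free y scales.
#' @export
plot_seasonality <- function(table_a, table_b,
                             labels = c("automatic", "Hirst-type"),
                             taxa = NULL) {
  to_long <- function(tab, device) {
    cols <- taxon_columns(tab)
    tab %>%
      dplyr::select(dplyr::all_of(c("date", cols))) %>%
      tidyr::pivot_longer(dplyr::all_of(cols), names_to = "taxon",
                          values_to = "concentration") %>%
      dplyr::mutate(device = device)
  }
  long <- dplyr::bind_rows(to_long(table_a, labels[1]),
                           to_long(table_b, labels[2]))
  if (!is.null(taxa)) {
    long <- dplyr::filter(long, .data$taxon %in% taxa)
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$concentration,
                                     colour = .data$device)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~taxon, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c("#2166ac", "#b2182b"),
                                 breaks = labels, name = NULL) +
    ggplot2::labs(x = NULL, y = "pollen concentration (grains/m³)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
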
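#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose table
#'
#' Per-station average daily doses on a log axis, coloured by metal and
#' faceted by receptor and pathway, for one endpoint.
#'
#' @param object A `dose_tbl` from [dose_table()].
#' @param endpoint Endpoint to display (default non-carcinogenic).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_tbl
#' @export
autoplot.dose_tbl <- function(object,
                              endpoint = c("noncarcinogenic", "carcinogenic"),
                              ...) {
  endpoint <- match.arg(endpoint)
  df <- dplyr::filter(object, .data$endpoint == .env$endpoint,
                      .data$add_ugkgday > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$station, y = .data$add_ugkgday,
                                   colour = .data$metal)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(receptor ~ pathway) +
    ggplot2::labs(x = "station", y = "average daily dose (µg/kg/day)",
                  colour = "metal",
                  title = paste(endpoint, "average daily doses")) +
    ggplot2::theme_minimal()
}

#' Plot a risk table
#'
#' `which = "hi"` draws per-station hazard indices by receptor and pathway
#' with the HQ = 1 concern threshold; `which = "tcr"` draws total cancer
#' risks with the 1e-6 and 1e-4 decision bands; `which = "contribution"`
#' draws each metal's percentage share of the combined hazard index.
#'
#' @param object A `metal_risk` object from [risk_table()].
#' @param which `"hi"`, `"tcr"`, or `"contribution"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metal_risk
#' @export
autoplot.metal_risk <- function(object, which = c("hi", "tcr", "contribution"),
                                ...) {
  which <- match.arg(which)
  if (which == "hi") {
    ggplot2::ggplot(object$hi,
                    ggplot2::aes(x = .data$station, y = .data$hi,
                                 fill = .data$pathway)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_hline(yintercept = risk_bands()$hq_threshold,
                          linetype = "dashed") +
      ggplot2::facet_wrap(~receptor, ncol = 1) +
      ggplot2::labs(x = "station", y = "hazard index",
                    title = "Non-carcinogenic hazard index by station") +
      ggplot2::theme_minimal()
  } else if (which == "tcr") {
    b <- risk_bands()
    ggplot2::ggplot(object$tcr,
                    ggplot2::aes(x = .data$station, y = .data$tcr,
                                 colour = .data$receptor)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = c(b$cr_negligible, b$cr_unacceptable),
                          linetype = "dashed") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "station", y = "total cancer risk",
                    title = "Total lifetime cancer risk by station") +
      ggplot2::theme_minimal()
  } else {
    contrib <- object$thq |>
      dplyr::group_by(.data$receptor, .data$metal) |>
      dplyr::summarise(total = sum(.data$thq), .groups = "drop_last") |>
      dplyr::mutate(pct = contribution_pct(.data$total)) |>
      dplyr::ungroup()
    ggplot2::ggplot(contrib, ggplot2::aes(x = .data$receptor, y = .data$pct,
                                          fill = .data$metal)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "share of combined hazard index (%)",
                    title = "Metal contributions to the hazard index") +
      ggplot2::theme_minimal()
  }
}
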
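#' Plot zone-wise mean synchronization
#'
#' Draws the 20-zone pitch grid colored by mean order-parameter value, the
#' standard way to read where on the pitch a team's angular order tightens or
#' loosens. Expects a [summarize_synchrony()] table grouped by
#' `lateral_zone` and `longitudinal_zone` (optionally faceted by any other
#' grouping column present).
#'
#' @param zone_summary A [summarize_synchrony()] output containing
#'   `lateral_zone` and `longitudinal_zone` columns.
#' @return A ggplot object.
#' @export
plot_zone_synchrony <- function(zone_summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the 'ggplot2' package is required for plotting")
  }
  stopifnot(all(c("lateral_zone", "longitudinal_zone") %in% names(zone_summary)))
  p <- ggplot2::ggplot(zone_summary,
                       ggplot2::aes(x = .data$longitudinal_zone,
                                    y = .data$lateral_zone,
                                    fill = .data$mean_r_prime)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1), name = "mean r'") +
    ggplot2::labs(x = "longitudinal zone (D → O, toward attacked goal)",
                  y = "lateral zone") +
    ggplot2::theme_minimal()
  extra <- setdiff(names(zone_summary),
                   c("lateral_zone", "longitudinal_zone",
                     "mean_r_prime", "sd_r_prime", "n_frames"))
  if (length(extra)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(extra, collapse = " + "))))
  }
  p
}
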
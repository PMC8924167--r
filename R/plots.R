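# ggplot2 displays for the main result types.

#' Plot a per-cycle MO2 series
#'
#' MO2 against trial time, rejected cycles marked by shape/colour.
#'
#' @param object An `mo2_series` from [extract_mo2()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mo2_series <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$cycle_time_h, y = .data$mo2, colour = .data$accepted)
  ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(
      data = object[object$accepted, ], colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "red"), name = "accepted"
    ) +
    ggplot2::labs(
      x = "time since exercise (h)",
      y = expression(italic(M) * O[2] ~ (mg ~ O[2] ~ h^-1 ~ kg^-1))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trait means vs experimental temperature by acclimation group
#'
#' @param group_summary Long table from [group_summaries()].
#' @param trait Trait name to display.
#' @return A ggplot.
#' @export
plot_trait_panel <- function(group_summary, trait) {
  df <- group_summary[group_summary$trait == trait, ]
  if (nrow(df) == 0) abort(paste0("No rows for trait '", trait, "'."))
  pd <- ggplot2::position_dodge(width = 0.6)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$experimental_temp, y = .data$mean,
      colour = factor(.data$acclimation_temp),
      group = factor(.data$acclimation_temp)
    )
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.4, position = pd, na.rm = TRUE
    ) +
    ggplot2::geom_line(position = pd) +
    ggplot2::geom_point(position = pd, size = 2) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(
      x = "experimental temperature (°C)", y = trait,
      colour = "acclimation (°C)"
    ) +
    ggplot2::theme_minimal()
}

#' Species divergence panel
#'
#' Percent divergence of the comparison species from the reference species
#' per trait across the pooling cells.
#'
#' @param divergence Output of [relative_divergence()].
#' @return A ggplot.
#' @export
plot_divergence <- function(divergence) {
  xvar <- if ("acclimation_temp" %in% names(divergence)) {
    "acclimation_temp"
  } else {
    names(divergence)[1]
  }
  ggplot2::ggplot(
    divergence,
    ggplot2::aes(
      x = .data[[xvar]], y = .data$divergence_pct,
      colour = .data$trait, group = .data$trait
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = xvar, y = "relative divergence (%)", colour = "trait"
    ) +
    ggplot2::theme_minimal()
}
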
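#' Plot a fitted Hill velocity-pCa curve
#'
#' Observed mean velocities (with SEM bars when available) and the fitted
#' Hill curve on a reversed pCa axis, the field's convention (calcium
#' increases to the right).
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  g <- glance(object)
  grid <- tibble::tibble(pCa = seq(min(d$pCa), max(d$pCa), length.out = 200))
  grid$velocity <- hill_velocity(grid$pCa, g$vmax, g$pca50, g$n)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pCa, y = .data$velocity)) +
    ggplot2::geom_point(size = 2)
  if ("sem" %in% names(d) && all(is.finite(d$sem))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$velocity - .data$sem,
                   ymax = .data$velocity + .data$sem),
      width = 0.05
    )
  }
  p +
    ggplot2::geom_line(data = grid, linewidth = 0.6, colour = "grey30") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "pCa", y = "Velocity (µm/s)",
                  title = sprintf("Hill fit: pCa50 = %.2f, n = %.2f",
                                  g$pca50, g$n)) +
    ggplot2::theme_classic()
}

#' Plot the XIC traces of a chromatogram set
#'
#' @param cset A `chromatogram_set`.
#' @param species Optional character vector restricting which species are
#'   shown.
#' @return A ggplot object.
#' @export
plot_chromatograms <- function(cset, species = NULL) {
  tr <- cset$traces
  if (!is.null(species)) tr <- tr[tr$species_id %in% species, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$rt_min, y = .data$intensity,
                                   colour = .data$species_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Retention time (min)", y = "Ion current (a.u.)",
                  colour = "Species",
                  title = sprintf("%s, %s, replicate %d",
                                  cset$meta$group,
                                  if (cset$meta$treated) "phosphatase-treated"
                                  else "untreated",
                                  cset$meta$replicate)) +
    ggplot2::theme_classic()
}

#' Plot motility summaries across pCa
#'
#' Velocity, percent moving or motility index as a function of pCa, one
#' line per condition, on a reversed pCa axis.
#'
#' @param summaries The `summaries` tibble of a `motility_analysis`.
#' @param quantity `"mean_velocity"`, `"fraction_moving"` or
#'   `"motility_index"`.
#' @return A ggplot object.
#' @export
plot_motility_summary <- function(summaries,
                                  quantity = c("mean_velocity",
                                               "fraction_moving",
                                               "motility_index")) {
  quantity <- match.arg(quantity)
  lab <- c(mean_velocity = "Velocity of moving filaments (µm/s)",
           fraction_moving = "Fraction moving",
           motility_index = "Motility index (µm/s)")[[quantity]]
  p <- ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$pCa, y = .data[[quantity]],
                 colour = .data$condition, group = .data$condition)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line()
  if (quantity == "mean_velocity") {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_velocity - .data$sem_velocity,
                   ymax = .data$mean_velocity + .data$sem_velocity),
      width = 0.05
    )
  }
  p +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "pCa", y = lab, colour = "Condition") +
    ggplot2::theme_classic()
}

#' Plot a quantification result
#'
#' Bar chart of per-group estimates with SD error bars for one quantity of
#' a quantification table.
#'
#' @param quant A `phospho_quant` tibble (or the combined
#'   [quantify_runs()] output filtered to one quantity/target).
#' @return A ggplot object.
#' @export
plot_phospho_quant <- function(quant) {
  ggplot2::ggplot(quant, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$sd,
                   ymax = .data$estimate + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~ .data$target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Estimate") +
    ggplot2::theme_classic()
}
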
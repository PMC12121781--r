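# Diagnostic plots: the two-panel density/derivative view behind the
# derivative method, and method-by-group frequency bars.

#' Plot a derivative-method cutoff diagnosis
#'
#' Two stacked panels: the kernel density estimate of the scores above, its
#' discrete first derivative below, with vertical lines at the GT and ST
#' cutoffs in both panels.
#'
#' @param object A `pavca_cutoffs` produced by [derivative_cutoffs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pavca_cutoffs
#' @export
autoplot.pavca_cutoffs <- function(object, ...) {
  if (is.null(object$curves)) {
    abort_validation(
      "This cutoff pair carries no curves; only derivative-method cutoffs can be plotted."
    )
  }
  dens <- object$curves$density
  deriv <- object$curves$derivative
  long <- dplyr::bind_rows(
    tibble(x = dens$x, y = dens$f, panel = "density f(x)"),
    tibble(x = deriv$x, y = deriv$dfdx, panel = "first derivative df/dx")
  )
  long$panel <- factor(
    long$panel, levels = c("density f(x)", "first derivative df/dx")
  )
  cuts <- tibble(
    cutoff = c(object$gt_cutoff, object$st_cutoff),
    group = c("GT cutoff", "ST cutoff")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = cuts,
      ggplot2::aes(xintercept = .data$cutoff, colour = .data$group),
      linetype = "dashed"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(
      x = "PavCA index score", y = NULL, colour = NULL,
      title = "Derivative-method cutoffs",
      subtitle = sprintf(
        "GT < %.3f, ST > %.3f (h = %.3f)",
        object$gt_cutoff, object$st_cutoff,
        object$diagnostics$bandwidth %||% NA_real_
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot phenotype frequencies by classification method
#'
#' @param report A `pavca_comparison`.
#' @return A ggplot of grouped frequency bars.
#' @export
plot_frequencies <- function(report) {
  long <- tidyr::pivot_longer(
    report$frequencies,
    cols = c("n_ST", "n_GT", "n_IN"),
    names_to = "group", names_prefix = "n_", values_to = "n"
  )
  long$group <- factor(long$group, levels = phenotype_levels)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$group, y = .data$n, fill = .data$method)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(
      x = "Phenotype group", y = "Subjects", fill = "Method",
      title = "Group frequencies by classification method"
    ) +
    ggplot2::theme_minimal()
}
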
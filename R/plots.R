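## ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free energy surface or profile
#'
#' @param object A `"fes"` from [fes_from_hills()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fes <- function(object, ...) {
  if (is.null(object$z)) {
    df <- tibble::tibble(s = object$s, F = object$F)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$F)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "S", y = "F (kcal/mol)"))
  }
  df <- tidyr::expand_grid(s = object$s, z = object$z)
  df$F <- as.vector(t(object$F))
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$z, fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$F), colour = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
    ggplot2::labs(x = "S", y = expression(Z ~ (nm^2)))
}

#' Plot a dG-versus-divider curve
#'
#' @param object A `"dg_curve"` from [dg_vs_divider_curve()].
#' @param x_star Optional [dividing_frame()] to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dg_curve <- function(object, x_star = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$s_star, .data$dg_b)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dividing frame s*",
                  y = expression(Delta * G[b] ~ "(kcal/mol)"))
  if (!is.null(x_star))
    p <- p + ggplot2::geom_vline(xintercept = x_star$s_star,
                                 linetype = "dashed", colour = "red")
  p
}

#' Hill-height decay of a metadynamics run
#'
#' The workhorse convergence view: deposited Gaussian heights against
#' time, with the residual-height threshold marked.
#'
#' @param run A `"wtmetad_run"` (or a hills tibble).
#' @param height_fraction Threshold fraction of the nominal height.
#' @return A ggplot.
#' @export
plot_hill_heights <- function(run, height_fraction = 0.1) {
  hills <- if (inherits(run, "wtmetad_run")) run$hills else run
  h0 <- if (inherits(run, "wtmetad_run")) run$params$height else max(hills$height)
  ggplot2::ggplot(hills, ggplot2::aes(.data$time, .data$height)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = height_fraction * h0,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (ps)", y = "hill height (kcal/mol)")
}

#' CV progression of a metadynamics run
#'
#' @param run A `"wtmetad_run"` (or a colvar tibble).
#' @return A ggplot of S against time (the diffusivity view).
#' @export
plot_cv_progression <- function(run) {
  colvar <- if (inherits(run, "wtmetad_run")) run$colvar else run
  ggplot2::ggplot(colvar, ggplot2::aes(.data$time, .data$s)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (ps)", y = "S")
}

#' Scatter of computed versus experimental binding free energies
#'
#' @param table A [benchmark_table()].
#' @param band Half-width of the agreement band (kcal/mol).
#' @return A ggplot.
#' @export
plot_benchmark <- function(table, band = 2) {
  ggplot2::ggplot(table, ggplot2::aes(.data$dg_exp, .data$dg_standard)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-band, band),
                         colour = "red", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dg_standard - .data$stderr,
                                        ymax = .data$dg_standard + .data$stderr),
                           width = 0.1) +
    ggplot2::labs(x = expression(Delta * G[b]^o ~ exp ~ "(kcal/mol)"),
                  y = expression(Delta * G[b]^o ~ comp ~ "(kcal/mol)"))
}
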
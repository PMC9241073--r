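#' Plot a cycle result
#'
#' Two-panel summary of a thermodynamic-cycle estimate: the per-window
#' mean dV/dlambda (with SEM error bars) for both legs, and the
#' forward/reverse convergence profile of the cycle ddG when present.
#'
#' @param object A `fep_cycle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fep_cycle
#' @export
autoplot.fep_cycle <- function(object, ...) {
  ws <- tidy(object)
  p <- ggplot2::ggplot(ws, ggplot2::aes(x = .data$lambda, y = .data$mean,
                                        colour = .data$environment)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(lambda),
      y = expression(paste("<", partialdiff * V / partialdiff * lambda,
                           "> (kcal/mol)")),
      colour = "environment",
      title = sprintf("%s: ddG = %+.2f +/- %.2f kcal/mol",
                      object$mutation_label, object$ddg, object$sigma)
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot the forward/reverse convergence of a cycle
#'
#' @param object A `fep_cycle` with a non-empty convergence profile.
#' @return A ggplot object.
#' @export
plot_convergence <- function(object) {
  conv <- object$convergence
  if (is.null(conv) || nrow(conv) == 0L) {
    rlang::abort("Cycle carries no convergence profile.")
  }
  ggplot2::ggplot(conv, ggplot2::aes(x = .data$fraction, y = .data$ddg,
                                     colour = .data$direction)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ddg - .data$sigma,
                                      ymax = .data$ddg + .data$sigma,
                                      fill = .data$direction),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of simulation time",
                  y = "ddG (kcal/mol)", colour = "direction",
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Plot computed vs experimental ddG for a benchmark run
#'
#' Scatter of computed against experimental relative binding free
#' energies with both error bars and the identity line; the standard
#' accuracy figure for a mutation benchmark.
#'
#' @param object A `fep_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fep_benchmark
#' @export
autoplot.fep_benchmark <- function(object, ...) {
  tab <- tidy(object)
  tab <- tab[tab$scored, ]
  if (!"ddg_comp_sd_kcal" %in% names(tab)) tab$ddg_comp_sd_kcal <- NA_real_
  if (!"ddg_exp_sd" %in% names(tab)) tab$ddg_exp_sd <- NA_real_
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$ddg_exp, y = .data$ddg_comp)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$ddg_comp - dplyr::coalesce(.data$ddg_comp_sd_kcal, 0),
      ymax = .data$ddg_comp + dplyr::coalesce(.data$ddg_comp_sd_kcal, 0)),
      width = 0, colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$ddg_exp - dplyr::coalesce(.data$ddg_exp_sd, 0),
      xmax = .data$ddg_exp + dplyr::coalesce(.data$ddg_exp_sd, 0)),
      height = 0, colour = "darkgreen", alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mutation),
                       vjust = -0.8, size = 2.8) +
    ggplot2::labs(
      x = "experimental ddG (kcal/mol)",
      y = "computed ddG (kcal/mol)",
      title = sprintf("MAE %.2f kcal/mol, r = %.2f (n = %d)",
                      object$stats$mae, object$stats$pearson_r,
                      object$stats$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a conformational-state histogram
#'
#' @param object A `conf_states` object.
#' @param ... Unused.
#' @return A ggplot object colouring each frame's descriptor value by its
#'   assigned state.
#' @method autoplot conf_states
#' @export
autoplot.conf_states <- function(object, ...) {
  df <- tibble::tibble(value = object$series$value,
                       state = object$assignments)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$state)) +
    ggplot2::geom_histogram(bins = 80, position = "identity",
                            alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$states$mode,
                        linetype = "dotted") +
    ggplot2::labs(x = "descriptor value", y = "frames", fill = "state") +
    ggplot2::theme_minimal()
}
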
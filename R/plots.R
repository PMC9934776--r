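# ggplot2 graphics for fitted objects.

#' Positional variance diagram
#'
#' Heatmap of the MCMC positional probabilities per subtype: rows are
#' events (biomarkers ordered as in the event set, i.e. cortical to
#' subcortical with the default ROI list; z = 1 "subtle abnormality" in red,
#' z = 2 "atrophy" in magenta), columns are sequence positions, and opacity
#' is the posterior probability that the event occupies the position.
#'
#' @param object A `zs_trace` from [mcmc_sequences()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zs_trace
#' @export
autoplot.zs_trace <- function(object, ...) {
  pp <- positional_probabilities(object)
  ev <- object$events$events
  lev <- rev(paste(ev$roi, ev$z, sep = " z="))
  pp$event_label <- factor(paste(pp$roi, pp$z, sep = " z="), levels = lev)
  pp$threshold <- factor(pp$z)
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$position, y = .data$event_label,
                                   fill = .data$threshold,
                                   alpha = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c("#d7191c", "#d01c8b"),
                               name = "z threshold") +
    ggplot2::scale_alpha(range = c(0, 1), limits = c(0, 1)) +
    ggplot2::facet_wrap(~subtype, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sequence position", y = NULL,
                  title = "Positional variance diagram") +
    ggplot2::theme_minimal()
}

#' CVIC model-selection curve
#'
#' @param object A `zs_cv` from [run_cv()].
#' @param ... Unused.
#' @return A ggplot of CVIC against the number of subtypes, the selected
#'   model highlighted.
#' @method autoplot zs_cv
#' @export
autoplot.zs_cv <- function(object, ...) {
  d <- tidy.zs_cv(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_subtypes, y = .data$cvic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 3) +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey40",
                                           "TRUE" = "#d7191c"),
                                guide = "none") +
    ggplot2::labs(x = "number of subtypes", y = "CVIC",
                  title = "Cross-validation information criterion") +
    ggplot2::theme_minimal()
}

#' Subtype-by-stage assignment heatmap
#'
#' @param assignments An [assign_subtypes()] tibble.
#' @param E Stage range upper bound (0..E); inferred when omitted.
#' @return A ggplot heatmap of assignment counts.
#' @export
plot_stage_heatmap <- function(assignments, E = max(assignments$ml_stage)) {
  d <- stage_counts(assignments, E = E)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ml_stage,
                                  y = factor(.data$ml_subtype),
                                  fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2b8cbe") +
    ggplot2::labs(x = "stage", y = "subtype", fill = "count",
                  title = "Stage assignments by subtype") +
    ggplot2::theme_minimal()
}

#' Per-subtype annualized decline with confidence intervals
#'
#' @param fit A converged [fit_decline_lme()].
#' @return A ggplot point-range of slopes from [decline_summary()].
#' @export
plot_decline <- function(fit) {
  d <- decline_summary(fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subtype, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(x = "subtype", y = "slope (score units / yr)",
                  title = "Annualized cognitive decline by subtype") +
    ggplot2::theme_minimal()
}
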
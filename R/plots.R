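#' Plot methods for pipeline results
#'
#' `autoplot()` methods give quick diagnostic figures: a stacked cell-type
#' composition bar chart for deconvolution results and a step survival
#' curve with its confidence band for Kaplan-Meier fits.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.deconvolution_result <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated fraction", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plots
#' @export
autoplot.km_fit <- function(object, ...) {
  tab <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, lower = 1, upper = 1), object$table)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dashed",
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dashed",
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Volcano plot of paired differential methylation results
#'
#' @param dmp A [paired_dmp()] result.
#' @param fdr_cut Highlight cutoff on the adjusted p-value.
#' @return A ggplot object.
#' @export
plot_volcano <- function(dmp, fdr_cut = 0.05) {
  ggplot2::ggplot(dmp, ggplot2::aes(x = .data$delta_beta,
                                    y = -log10(.data$p_value),
                                    colour = .data$p_adjusted < fdr_cut)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = paste0("FDR < ", fdr_cut)) +
    ggplot2::labs(x = expression(Delta * beta ~ "(on-treatment - baseline)"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Dot plot of jointly hypomethylated and upregulated gene sets
#'
#' @param joint A [joint_hypo_up()] result.
#' @return A ggplot object.
#' @export
plot_joint_enrichment <- function(joint) {
  ggplot2::ggplot(joint, ggplot2::aes(x = .data$neg_log10_p_expr,
                                      y = stats::reorder(.data$set,
                                                         .data$neg_log10_p_expr),
                                      size = .data$neg_log10_p_meth)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = expression(-log[10] ~ p ~ "(expression)"),
                  y = NULL,
                  size = expression(-log[10] ~ p ~ "(methylation)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
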
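#' Plot aggregated proportional variable importance
#'
#' One panel per model family, variables ordered by mean proportional
#' importance with an SD error bar — the layout of the bootstrap importance
#' figures.
#'
#' @param importance_agg output of [aggregate_importance()].
#' @return a ggplot object.
#' @export
plot_importance <- function(importance_agg) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting needs the ggplot2 package")
  ord <- stats::aggregate(mean_proportional ~ variable, importance_agg, mean)
  importance_agg$variable <- factor(
    importance_agg$variable, levels = ord$variable[order(ord$mean_proportional)])
  ggplot2::ggplot(importance_agg,
                  ggplot2::aes(x = .data$mean_proportional, y = .data$variable)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = pmax(.data$mean_proportional - .data$sd_proportional, 0),
      xmax = .data$mean_proportional + .data$sd_proportional), height = 0.3) +
    ggplot2::facet_wrap(~learner_type) +
    ggplot2::labs(x = "mean proportional importance", y = NULL)
}

#' Plot change importance products per model family
#'
#' Variables ordered by their overall mean change importance product,
#' descending, with per-family points.
#'
#' @param cip a `cip_table` from [change_importance_product()].
#' @return a ggplot object.
#' @export
plot_cip <- function(cip) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting needs the ggplot2 package")
  ord <- unique(cip[order(cip$overall_mean_product), "variable"])
  cip$variable <- factor(cip$variable, levels = ord)
  ggplot2::ggplot(cip, ggplot2::aes(x = .data$product, y = .data$variable,
                                    colour = .data$learner_type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$overall_mean_product),
                        colour = "black", shape = 3) +
    ggplot2::labs(x = "change importance product", y = NULL,
                  colour = "model")
}

#' Plot an ensemble partial-dependence curve
#'
#' Mean probability of presence against the covariate grid with a +-SD
#' ribbon pooled across all members of all model families.
#'
#' @param curve a `pd_curve` from [partial_dependence()].
#' @return a ggplot object.
#' @export
plot_partial_dependence <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting needs the ggplot2 package")
  ggplot2::ggplot(as.data.frame(curve), ggplot2::aes(x = .data$grid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd, 1)),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = curve$variable[1], y = "probability of presence")
}
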
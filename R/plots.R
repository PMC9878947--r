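#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot survival curves
#'
#' @param object A `surv_curves`.
#' @param max_curves Spaghetti lines to draw (seeded-free: first ids).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot surv_curves
#' @export
autoplot.surv_curves <- function(object, max_curves = 50, ...) {
  df <- tidy(object)
  show <- object$ids[seq_len(min(max_curves, length(object$ids)))]
  mean_df <- df |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(survival = mean(.data$survival), .groups = "drop")
  ggplot2::ggplot(df[df$participant_id %in% show, ],
                  ggplot2::aes(.data$time, .data$survival,
                               group = .data$participant_id)) +
    ggplot2::geom_step(alpha = 0.2) +
    ggplot2::geom_step(data = mean_df, ggplot2::aes(group = NULL),
                       linewidth = 1.1, colour = "firebrick") +
    ggplot2::labs(x = "Years since landmark", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Ranked variable-importance bars
#'
#' @param object A `trajsurv_importance`.
#' @param top_n Features to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajsurv_importance
#' @export
autoplot.trajsurv_importance <- function(object, top_n = 20, ...) {
  df <- object |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(.data$importance,
                                   stats::reorder(.data$feature,
                                                  .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Normalized importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Force-style plot of one participant's Shapley attribution
#'
#' @param object A `trajsurv_shapley`.
#' @param top_n Features to display (by absolute contribution).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajsurv_shapley
#' @export
autoplot.trajsurv_shapley <- function(object, top_n = 15, ...) {
  df <- object |>
    dplyr::arrange(dplyr::desc(abs(.data$phi_adjusted))) |>
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(.data$phi_adjusted,
                                   stats::reorder(.data$feature,
                                                  abs(.data$phi_adjusted)),
                                   fill = .data$phi_adjusted > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Contribution to predicted risk", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cluster partial-dependence curves
#'
#' @param object A `trajsurv_pdp`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajsurv_pdp
#' @export
autoplot.trajsurv_pdp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$survival,
                                       colour = factor(.data$cluster))) +
    ggplot2::geom_step(linewidth = 1) +
    ggplot2::labs(x = "Years since landmark", y = "Mean survival",
                  colour = "Cluster",
                  title = attr(object, "variable")) +
    ggplot2::theme_minimal()
}

#' Variable-by-visit importance heatmap
#'
#' Cell shading encodes per-visit permutation importance in ordered
#' quartile bins (darker = more important); rows are ordered by overall
#' importance.
#'
#' @param object A `trajsurv_time`.
#' @param visit_years Optional visit labels for the columns.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajsurv_time
#' @export
autoplot.trajsurv_time <- function(object, visit_years = NULL, ...) {
  cells <- attr(object, "cells")
  df <- tibble::as_tibble(cells, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "visit",
                        values_to = "cell") |>
    dplyr::mutate(visit = as.integer(gsub("\\D", "", .data$visit)))
  if (!is.null(visit_years)) df$visit <- visit_years[df$visit]
  pos <- df$cell[df$cell > 0 & !is.na(df$cell)]
  brk <- unique(c(-Inf, quantile(pos, c(0.25, 0.5, 0.75)), Inf))
  df$bin <- cut(df$cell, breaks = brk,
                labels = paste0("Q", seq_len(length(brk) - 1)))
  ord <- object$variable[order(object$importance)]
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$visit),
                                   factor(.data$variable, levels = ord),
                                   fill = .data$bin)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "Blues", na.value = "grey90") +
    ggplot2::labs(x = "Visit", y = NULL, fill = "Importance") +
    ggplot2::theme_minimal()
}

#' Time-varying AUC curves per strategy
#'
#' The time-dependent AUC over the prediction window, one line per
#' (strategy, model), with the bootstrap interval as a ribbon.
#'
#' @param summary Output of [summarize_benchmark()].
#' @return A ggplot.
#' @export
plot_auc_curves <- function(summary) {
  df <- summary[summary$metric == "auc" & !is.na(summary$horizon), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$horizon, .data$mean,
                                   colour = .data$strategy,
                                   fill = .data$strategy,
                                   linetype = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Years since landmark", y = "Time-dependent AUC") +
    ggplot2::theme_minimal()
}
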
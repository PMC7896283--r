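# ggplot2 views of the main result types.

#' Plot a detected trend with station-level lines
#'
#' Station-year points on the transformed scale, thin per-station fitted
#' lines (fixed plus random effects), the bold fixed-effect trend, and its
#' 95% confidence ribbon.
#'
#' @param object A `pollen_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pollen_trend <- function(object, ...) {
  fit <- object$fit
  df <- fit$data
  df$year <- df$year_c + mean(range(df$year))
  co <- tidy(fit)
  b0 <- co$estimate[co$term == "(Intercept)"]
  b1 <- co$estimate[co$term == "year_c"]
  re <- random_effects(fit)
  idx <- match(df$station_id, re$station_id)
  df$.line <- (b0 + re$intercept[idx]) + (b1 + re$year_c[idx]) * df$year_c

  v <- tryCatch(stats::vcov(fit$model)$cond, error = function(e) NULL)
  grid <- tibble::tibble(
    year_c = seq(min(df$year_c), max(df$year_c), length.out = 50)
  )
  grid$year <- grid$year_c + mean(range(df$year))
  grid$.fixed <- b0 + b1 * grid$year_c
  if (!is.null(v)) {
    se <- sqrt(v[1, 1] + 2 * grid$year_c * v[1, 2] + grid$year_c^2 * v[2, 2])
    grid$.lo <- grid$.fixed - qnorm(0.975) * se
    grid$.hi <- grid$.fixed + qnorm(0.975) * se
  }

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$.y), alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$.line, group = .data$station_id),
      alpha = 0.35, linewidth = 0.3
    )
  if (!is.null(v)) {
    p <- p + ggplot2::geom_ribbon(
      data = grid,
      ggplot2::aes(ymin = .data$.lo, ymax = .data$.hi),
      alpha = 0.25, fill = "steelblue"
    )
  }
  p +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$.fixed),
      linewidth = 1, color = "steelblue4"
    ) +
    ggplot2::labs(
      x = "Year",
      y = sprintf("%s(%s)", fit$transform, fit$response),
      title = sprintf("Trend in %s", fit$response)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of ensemble percent ACC contributions
#'
#' One box per metric and period: the distribution across climate models of
#' the percent contribution of anthropogenic climate change to the observed
#' metric trend.
#'
#' @param object A `pollen_attribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pollen_attribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$period <- sprintf("%d-%d", df$period_start, df$period_end)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$metric, y = .data$percent_contribution,
      fill = .data$period
    )
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::labs(
      x = NULL, y = "ACC contribution to observed trend (%)",
      fill = "Period"
    ) +
    ggplot2::theme_minimal()
}

#' Delta-AIC profile of an all-subsets selection
#'
#' Candidate models by rank against delta-AIC, highlighting the plausible
#' set (delta-AIC within the selection window) and the selected model
#' (highest marginal R2 within the set).
#'
#' @param object A `pollen_selection`.
#' @param max_rank Show at most this many top-ranked models.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pollen_selection <- function(object, max_rank = 30, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$rank <= max_rank & !is.na(df$delta_aic), ]
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$delta_aic,
      y = stats::reorder(.data$terms, -.data$rank),
      color = .data$in_top_set, shape = .data$selected
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(
      x = expression(Delta * "AIC"), y = NULL,
      color = "Plausible set", shape = "Selected"
    ) +
    ggplot2::theme_minimal()
}
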
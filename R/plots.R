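#' Plot a fitted age trend
#'
#' Expression values against age (log2-scaled axis) with the fitted
#' population trend overlaid; the residual fluctuations around the
#' curve are what the age-corrected correlation is computed on.
#'
#' @param object a `trend_fit`.
#' @param n_grid grid points for the trend curve.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trend_fit <- function(object, n_grid = 200, ...) {
  df <- tidy(object)
  grid <- tibble::tibble(
    age_pcd = 2^seq(log2(min(df$age_pcd)), log2(max(df$age_pcd)),
                    length.out = n_grid))
  grid$fitted <- predict(object, grid$age_pcd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_pcd)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       linewidth = 1, colour = "#1f77b4") +
    ggplot2::geom_vline(xintercept = 280, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "age (post-conception days, log scale)",
                  y = "log2 expression",
                  title = if (is.na(object$gene)) NULL else object$gene,
                  subtitle = sprintf("%d knots%s, LOO-ready trend",
                                     object$n_knots,
                                     if (object$relaxed) " (relaxed)" else "")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.trend_fit
#' @param x a `trend_fit`.
#' @param y unused.
#' @export
plot.trend_fit <- function(x, y, ...) print(autoplot.trend_fit(x, ...))

#' Plot both genes of an age-corrected pair
#'
#' The two expression profiles and their fitted trends on one panel —
#' the visual signature of a developmental switch is two crossing
#' trend curves with co-fluctuating residuals.
#'
#' @param object an `age_corrected` result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.age_corrected <- function(object, ...) {
  dfs <- dplyr::bind_rows(
    dplyr::mutate(tidy(object$fit_a), which = object$summary$gene_a),
    dplyr::mutate(tidy(object$fit_b), which = object$summary$gene_b))
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$age_pcd, colour = .data$which)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 1) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "age (post-conception days, log scale)",
                  y = "log2 expression", colour = NULL,
                  subtitle = sprintf(
                    "raw rho = %.2f, trend corr = %.2f, residual rho = %.2f",
                    object$summary$raw_rho, object$summary$trend_corr,
                    object$summary$resid_rho)) +
    ggplot2::theme_minimal()
}

#' Heatmap of ranked pairs across regions
#'
#' Tile plot of the heatmap table from [render_heatmap_table()]:
#' colour encodes `-log10(q)`, gray tiles mark regions where the pair
#' was range-filtered or not significant.
#'
#' @param heatmap_tbl output of [render_heatmap_table()].
#' @return a ggplot.
#' @export
plot_pair_heatmap <- function(heatmap_tbl) {
  df <- dplyr::mutate(heatmap_tbl,
    pair = stats::reorder(paste(.data$gene_a, .data$gene_b, sep = " / "),
                          -.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$pair)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score), colour = "white") +
    ggplot2::geom_tile(data = df[df$missing, , drop = FALSE],
                       fill = "grey80", colour = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  name = expression(-log[10](q))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of a p-value distribution
#'
#' @param object a `pval_dist`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pval_dist <- function(object, ...) {
  df <- tidy(object)
  df$bin <- factor(sprintf("[%.1f, %s)", df$bin_lo,
                           ifelse(is.finite(df$bin_hi),
                                  sprintf("%.1f", df$bin_hi), "Inf")),
                   levels = unique(sprintf("[%.1f, %s)", df$bin_lo,
                                           ifelse(is.finite(df$bin_hi),
                                                  sprintf("%.1f", df$bin_hi),
                                                  "Inf"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::labs(x = expression(-log[10](p)), y = "fraction of pairs",
                  title = object$label) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
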
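#' Manhattan plot of an EnWAS screen
#'
#' Plots the signed `-log10` p-value of every screened exposure: height gives
#' statistical significance, sign the direction of association (magnitude of
#' the effect is deliberately not encoded). Horizontal lines mark the
#' Bonferroni threshold in both directions.
#'
#' @param object An [enwas_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enwas_screen <- function(object, ...) {
  thr <- -log10(attr(object, "threshold"))
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = df$variable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$signed_log10p,
                                   colour = .data$signed_log10p > 0)) +
    ggplot2::geom_point(size = 2, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "#2980b9")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p) %*% sign),
                  title = "Environment-wide association screen") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 7))
}

#' Quantile-quantile plot of screen p-values
#'
#' Observed versus expected `-log10` p-values under the global null; marked
#' departure from the diagonal indicates systematic over- or
#' under-dispersion of the screen statistics.
#'
#' @param screen An [enwas_screen()] result (or any data frame with a `p`
#'   column).
#' @return A ggplot object.
#' @export
plot_qq <- function(screen) {
  pts <- qq_points(screen$p)
  ggplot2::ggplot(pts, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Map or caterpillar plot of a fitted risk surface
#'
#' With graph coordinates available, draws the posterior mean relative-risk
#' surface as a point map (optionally coloured by exceedance class);
#' otherwise a caterpillar plot of per-area RRs with 95% credible intervals,
#' sorted by posterior mean.
#'
#' @param object A [fit_bym2()] result.
#' @param classify If `TRUE`, overlay the 80% exceedance classification.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bym2_fit <- function(object, classify = FALSE, ...) {
  df <- object$areas
  g <- object$graph
  if (!is.null(g$coords)) {
    df$x <- g$coords[match(df$area_id, g$area_ids), 1]
    df$y <- g$coords[match(df$area_id, g$area_ids), 2]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
    if (classify) {
      df$class <- exceedance(object)$class
      p <- p + ggplot2::geom_point(data = df,
                                   ggplot2::aes(colour = .data$class), size = 3) +
        ggplot2::scale_colour_manual(values = c(elevated = "#c0392b",
                                                lowered = "#2980b9",
                                                uncertain = "grey75"))
    } else {
      p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$rr_mean),
                                   size = 3) +
        ggplot2::scale_colour_gradient2(midpoint = 1, low = "#2980b9",
                                        mid = "grey90", high = "#c0392b")
    }
    p + ggplot2::coord_equal() + ggplot2::theme_void() +
      ggplot2::labs(colour = if (classify) "classification" else "RR")
  } else {
    df <- df[order(df$rr_mean), ]
    df$rank <- seq_len(nrow(df))
    ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$rr_mean)) +
      ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rr_low,
                                            ymax = .data$rr_high),
                               size = 0.2) +
      ggplot2::labs(x = "areas (sorted)", y = "relative risk") +
      ggplot2::theme_minimal()
  }
}

#' Correlation heat map of the exposure battery
#'
#' Displays the Spearman correlation matrix used to identify groups of
#' intercorrelated exposures that cannot enter the same regression.
#'
#' @param corr A correlation matrix from [spearman_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr) {
  df <- tibble::as_tibble(corr, rownames = "var1") |>
    tidyr::pivot_longer(-"var1", names_to = "var2", values_to = "rho")
  lv <- rownames(corr)
  df$var1 <- factor(df$var1, levels = lv)
  df$var2 <- factor(df$var2, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2980b9",
                                  mid = "white", high = "#c0392b",
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(rho)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
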
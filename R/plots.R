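#' Plot the compensatory-power profile of a scan
#'
#' Per-residue compensatory power along the sequence, with predicted
#' rescue sites highlighted and the classification threshold drawn as a
#' dashed line.
#'
#' @param object A `dfs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfs_result <- function(object, ...) {
  prof <- object$profile
  prof$position <- seq_len(nrow(prof))
  thr <- attr(prof, "threshold")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$P)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$predicted), size = 1.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "forestgreen"),
      labels = c(`FALSE` = "other", `TRUE` = "rescue site"), name = NULL
    ) +
    ggplot2::labs(
      x = "residue (sequence order)", y = "compensatory power P",
      title = "Double-force-scanning compensatory power"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a rescuability matrix
#'
#' S_ij over all ordered pairs: rows are first (pathogenic) sites, columns
#' candidate rescue sites; positive values mark compensatory pairs.
#'
#' @param m A `rescuability_matrix`.
#' @return A ggplot object.
#' @export
plot_rescuability <- function(m) {
  df <- tidy(m)
  df$i <- match(df$first_site, rownames(m))
  df$j <- match(df$rescue_site, colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick",
      midpoint = 0, name = expression(S[ij])
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "candidate rescue site j", y = "first site i",
      title = paste0("Rescuability matrix (", attr(m, "scheme"), " scheme)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot mode overlaps of compensatory motions
#'
#' Boxplots of the squared inner products between a set of compensatory
#' motions and each normal mode of the essential space, with the per-mode
#' collectivity index overlaid.
#'
#' @param overlaps Tibble with columns `mode` and `inner_product_sq` (one
#'   row per motion/mode pair), e.g. assembled from [rmsip()] calls.
#' @param spectrum Optional `mode_spectrum` whose collectivity to overlay.
#' @return A ggplot object.
#' @export
plot_mode_overlap <- function(overlaps, spectrum = NULL) {
  p <- ggplot2::ggplot(
    overlaps,
    ggplot2::aes(x = factor(.data$mode), y = .data$inner_product_sq)
  ) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.6) +
    ggplot2::labs(
      x = "normal mode", y = "squared inner product",
      title = "Overlap of compensatory motions with the essential space"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(spectrum)) {
    kap <- tidy(spectrum)
    p <- p + ggplot2::geom_line(
      data = kap,
      ggplot2::aes(x = .data$mode, y = .data$collectivity, group = 1),
      colour = "orange", linewidth = 0.9
    ) +
      ggplot2::geom_point(
        data = kap,
        ggplot2::aes(x = .data$mode, y = .data$collectivity),
        colour = "orange"
      )
  }
  p
}
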
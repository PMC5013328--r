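#' Plot a TFI ROC curve
#'
#' ROC curve of the slide-level TFI classifier with the closest-to-(0,1)
#' operating point highlighted and the AUC in the subtitle.
#'
#' @param object a `tfi_roc` from [roc_from_tfi()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tfi_roc <- function(object, ...) {
  pts <- object$points
  opt <- tibble(fpr = object$optimal_point["fpr"],
                tpr = object$optimal_point["tpr"])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::geom_point(data = opt, colour = "#d95f02", size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "Low-risk classification from mean tubule nuclei ratio",
      subtitle = sprintf("AUC = %.3f; optimal threshold = %.4f",
                         object$auc, object$optimal_threshold)) +
    ggplot2::theme_minimal()
}

#' Violin plot of per-slide mean TFI by group
#'
#' @param wsi per-slide tibble with a `mean_tfi` column, e.g.
#'   `analyze_cohort()$wsi`.
#' @param group name of the grouping column (default `"group_label"`).
#' @return a ggplot.
#' @export
plot_tfi_violin <- function(wsi, group = "group_label") {
  ggplot2::ggplot(wsi, ggplot2::aes(x = .data[[group]], y = .data$mean_tfi,
                                    fill = .data[[group]])) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.7,
                         show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Mean tubule nuclei ratio per slide") +
    ggplot2::theme_minimal()
}

#' Quick-look rendering of a synthetic field
#'
#' Displays the RGB field with ground-truth nuclei centroids and tubule
#' polygon outlines, for eyeballing the generator.
#'
#' @param x a `synthetic_field` from [generate_field()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_synthetic_field <- function(x, ...) {
  px <- x$field$pixels
  d <- dim(px)
  raster <- grDevices::rgb(px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255)
  dim(raster) <- d[1:2]
  polys <- purrr::imap_dfr(x$annotation$polygons, function(p, id) {
    tibble(tubule_id = id, x = c(p[, "x"], p[1, "x"]),
           y = c(p[, "y"], p[1, "y"]))
  })
  g <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = -0.5, xmax = d[2] - 0.5,
                               ymin = -(d[1] - 0.5), ymax = 0.5) +
    ggplot2::geom_point(data = x$nuclei,
                        ggplot2::aes(x = .data$col, y = -.data$row,
                                     colour = .data$is_tubule),
                        size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b9e77",
                                            `FALSE` = "#7570b3")) +
    ggplot2::coord_equal(xlim = c(-0.5, d[2] - 0.5),
                         ylim = c(-(d[1] - 0.5), 0.5), expand = FALSE) +
    ggplot2::labs(x = "col", y = "-row", colour = "tubule nucleus") +
    ggplot2::theme_minimal()
  if (nrow(polys) > 0) {
    g <- g + ggplot2::geom_path(data = polys,
                                ggplot2::aes(x = .data$x, y = -.data$y,
                                             group = .data$tubule_id),
                                colour = "#e6ab02", linewidth = 0.5)
  }
  g
}
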
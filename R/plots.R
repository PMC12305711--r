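#' Plot a dentition scene
#'
#' Draws the ground-truth arch (solid boxes, colored by ICDAS code) and
#' optionally a set of detections (dashed boxes). The y axis is flipped
#' to match image coordinates (origin top-left).
#'
#' @param scene A `"dentition_scene"` from [simulate_scene()], or a
#'   ground-truth tibble.
#' @param dets Optional tibble of detections to overlay.
#' @return A ggplot object.
#' @export
plot_scene <- function(scene, dets = NULL) {
  gts <- if (inherits(scene, "dentition_scene")) scene$gts else scene
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = gts,
      ggplot2::aes(xmin = .data$cx - .data$w / 2, xmax = .data$cx + .data$w / 2,
                   ymin = .data$cy - .data$h / 2, ymax = .data$cy + .data$h / 2,
                   color = factor(.data$cls, levels = 0:6)),
      fill = NA, linewidth = 0.6
    ) +
    ggplot2::scale_color_viridis_d(name = "ICDAS", drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(dets) && nrow(dets) > 0) {
    p <- p + ggplot2::geom_rect(
      data = dets,
      ggplot2::aes(xmin = .data$cx - .data$w / 2, xmax = .data$cx + .data$w / 2,
                   ymin = .data$cy - .data$h / 2, ymax = .data$cy + .data$h / 2),
      fill = NA, linetype = "dashed", color = "grey30", linewidth = 0.4
    )
  }
  p
}

#' Plot a detection evaluation
#'
#' `type = "ap"` draws per-class AP bars with the mAP@50 as a reference
#' line; `type = "pr"` draws the per-class precision-recall curves the
#' AP integrates.
#'
#' @param object A `"dentpost_eval"` from [evaluate_detections()].
#' @param type `"ap"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dentpost_eval <- function(object, type = c("ap", "pr"), ...) {
  type <- match.arg(type)
  if (type == "ap") {
    pc <- object$per_class[object$per_class$n_gt > 0, , drop = FALSE]
    return(
      ggplot2::ggplot(pc, ggplot2::aes(x = factor(.data$cls), y = .data$ap)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::geom_hline(yintercept = object$map50, linetype = "dashed") +
        ggplot2::labs(x = "ICDAS code", y = "AP@50",
                      title = sprintf("mAP@50 = %.3f", object$map50)) +
        ggplot2::ylim(0, 1) +
        ggplot2::theme_minimal()
    )
  }
  curves <- purrr::imap_dfr(object$curves, function(cv, k) {
    dplyr::mutate(cv, cls = k)
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               color = .data$cls)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_color_viridis_d(name = "ICDAS") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confidence-correction trigger sweep
#'
#' @param sweep Tibble from [sweep_correction()].
#' @return A ggplot object (tile heatmap of mAP@50 with the best cell
#'   marked).
#' @export
plot_sweep <- function(sweep) {
  best <- attr(sweep, "best")
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(x = .data$fn_ratio, y = .data$fp_angle_deg,
                                    fill = .data$map50)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mAP@50") +
    ggplot2::labs(x = "d2/d1 trigger", y = "angle trigger (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(best)) {
    p <- p + ggplot2::geom_point(data = best, shape = 4, size = 3,
                                 color = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
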
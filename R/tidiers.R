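#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection result into its particle table
#'
#' @param x An `ld_detection`.
#' @param keep_pixels Retain the `pixels` list-column (default drops it).
#' @param ... Unused.
#' @return The particle tibble, one row per detection.
#' @method tidy ld_detection
#' @export
tidy.ld_detection <- function(x, keep_pixels = FALSE, ...) {
  out <- x$particles
  if (!keep_pixels && "pixels" %in% names(out)) out$pixels <- NULL
  out
}

#' One-row overview of a detection run
#'
#' @param x An `ld_detection`.
#' @param ... Unused.
#' @return A one-row tibble: brain id, stack geometry, raw and retained
#'   particle counts, ROI area and origin, iterations used.
#' @method glance ld_detection
#' @export
glance.ld_detection <- function(x, ...) {
  tibble::tibble(
    brain_id = x$brain_id,
    n_slices = x$stack_dim[1],
    n_detections = nrow(x$particles),
    n_retained = sum(x$particles$kept_after_dedup),
    roi_area_px = sum(x$roi$mask),
    roi_origin = x$roi$origin,
    max_iteration_used = if (nrow(x$particles)) max(x$particles$iteration) else 0L,
    deduplicated = x$deduplicated
  )
}

#' Overlay detected particles on the stack projection
#'
#' Quality-control figure: the maximum-intensity projection of the ROI
#' boundary-relevant region in grayscale with detected centroids overlaid;
#' retained particles and discarded doublets are distinguished by color.
#'
#' @param object An `ld_detection`.
#' @param stack Optional [image_stack()] to use for the background
#'   projection (required for the image layer; omitted, only centroids are
#'   drawn).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_detection
#' @export
autoplot.ld_detection <- function(object, stack = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(stack)) {
    proj <- apply(stack$voxels, c(2, 3), max)
    df <- tidyr::expand_grid(y = seq_len(nrow(proj)) - 1L,
                             x = seq_len(ncol(proj)) - 1L)
    df$intensity <- as.vector(t(proj))
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  pts <- tidy(object)
  if (nrow(pts) > 0) {
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                   colour = .data$kept_after_dedup),
      shape = 1, size = 2) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "#00B0F6", `FALSE` = "#F8766D"),
        name = "retained")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot control-normalized fold changes
#'
#' Dot plot of per-brain fold changes by group and metric, with the control
#' mean (fold change 1) as a reference line — the layout of the usual
#' "relative to control" quantification panels.
#'
#' @param object An `ld_comparison` from [fold_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_comparison
#' @export
autoplot.ld_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$fold_change)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fold change vs control")
}

#' @importFrom rlang .data
NULL
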
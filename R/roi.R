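#' Automatically delineate the tissue region of interest
#'
#' Whole-mount brains image as a single bright region on a dark background,
#' so the ROI is recovered as: maximum-intensity projection over z, Gaussian
#' smoothing, a global threshold, binary closing, hole filling, and keeping
#' the largest connected component. The default threshold is Otsu's method:
#' the tissue/exterior split is a two-class separation, which Otsu handles
#' robustly whether the tissue histogram is a broad tail or a second mode.
#' The triangle method (suited to unimodal-skewed histograms) and a fixed
#' cutoff are available alternatives; the maximum-entropy criterion is
#' reserved for particle detection, where it belongs. The mask is
#' computed once on the projection and shared across slices: the anatomical
#' region is stable over a short stack and a shared mask avoids per-slice
#' flicker.
#'
#' @param stack An [image_stack()].
#' @param sigma Gaussian smoothing sigma (px) applied to the projection.
#' @param method `"otsu"` (default), `"triangle"`, or `"fixed"`.
#' @param fixed_value Intensity cutoff when `method = "fixed"`.
#' @param close_radius Radius (px) of the disc structuring element for
#'   binary closing.
#' @param fallback If the resulting mask is empty, return a full-frame mask
#'   (with a warning) instead of erroring.
#' @return A [roi_mask()] with origin `"auto"`, or `"full-frame"` if the
#'   fallback fired.
#' @export
delineate_roi <- function(stack, sigma = 8, method = c("otsu", "triangle", "fixed"),
                          fixed_value = NULL, close_radius = 5, fallback = TRUE) {
  method <- match.arg(method)
  d <- dim(stack$voxels)
  proj <- apply(stack$voxels, c(2, 3), max)
  sm <- smooth_slice(proj, sigma)
  binary <- tryCatch({
    cutoff <- switch(method,
      triangle = {
        h <- bin_histogram(as.vector(sm))
        threshold_cutoff(h, triangle_threshold(h$counts))
      },
      otsu = {
        rng <- range(sm)
        if (rng[1] == rng[2]) stop(degenerate_histogram_error())
        EBImage::otsu(sm, range = rng, levels = 256L)
      },
      fixed = {
        if (is.null(fixed_value)) stop("`fixed_value` required", call. = FALSE)
        fixed_value
      })
    sm > cutoff
  }, dropletquant_degenerate_histogram = function(e) {
    matrix(FALSE, d[2], d[3])
  })
  if (any(binary)) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
    closed <- EBImage::closing(binary * 1, brush)
    filled <- EBImage::fillHull(closed)
    lab <- label_components(filled > 0)
    if (max(lab) > 0) {
      largest <- which.max(tabulate(lab[lab > 0]))
      binary <- lab == largest
    } else {
      binary <- matrix(FALSE, d[2], d[3])
    }
  }
  if (!any(binary)) {
    if (!fallback) {
      stop("ROI delineation produced an empty mask (fallback disabled)",
           call. = FALSE)
    }
    warning("ROI delineation produced an empty mask; using full frame",
            call. = FALSE)
    return(full_frame_mask(stack))
  }
  roi_mask(binary, origin = "auto", n_z = d[1])
}

#' ROI area summary
#'
#' True-pixel counts per slice and in total, with square-micrometre
#' equivalents when a pixel size is known. The total over the 3-D mask is
#' the denominator of particle density.
#'
#' @param roi A [roi_mask()].
#' @param pixel_size_xy Optional pixel size (um/px).
#' @return A list with `per_slice` (tibble: `slice`, `area_px`, `area_um2`),
#'   `total_px`, and `total_um2` (`NA` when uncalibrated).
#' @export
roi_area <- function(roi, pixel_size_xy = NULL) {
  d <- dim(roi$mask)
  per <- vapply(seq_len(d[1]), function(z) sum(roi$mask[z, , ]), numeric(1))
  f <- if (is.null(pixel_size_xy)) NA_real_ else pixel_size_xy^2
  list(
    per_slice = tibble::tibble(slice = seq_len(d[1]) - 1L,
                               area_px = per, area_um2 = per * f),
    total_px = sum(per),
    total_um2 = sum(per) * f
  )
}
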
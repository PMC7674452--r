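#' Circularity shape descriptor
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a perfect disc, smaller for
#' elongated or ragged shapes. Values are clamped to 1 (digital perimeter
#' estimators can slightly undershoot the true boundary length for small
#' discs). A particle with zero perimeter (a single pixel) is circular by
#' convention.
#'
#' @param area Area in px (vectorized).
#' @param perimeter Perimeter in px (vectorized).
#' @return Circularity in `(0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  stopifnot(all(perimeter >= 0), all(area > 0))
  ifelse(perimeter == 0, 1, pmin(1, 4 * pi * area / perimeter^2))
}

#' Per-brain summary statistics
#'
#' Aggregates a deduplicated particle table into the per-brain quantities
#' used for group comparison: particle count, density (count per unit ROI
#' area; the denominator is the total true-pixel count of the 3-D mask, so
#' padding a stack with empty-mask slices leaves density unchanged), total
#' and mean particle surface, and the circularity distribution. "Surface"
#' is the 2-D cross-sectional area of each retained particle; both the
#' per-brain total and the per-particle mean are reported.
#'
#' @param particles Particle tibble; rows with `kept_after_dedup = FALSE`
#'   are excluded.
#' @param roi A [roi_mask()], or a single number giving the ROI area in px.
#' @param pixel_size_xy Optional pixel size (um/px).
#' @param brain_id Identifier; defaults to the one carried by the particles.
#' @return A one-row tibble: `brain_id`, `n_particles`, `roi_area_px`,
#'   `density_per_px2`, `density_per_um2`, `total_surface_px2`,
#'   `mean_surface_px2`, `total_surface_um2`, `mean_surface_um2`,
#'   `circularity_mean`, `circularity_q25/q50/q75`, and `n_by_slice`
#'   (list-column). Circularity statistics are `NA` for an empty set.
#' @export
summarize_droplets <- function(particles, roi, pixel_size_xy = NULL,
                               brain_id = NULL) {
  area_px <- if (inherits(roi, "roi_mask")) sum(roi$mask) else as.numeric(roi)
  if (!is.finite(area_px) || area_px <= 0) {
    stop("ROI area must be positive", call. = FALSE)
  }
  kept <- particles[particles$kept_after_dedup %||% TRUE, , drop = FALSE]
  if (is.null(brain_id)) {
    brain_id <- if (nrow(particles) > 0) particles$brain_id[1] else "brain"
  }
  n <- nrow(kept)
  total <- sum(kept$area_px)
  f <- if (is.null(pixel_size_xy)) NA_real_ else pixel_size_xy^2
  circ_q <- if (n > 0) stats::quantile(kept$circularity, c(.25, .5, .75),
                                       names = FALSE) else rep(NA_real_, 3)
  tibble::tibble(
    brain_id = brain_id,
    n_particles = n,
    roi_area_px = area_px,
    density_per_px2 = n / area_px,
    density_per_um2 = if (is.na(f)) NA_real_ else n / (area_px * f),
    total_surface_px2 = total,
    mean_surface_px2 = if (n > 0) total / n else 0,
    total_surface_um2 = total * f,
    mean_surface_um2 = if (n > 0) total * f / n else 0 * f,
    circularity_mean = if (n > 0) mean(kept$circularity) else NA_real_,
    circularity_q25 = circ_q[1],
    circularity_q50 = circ_q[2],
    circularity_q75 = circ_q[3],
    n_by_slice = list(table_by_slice(kept))
  )
}

table_by_slice <- function(kept) {
  if (nrow(kept) == 0) return(tibble::tibble(slice = integer(), n = integer()))
  dplyr::count(kept, slice = .data$slice, name = "n")
}

#' Control-normalized fold changes
#'
#' Mirrors the figure-style quantification "relative to control": for each
#' metric, every brain's value is divided by the mean of the control group,
#' so control fold changes average to exactly 1 by construction, and test-
#' group values read directly as fold differences. The result is invariant
#' to rescaling all brains by a common factor.
#'
#' @param summaries Tibble of per-brain summaries (rows from
#'   [summarize_droplets()], or any tibble with `brain_id` and metric
#'   columns) plus a grouping column.
#' @param control Label of the control group.
#' @param metrics Character vector of metric column names to normalize.
#' @param group Name of the grouping column (default `"group"`).
#' @return A tibble of class `ld_comparison`: `brain_id`, `group`, `metric`,
#'   `value`, `control_mean`, `fold_change`, long over metrics.
#' @export
fold_change <- function(summaries, control,
                        metrics = c("n_particles", "total_surface_px2"),
                        group = "group") {
  if (!group %in% names(summaries)) {
    stop("no grouping column '", group, "' in `summaries`", call. = FALSE)
  }
  grp <- summaries[[group]]
  if (!any(grp == control)) stop("control group '", control, "' is empty",
                                 call. = FALSE)
  missing <- setdiff(metrics, names(summaries))
  if (length(missing)) stop("unknown metric(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  long <- tidyr::pivot_longer(
    summaries[, c("brain_id", group, metrics)],
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  names(long)[names(long) == group] <- "group"
  ctrl_means <- long |>
    dplyr::filter(.data$group == control) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(control_mean = mean(.data$value), .groups = "drop")
  bad <- ctrl_means$metric[ctrl_means$control_mean == 0]
  if (length(bad)) {
    stop("control mean is zero for metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- long |>
    dplyr::left_join(ctrl_means, by = "metric") |>
    dplyr::mutate(fold_change = .data$value / .data$control_mean)
  attr(out, "control") <- control
  class(out) <- c("ld_comparison", class(out))
  out
}
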
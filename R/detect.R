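#' Detection configuration
#'
#' Tunable parameters of the iterative particle detector. The defaults are
#' this package's choices, recorded in every provenance sidecar; none are
#' prescribed by the underlying method description.
#'
#' @param sigma Gaussian blur sigma in pixels applied to the working copy
#'   before thresholding (detection only; measurements always use the
#'   original slice). 0 disables smoothing.
#' @param max_iterations Maximum detect-erase rounds per slice.
#' @param min_area,max_area Particle area bounds in pixels.
#' @param min_circularity Minimum circularity `4*pi*A/P^2` to keep a
#'   particle; the default 0 reports all shapes rather than filtering.
#' @param erase_fill Value used to overwrite detected pixels on the working
#'   copy: `"background-median"` (per-slice median of the original image
#'   inside the ROI) or `"zero"`.
#' @param erase_dilate_px Radius (px) by which the erased region is dilated
#'   around each detected component. A thresholded particle is only the
#'   core of a blurred spot; its point-spread skirt stays elevated, and
#'   later, lower thresholds would re-detect fragments of that halo as
#'   spurious particles. Erasing the skirt together with the core prevents
#'   this. 0 disables dilation.
#' @param containment ROI membership rule: `"centroid"` keeps a particle
#'   whose centroid pixel lies inside the ROI, `"full"` requires every pixel
#'   inside.
#' @param histogram_bins Number of histogram bins for thresholding (fixed
#'   convention: 256).
#' @param max_fg_fraction Stopping guard: if a threshold would select more
#'   than this fraction of the ROI as foreground, the entropy criterion has
#'   started splitting the unimodal background (no genuine particles remain)
#'   and the slice's iteration loop stops.
#' @return A `detect_config` object (named list).
#' @export
detect_config <- function(sigma = 1, max_iterations = 3L, min_area = 4L,
                          max_area = 10000L, min_circularity = 0,
                          erase_fill = c("background-median", "zero"),
                          containment = c("centroid", "full"),
                          histogram_bins = 256L, max_fg_fraction = 0.2,
                          erase_dilate_px = 3L) {
  erase_fill <- match.arg(erase_fill)
  containment <- match.arg(containment)
  stopifnot(sigma >= 0, max_iterations >= 1, min_area >= 1,
            max_area > min_area, min_circularity >= 0, min_circularity <= 1,
            histogram_bins >= 2, max_fg_fraction > 0, max_fg_fraction <= 1,
            erase_dilate_px >= 0)
  structure(
    list(sigma = sigma, max_iterations = as.integer(max_iterations),
         min_area = as.integer(min_area), max_area = as.integer(max_area),
         min_circularity = min_circularity, erase_fill = erase_fill,
         containment = containment, histogram_bins = as.integer(histogram_bins),
         max_fg_fraction = max_fg_fraction,
         erase_dilate_px = as.integer(erase_dilate_px)),
    class = "detect_config"
  )
}

reflect_index <- function(i, n) {
  # symmetric (reflect) boundary: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
  i <- (i - 1L) %% (2L * n)
  i <- ifelse(i >= n, 2L * n - 1L - i, i)
  i + 1L
}

#' Gaussian smoothing of one slice
#'
#' Separable Gaussian convolution with reflect (symmetric) boundary
#' handling and a normalized kernel truncated at 3 sigma.
#'
#' @param img Numeric matrix (`y` by `x`).
#' @param sigma Standard deviation in pixels; 0 returns the input unchanged.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_slice <- function(img, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  ny <- nrow(img)
  nx <- ncol(img)
  out <- matrix(0, ny, nx)
  for (d in -r:r) out <- out + k[d + r + 1L] * img[reflect_index(1:ny + d, ny), , drop = FALSE]
  res <- matrix(0, ny, nx)
  for (d in -r:r) res <- res + k[d + r + 1L] * out[, reflect_index(1:nx + d, nx), drop = FALSE]
  res
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged through a label-adjacency graph.
label_components <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  m <- max(lab)
  if (m <= 1) return(lab)
  ny <- nrow(lab)
  nx <- ncol(lab)
  a1 <- lab[-ny, -nx]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-ny, -1];  b2 <- lab[-1, -nx]   # down-left diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0) return(lab)
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2), directed = FALSE)
  comp <- igraph::components(g)
  remap <- seq_len(m)
  ids <- as.integer(igraph::V(g)$name)
  remap[ids] <- m + comp$membership     # temporary ids, then compact
  lab2 <- lab
  lab2[lab > 0] <- remap[lab[lab > 0]]
  compact <- match(lab2, sort(unique(lab2[lab2 > 0])))
  lab2[lab2 > 0] <- compact[lab2 > 0]
  lab2
}

# Moore-neighbour boundary tracing; perimeter is the chain length with
# axial steps weighted 1 and diagonal steps sqrt(2). Single pixels have
# perimeter 0 by convention (circularity 1).
trace_perimeter <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(0)
  r0 <- min(rows) - 2L
  c0 <- min(cols) - 2L
  ny <- max(rows) - r0 + 2L
  nx <- max(cols) - c0 + 2L
  m <- matrix(FALSE, ny, nx)
  m[cbind(rows - r0, cols - c0)] <- TRUE
  idx <- cbind(rows - r0, cols - c0)
  start <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE][1, ]
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  step_len <- ifelse(rowSums(abs(offs)) == 2, sqrt(2), 1)
  cur <- start
  backtrack <- 1L
  per <- 0
  steps <- 0L
  repeat {
    advanced <- FALSE
    for (k in 0:7) {
      j <- ((backtrack - 1L + k) %% 8L) + 1L
      rr <- cur[1] + offs[j, 1]
      cc <- cur[2] + offs[j, 2]
      if (m[rr, cc]) {
        per <- per + step_len[j]
        backtrack <- ((j + 5L - 1L) %% 8L) + 1L
        cur <- c(rr, cc)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) return(0)        # isolated pixel reached via degenerate mask
    steps <- steps + 1L
    if (cur[1] == start[1] && cur[2] == start[2]) break
    if (steps > 8L * n + 8L) break  # safety; cannot trigger on valid components
  }
  per
}

empty_particles <- function() {
  tibble::tibble(
    brain_id = character(), slice = integer(), iteration = integer(),
    centroid_y = numeric(), centroid_x = numeric(),
    area_px = integer(), area_um2 = numeric(), perimeter_px = numeric(),
    circularity = numeric(), mean_intensity = numeric(),
    max_intensity = numeric(), kept_after_dedup = logical(),
    pixels = list()
  )
}

#' Extract and measure particles from a thresholded slice
#'
#' Labels the 8-connected components of `binary`, measures each on the
#' original (unblurred) slice, and applies the configured filters: area in
#' `[min_area, max_area]`, circularity at least `min_circularity`, and ROI
#' containment (`"centroid"`: the centroid pixel lies inside the ROI;
#' `"full"`: all pixels do). Centroids are 0-based `(y, x)` pixel
#' coordinates.
#'
#' @param binary Logical matrix of foreground pixels.
#' @param original Numeric matrix; intensity statistics are read from here.
#' @param roi_slice Logical matrix, the ROI restricted to this slice.
#' @param cfg A [detect_config()].
#' @param z 0-based slice index stored on each particle.
#' @param iteration 1-based detection iteration stored on each particle.
#' @param brain_id Identifier stored on each particle.
#' @param pixel_size_xy Optional pixel size (um/px) for `area_um2`.
#' @return A tibble of kept particles (possibly empty) with a `pixels`
#'   list-column of 1-based `(row, col)` index matrices. The attribute
#'   `all_pixels` carries the pixels of every component (kept or filtered),
#'   used by the iterative detector to erase everything it has seen.
#' @export
extract_particles <- function(binary, original, roi_slice, cfg, z, iteration,
                              brain_id = "brain", pixel_size_xy = NULL) {
  stopifnot(identical(dim(binary), dim(original)),
            identical(dim(binary), dim(roi_slice)))
  lab <- label_components(binary)
  if (max(lab) == 0) {
    out <- empty_particles()
    attr(out, "all_pixels") <- matrix(integer(), ncol = 2)
    return(out)
  }
  fg <- which(lab > 0)
  labs <- lab[fg]
  rows <- ((fg - 1L) %% nrow(lab)) + 1L
  cols <- ((fg - 1L) %/% nrow(lab)) + 1L
  by_lab <- split(seq_along(fg), labs)
  recs <- lapply(by_lab, function(ii) {
    r <- rows[ii]
    c <- cols[ii]
    a <- length(ii)
    cy <- mean(r) - 1
    cx <- mean(c) - 1
    ok_contain <- if (cfg$containment == "centroid") {
      roi_slice[round(cy) + 1L, round(cx) + 1L]
    } else {
      all(roi_slice[cbind(r, c)])
    }
    if (!ok_contain || a < cfg$min_area || a > cfg$max_area) return(NULL)
    per <- trace_perimeter(r, c)
    circ <- circularity(a, per)
    if (circ < cfg$min_circularity) return(NULL)
    vals <- original[cbind(r, c)]
    list(slice = as.integer(z), centroid_y = cy, centroid_x = cx,
         area_px = a, perimeter_px = per, circularity = circ,
         mean_intensity = mean(vals), max_intensity = max(vals),
         pixels = cbind(r, c))
  })
  recs <- unname(recs[!vapply(recs, is.null, logical(1))])
  all_px <- cbind(rows, cols)
  if (length(recs) == 0) {
    out <- empty_particles()
  } else {
    out <- tibble::tibble(
      brain_id = brain_id,
      slice = vapply(recs, `[[`, integer(1), "slice"),
      iteration = as.integer(iteration),
      centroid_y = vapply(recs, `[[`, numeric(1), "centroid_y"),
      centroid_x = vapply(recs, `[[`, numeric(1), "centroid_x"),
      area_px = vapply(recs, `[[`, integer(1), "area_px"),
      area_um2 = if (is.null(pixel_size_xy)) NA_real_ else
        vapply(recs, `[[`, integer(1), "area_px") * pixel_size_xy^2,
      perimeter_px = vapply(recs, `[[`, numeric(1), "perimeter_px"),
      circularity = vapply(recs, `[[`, numeric(1), "circularity"),
      mean_intensity = vapply(recs, `[[`, numeric(1), "mean_intensity"),
      max_intensity = vapply(recs, `[[`, numeric(1), "max_intensity"),
      kept_after_dedup = TRUE,
      pixels = lapply(recs, `[[`, "pixels")
    )
  }
  attr(out, "all_pixels") <- all_px
  out
}

#' Erase detected particles from a working image
#'
#' Sets every pixel of every particle to the fill value and leaves all other
#' pixels untouched. The fill is either 0 or the per-slice background
#' median, which the caller computes on the original image inside the ROI.
#'
#' @param working Numeric matrix (the working copy of a slice).
#' @param particles Particle tibble with a `pixels` list-column, or a
#'   2-column `(row, col)` index matrix.
#' @param fill Numeric fill value.
#' @return The modified matrix.
#' @export
erase_particles <- function(working, particles, fill) {
  px <- if (is.matrix(particles)) particles else
    do.call(rbind, particles$pixels)
  if (is.null(px) || nrow(px) == 0) return(working)
  working[px] <- fill
  working
}

#' Iterative brightest-particle detection over a stack
#'
#' The core detector. Each slice is processed independently: a working copy
#' is smoothed, its within-ROI histogram thresholded with the Kapur
#' maximum-entropy criterion, super-threshold components are measured
#' (intensities on the original slice) and then erased from the working
#' copy, so the next iteration's histogram — rebinned over a now narrower
#' intensity range — places its threshold lower and surfaces dimmer
#' particles. Iteration stops early when the histogram is degenerate, the
#' threshold would select more than `max_fg_fraction` of the ROI (the
#' entropy criterion splitting bare background), or no particle passes the
#' filters.
#'
#' All super-threshold components, kept or filtered, are erased, so pixel
#' sets of particles from different iterations of one slice are disjoint by
#' construction. Detection contains no randomness: identical stack, ROI and
#' configuration yield an identical result.
#'
#' @param stack An [image_stack()].
#' @param roi A [roi_mask()] congruent with the stack.
#' @param cfg A [detect_config()].
#' @param brain_id Identifier stored on every particle.
#' @return A list of class `ld_detection`: `particles` (tibble, one row per
#'   detection, `kept_after_dedup` all `TRUE` until [dedup_particles()] is
#'   applied), `thresholds` (per slice and iteration: intensity cutoff,
#'   foreground fraction, particle count and a status flag), `roi`, `config`
#'   and stack metadata.
#' @export
iterative_detect <- function(stack, roi, cfg = detect_config(),
                             brain_id = "brain") {
  check_congruent(stack, roi)
  nz <- n_slices(stack)
  parts <- vector("list", nz)
  logs <- vector("list", nz)
  for (zi in seq_len(nz)) {
    z <- zi - 1L
    original <- get_slice(stack, z)
    rsl <- mask_slice(roi, z)
    roi_n <- sum(rsl)
    fill <- if (cfg$erase_fill == "zero") 0 else
      stats::median(original[rsl])
    working <- original
    slice_parts <- list()
    slice_log <- list()
    if (roi_n == 0) {
      logs[[zi]] <- tibble::tibble(slice = z, iteration = 1L,
                                   threshold = NA_real_, fg_fraction = NA_real_,
                                   n_particles = 0L, status = "empty-roi")
      parts[[zi]] <- empty_particles()
      next
    }
    for (k in seq_len(cfg$max_iterations)) {
      sm <- smooth_slice(working, cfg$sigma)
      h <- bin_histogram(sm[rsl], cfg$histogram_bins)
      t <- tryCatch(max_entropy_threshold(h$counts),
                    dropletquant_degenerate_histogram = function(e) NA_integer_)
      if (is.na(t) || h$width == 0) {
        slice_log[[k]] <- list(threshold = NA_real_, fg_fraction = NA_real_,
                               n = 0L, status = "degenerate")
        break
      }
      cutoff <- threshold_cutoff(h, t)
      fgm <- sm > cutoff
      frac <- sum(fgm & rsl) / roi_n
      if (frac > cfg$max_fg_fraction) {
        slice_log[[k]] <- list(threshold = cutoff, fg_fraction = frac,
                               n = 0L, status = "saturated")
        break
      }
      found <- extract_particles(fgm, original, rsl, cfg, z, k,
                                 brain_id = brain_id,
                                 pixel_size_xy = stack$pixel_size_xy)
      all_px <- attr(found, "all_pixels")
      slice_log[[k]] <- list(threshold = cutoff, fg_fraction = frac,
                             n = nrow(found),
                             status = if (nrow(found) == 0) "no-particles" else "ok")
      if (nrow(found) == 0) break
      slice_parts[[k]] <- found
      erase_mask <- matrix(FALSE, nrow(working), ncol(working))
      erase_mask[all_px] <- TRUE
      if (cfg$erase_dilate_px > 0) {
        brush <- EBImage::makeBrush(2L * cfg$erase_dilate_px + 1L, "disc")
        erase_mask <- EBImage::dilate(erase_mask * 1, brush) > 0
      }
      working <- erase_particles(working, which(erase_mask, arr.ind = TRUE), fill)
    }
    parts[[zi]] <- if (length(slice_parts)) dplyr::bind_rows(slice_parts) else
      empty_particles()
    logs[[zi]] <- tibble::tibble(
      slice = z,
      iteration = seq_along(slice_log),
      threshold = vapply(slice_log, function(l) l$threshold, numeric(1)),
      fg_fraction = vapply(slice_log, function(l) l$fg_fraction, numeric(1)),
      n_particles = vapply(slice_log, function(l) as.integer(l$n), integer(1)),
      status = vapply(slice_log, function(l) l$status, character(1))
    )
  }
  structure(
    list(particles = dplyr::bind_rows(parts),
         thresholds = dplyr::bind_rows(logs),
         roi = roi, config = cfg, brain_id = brain_id,
         stack_dim = dim(stack$voxels),
         pixel_size_xy = stack$pixel_size_xy,
         deduplicated = FALSE, link = NULL),
    class = "ld_detection"
  )
}

#' One-call droplet detection pipeline
#'
#' Resolves the ROI (automatic delineation, a user-supplied mask, or the
#' full frame), runs [iterative_detect()], and removes z-dimension doublets
#' with [dedup_particles()] unless `dedup = FALSE`.
#'
#' @param stack An [image_stack()].
#' @param roi `NULL` for automatic delineation, a [roi_mask()] to use as-is,
#'   or `"full"` for the whole frame.
#' @param config A [detect_config()].
#' @param link A [link_config()] controlling doublet linking.
#' @param dedup Apply doublet removal (default `TRUE`).
#' @param brain_id Identifier stored on every particle.
#' @param roi_args List of arguments passed on to [delineate_roi()] when
#'   `roi` is `NULL`.
#' @return An `ld_detection` object (see [iterative_detect()]); after
#'   dedup, discarded doublets remain in the table with
#'   `kept_after_dedup = FALSE` for audit.
#' @export
detect_droplets <- function(stack, roi = NULL, config = detect_config(),
                            link = link_config(), dedup = TRUE,
                            brain_id = "brain", roi_args = list()) {
  roi <- if (is.null(roi)) {
    do.call(delineate_roi, c(list(stack), roi_args))
  } else if (identical(roi, "full")) {
    full_frame_mask(stack)
  } else if (inherits(roi, "roi_mask")) {
    roi
  } else {
    stop("`roi` must be NULL, \"full\", or an roi_mask", call. = FALSE)
  }
  det <- iterative_detect(stack, roi, config, brain_id = brain_id)
  if (dedup) {
    det$particles <- dedup_particles(det$particles, link)
    det$deduplicated <- TRUE
    det$link <- link
  }
  det
}

#' @export
print.ld_detection <- function(x, ...) {
  n <- nrow(x$particles)
  kept <- sum(x$particles$kept_after_dedup)
  cat(sprintf("<ld_detection> '%s': %d detections over %d slice(s)%s\n",
              x$brain_id, n, x$stack_dim[1],
              if (x$deduplicated) sprintf(", %d retained after doublet removal", kept)
              else " (doublet removal not applied)"))
  invisible(x)
}
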
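#' Specification of a synthetic confocal stack
#'
#' Describes a benchmark scene: a dark exterior with additive read noise, a
#' single bright tissue disc (the "brain"), and quasi-spherical droplets
#' planted inside the tissue. Droplet brightness is sampled log-uniformly —
#' a wide, bottom-heavy intensity range — so that a single-pass threshold
#' misses the dim end while iterative detection recovers it. Droplets are
#' rendered at absolute intensity (combined with the tissue by maximum):
#' punctum brightness reflects dye concentrated in the droplet, largely
#' independent of the autofluorescence beneath it. Each droplet is a sphere
#' in voxel space, so it appears on several consecutive slices with
#' cross-sections shrinking away from its central slice, exercising doublet
#' removal.
#'
#' @param shape Integer `(z, y, x)` dimensions.
#' @param n_droplets Number of planted droplets (K).
#' @param radius_range Droplet radius range in px (uniform).
#' @param intensity_range Absolute droplet intensity range; sampled
#'   log-uniformly. Default 3-20 times `background`.
#' @param background Exterior background level.
#' @param tissue_level,tissue_radius,tissue_center Tissue disc intensity,
#'   radius (px) and 0-based `(y, x)` center (default: frame center).
#' @param noise_sd Gaussian read-noise standard deviation (default
#'   `background / 5`).
#' @param poisson Also apply Poisson shot noise.
#' @param psf_sigma Per-slice Gaussian PSF sigma (px).
#' @param z_aspect Axial extent of one slice step in lateral-pixel units;
#'   a droplet of radius r spans slices with `|dz| * z_aspect < r`.
#' @param min_separation Minimum distance between droplet centers (px).
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; the same spec always renders the same stack.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(shape = c(12L, 512L, 512L), n_droplets = 60L,
                           radius_range = c(2, 6),
                           intensity_range = background * c(3, 20),
                           background = 10, tissue_level = 25,
                           tissue_radius = 200,
                           tissue_center = (shape[2:3] - 1) / 2,
                           noise_sd = background / 5, poisson = FALSE,
                           psf_sigma = 1, z_aspect = 1.5,
                           min_separation = 16, bit_depth = 8L, seed = 101L) {
  stopifnot(length(shape) == 3, all(shape >= 1), n_droplets >= 0,
            radius_range[1] > 0, radius_range[2] >= radius_range[1],
            intensity_range[1] > background,
            tissue_level > background, noise_sd >= 0, z_aspect > 0)
  structure(
    list(shape = as.integer(shape), n_droplets = as.integer(n_droplets),
         radius_range = radius_range, intensity_range = intensity_range,
         background = background, tissue_level = tissue_level,
         tissue_radius = tissue_radius, tissue_center = tissue_center,
         noise_sd = noise_sd, poisson = poisson, psf_sigma = psf_sigma,
         z_aspect = z_aspect, min_separation = min_separation,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' The standard benchmark scene
#'
#' 60 droplets of radius 2-6 px over 12 slices of 512 x 512, intensities
#' log-uniform between 3 and 20 times the background, read-noise sd of one
#' fifth of the background — the fixed conditions under which detector
#' recall, precision and the benefit of iteration are asserted.
#'
#' @param seed Integer seed (default 101).
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
benchmark_spec <- function(seed = 101L, ...) {
  synthetic_spec(seed = seed, ...)
}

with_preserved_rng <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic stack with ground truth
#'
#' Renders the tissue disc, plants each droplet on its spanned slices,
#' applies the per-slice PSF blur, adds noise, and quantizes to the spec's
#' bit depth. Identical specs (including seed) render bitwise-identical
#' stacks. Droplet centers are rejection-sampled to lie inside the tissue
#' with a margin and at least `min_separation` apart, so planted objects
#' are individually resolvable.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `stack` (an [image_stack()]) and `truth` (tibble, one
#'   row per droplet: `id`, `central_slice`, `center_y`, `center_x`,
#'   `radius`, `peak_intensity`, `first_slice`, `last_slice`,
#'   `n_slices_spanned`, `area_px_central`).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_preserved_rng(spec$seed, render_stack(spec))
}

render_stack <- function(spec) {
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  tis <- (yy - spec$tissue_center[1])^2 + (xx - spec$tissue_center[2])^2 <=
    spec$tissue_radius^2
  # sample droplets
  K <- spec$n_droplets
  radii <- stats::runif(K, spec$radius_range[1], spec$radius_range[2])
  intens <- exp(stats::runif(K, log(spec$intensity_range[1]),
                             log(spec$intensity_range[2])))
  margin <- radii + 3 * spec$psf_sigma + 2
  if (any(margin >= spec$tissue_radius)) {
    stop("droplets cannot fit inside the tissue disc", call. = FALSE)
  }
  cys <- numeric(K); cxs <- numeric(K)
  for (i in seq_len(K)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (spec$tissue_radius - margin[i])
      cy <- spec$tissue_center[1] + rad * sin(ang)
      cx <- spec$tissue_center[2] + rad * cos(ang)
      if (i == 1 || all((cys[seq_len(i - 1)] - cy)^2 +
                        (cxs[seq_len(i - 1)] - cx)^2 >=
                        spec$min_separation^2)) {
        cys[i] <- cy; cxs[i] <- cx; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place droplets at the requested separation",
                  call. = FALSE)
  }
  czs <- if (K > 0) sample.int(nz, K, replace = TRUE) - 1L else integer()
  # render scene (clean, double precision), slice by slice
  scene <- lapply(seq_len(nz) - 1L, function(z) {
    sl <- matrix(spec$background, ny, nx)
    sl[tis] <- spec$tissue_level
    sl
  })
  first_sl <- rep(NA_integer_, K); last_sl <- rep(NA_integer_, K)
  area_central <- rep(NA_integer_, K)
  for (i in seq_len(K)) {
    span <- floor((radii[i] - 1e-9) / spec$z_aspect)
    for (dz in -span:span) {
      z <- czs[i] + dz
      if (z < 0 || z >= nz) next
      rz <- sqrt(radii[i]^2 - (dz * spec$z_aspect)^2)
      dmask <- (yy - cys[i])^2 + (xx - cxs[i])^2 <= rz^2
      if (!any(dmask)) next
      sl <- scene[[z + 1L]]
      sl[dmask] <- pmax(sl[dmask], intens[i])
      scene[[z + 1L]] <- sl
      first_sl[i] <- min(first_sl[i], z, na.rm = TRUE)
      last_sl[i] <- max(last_sl[i], z, na.rm = TRUE)
      if (dz == 0) area_central[i] <- sum(dmask)
    }
  }
  vmax <- 2^spec$bit_depth - 1
  vox <- array(0L, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) {
    sl <- smooth_slice(scene[[z]], spec$psf_sigma)
    if (spec$poisson) sl <- stats::rpois(length(sl), lambda = sl)
    if (spec$noise_sd > 0) sl <- sl + stats::rnorm(length(sl), 0, spec$noise_sd)
    vox[z, , ] <- pmin(pmax(round(sl), 0), vmax)
  }
  truth <- tibble::tibble(
    id = seq_len(K), central_slice = czs, center_y = cys, center_x = cxs,
    radius = radii, peak_intensity = intens,
    first_slice = first_sl, last_slice = last_sl,
    n_slices_spanned = last_sl - first_sl + 1L,
    area_px_central = area_central
  )
  list(stack = image_stack(vox, bit_depth = spec$bit_depth), truth = truth)
}

#' Score detections against planted ground truth
#'
#' Greedy nearest-centroid matching between retained detections and truth
#' records: candidate pairs within `tol` pixels (lateral distance) are
#' accepted in order of increasing distance, each detection and each truth
#' record used at most once. Precision is the matched fraction of
#' detections (1 for an empty detection set, by convention), recall the
#' matched fraction of truth.
#'
#' @param particles Particle tibble (rows with `kept_after_dedup = FALSE`
#'   are ignored) or an `ld_detection`.
#' @param truth Truth tibble from [generate_stack()].
#' @param tol Matching tolerance in pixels (> 0).
#' @return A list of class `ld_eval`: `metrics` (one-row tibble: precision,
#'   recall, f1, n_detected, n_truth, n_matched,
#'   mean_abs_size_error_px2), `decile_recall` (recall within deciles of
#'   truth peak intensity; decile 1 is the dimmest), and `matches`.
#' @export
match_and_score <- function(particles, truth, tol = 4) {
  stopifnot(tol > 0)
  if (inherits(particles, "ld_detection")) particles <- particles$particles
  kept <- particles[particles$kept_after_dedup %||% TRUE, , drop = FALSE]
  nd <- nrow(kept); nt <- nrow(truth)
  pairs <- if (nd > 0 && nt > 0) {
    d2 <- outer(kept$centroid_y, truth$center_y, "-")^2 +
      outer(kept$centroid_x, truth$center_x, "-")^2
    idx <- which(d2 <= tol^2, arr.ind = TRUE)
    tibble::tibble(det = idx[, 1], truth_id = truth$id[idx[, 2]],
                   dist = sqrt(d2[idx]))
  } else {
    tibble::tibble(det = integer(), truth_id = integer(), dist = numeric())
  }
  pairs <- pairs[order(pairs$dist, pairs$truth_id, pairs$det), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  keep <- logical(nrow(pairs))
  ti <- match(pairs$truth_id, truth$id)
  for (i in seq_len(nrow(pairs))) {
    if (!used_d[pairs$det[i]] && !used_t[ti[i]]) {
      keep[i] <- TRUE
      used_d[pairs$det[i]] <- TRUE
      used_t[ti[i]] <- TRUE
    }
  }
  matches <- pairs[keep, , drop = FALSE]
  nm <- nrow(matches)
  precision <- if (nd == 0) 1 else nm / nd
  recall <- if (nt == 0) 1 else nm / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  size_err <- if (nm > 0) {
    mean(abs(kept$area_px[matches$det] -
               truth$area_px_central[match(matches$truth_id, truth$id)]))
  } else NA_real_
  decile <- if (nt > 0) {
    truth$decile <- dplyr::ntile(truth$peak_intensity, 10)
    truth$matched <- truth$id %in% matches$truth_id
    truth |>
      dplyr::group_by(.data$decile) |>
      dplyr::summarise(n = dplyr::n(), recall = mean(.data$matched),
                       .groups = "drop")
  } else {
    tibble::tibble(decile = integer(), n = integer(), recall = numeric())
  }
  structure(
    list(metrics = tibble::tibble(
           precision = precision, recall = recall, f1 = f1,
           n_detected = nd, n_truth = nt, n_matched = nm,
           mean_abs_size_error_px2 = size_err),
         decile_recall = decile, matches = matches),
    class = "ld_eval"
  )
}

#' @export
print.ld_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<ld_eval> precision %.3f, recall %.3f, F1 %.3f (%d detected / %d planted)\n",
    m$precision, m$recall, m$f1, m$n_detected, m$n_truth))
  invisible(x)
}
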
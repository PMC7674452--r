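#' Confocal image stack
#'
#' Lightweight container for an ordered sequence of 2-D grayscale optical
#' sections. Voxels are stored as a 3-D array in `(z, y, x)` order with the
#' origin at the top-left corner of slice 0; all coordinates reported by the
#' package are 0-based.
#'
#' @param voxels Numeric 3-D array in `(z, y, x)` order, or a single 2-D
#'   matrix (`y` by `x`) which is treated as a one-slice stack. Intensities
#'   must be non-negative integers within the range of `bit_depth`.
#' @param bit_depth Either 8 or 16. If `NULL`, the smallest of the two that
#'   accommodates the data is used.
#' @param pixel_size_xy Optional lateral pixel size in micrometres per pixel.
#' @param z_step Optional axial distance between consecutive slices (um).
#' @param source_path Optional path the stack was read from.
#'
#' @return An object of class `image_stack`: a list with elements `voxels`,
#'   `bit_depth`, `pixel_size_xy`, `z_step` and `source_path`.
#' @export
image_stack <- function(voxels, bit_depth = NULL, pixel_size_xy = NULL,
                        z_step = NULL, source_path = NA_character_) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a (z, y, x) array or a single 2-D matrix",
         call. = FALSE)
  }
  if (dim(voxels)[1] < 1L) stop("stack must have at least one slice", call. = FALSE)
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("stack intensities must be finite", call. = FALSE)
  }
  if (any(voxels < 0)) stop("stack intensities must be non-negative", call. = FALSE)
  if (any(voxels != round(voxels))) {
    stop("stack intensities must be integer-valued", call. = FALSE)
  }
  if (is.null(bit_depth)) bit_depth <- if (max(voxels) > 255) 16L else 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  if (max(voxels) > 2^bit_depth - 1) {
    stop("intensities exceed the range of the stated bit depth", call. = FALSE)
  }
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, bit_depth = bit_depth,
         pixel_size_xy = pixel_size_xy, z_step = z_step,
         source_path = source_path),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d slice(s), %d x %d px, %d-bit\n",
              d[1], d[2], d[3], x$bit_depth))
  if (!is.null(x$pixel_size_xy)) {
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size_xy))
  }
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[1]

#' Extract one slice of a stack as a matrix
#'
#' @param stack An [image_stack()].
#' @param z 0-based slice index.
#' @return A `y` by `x` numeric matrix.
#' @export
get_slice <- function(stack, z) {
  stopifnot(z >= 0, z < n_slices(stack))
  stack$voxels[z + 1L, , ]
}

#' Region-of-interest mask
#'
#' A binary mask congruent with a stack, restricting where particles are
#' detected and providing the denominator of particle density. A 2-D mask is
#' broadcast across all slices.
#'
#' @param mask Logical 3-D `(z, y, x)` array or 2-D `(y, x)` matrix.
#' @param origin One of `"auto"` (computed by [delineate_roi()]), `"file"`
#'   (user-supplied image) or `"full-frame"` (fallback covering every pixel).
#' @param n_z Number of slices to broadcast a 2-D mask over (ignored for 3-D
#'   input).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, origin = c("auto", "file", "full-frame"), n_z = NULL) {
  origin <- match.arg(origin)
  if (is.matrix(mask)) {
    if (is.null(n_z)) n_z <- 1L
    mask <- aperm(array(mask, dim = c(nrow(mask), ncol(mask), n_z)), c(3, 1, 2))
  }
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a (z, y, x) array or 2-D matrix", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask) && origin != "full-frame") {
    stop("ROI mask has no true pixels", call. = FALSE)
  }
  structure(list(mask = mask, origin = origin), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<roi_mask> origin '%s', %d slice(s), %d x %d px, %d true px\n",
              x$origin, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

full_frame_mask <- function(stack) {
  d <- dim(stack$voxels)
  roi_mask(array(TRUE, dim = d), origin = "full-frame")
}

# Mask slice as (y, x) logical matrix, 0-based z.
mask_slice <- function(roi, z) roi$mask[z + 1L, , ]

check_congruent <- function(stack, roi) {
  if (!identical(dim(stack$voxels), dim(roi$mask))) {
    stop("ROI mask dimensions do not match the stack", call. = FALSE)
  }
  invisible(TRUE)
}
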
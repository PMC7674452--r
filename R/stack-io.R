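#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages become slices in order; integer sample values are preserved exactly
#' (no rescaling). The lateral pixel size is taken from the TIFF resolution
#' tags when present ("inch" and "cm" units are converted to micrometres; a
#' bare resolution with no unit is interpreted as pixels per micrometre, the
#' common convention of microscopy exports), otherwise left unset.
#'
#' @param path Path to a TIFF file (single- or multi-page).
#' @param channel For multichannel images, 1-based index of the channel to
#'   keep. Multichannel input without `channel` is an error: silently picking
#'   a channel is a reproducibility hazard.
#' @param pixel_size_xy Optional explicit pixel size (um/px) overriding any
#'   resolution tag.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel = NULL, pixel_size_xy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("could not read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  bits <- attr(first, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(first) > 255) 16L else 8L
  res_ps <- pixel_size_from_info(first)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (is.null(channel)) {
        stop("multichannel image: supply `channel` (or --channel) to select ",
             "a single channel", call. = FALSE)
      }
      if (channel < 1 || channel > dim(p)[3]) {
        stop("channel index out of range", call. = FALSE)
      }
      p <- p[, , channel]
    }
    if (!is.integer(p)) {
      # float sample format: values in [0,1]; map onto the integer range
      p <- round(p * (2^bits - 1))
    }
    attributes(p) <- list(dim = dim(p))
    p
  })
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all pages must share identical dimensions", call. = FALSE)
  }
  vox <- aperm(array(unlist(pages), dim = c(dims[1, 1], dims[2, 1], length(pages))),
               c(3, 1, 2))
  image_stack(vox, bit_depth = bits,
              pixel_size_xy = pixel_size_xy %||% res_ps,
              source_path = path)
}

pixel_size_from_info <- function(page) {
  xres <- attr(page, "x.resolution")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- attr(page, "resolution.unit")
  if (is.null(unit)) unit <- "none"
  switch(unit,
         inch = 25400 / xres,
         cm   = 10000 / xres,
         1 / xres)
}

#' Write an image stack to a multi-page TIFF
#'
#' Voxels are written losslessly at the stack's bit depth; a stack written
#' and re-read is bitwise identical.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  scale <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(n_slices(stack)) - 1L,
                  function(z) get_slice(stack, z) / scale)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth),
                 error = function(e) stop("could not write TIFF '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a binary ROI mask image
#'
#' Nonzero pixels are inside the ROI. A single-page mask is broadcast across
#' all slices of the stack; a multi-page mask must match the slice count.
#'
#' @param path Path to a TIFF mask.
#' @param stack The [image_stack()] the mask applies to.
#' @return A [roi_mask()] with origin `"file"`.
#' @export
read_mask <- function(path, stack) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    attributes(p) <- list(dim = dim(p))
    p != 0
  })
  d <- dim(stack$voxels)
  if (nrow(pages[[1]]) != d[2] || ncol(pages[[1]]) != d[3]) {
    stop("mask dimensions (", nrow(pages[[1]]), " x ", ncol(pages[[1]]),
         ") do not match the stack (", d[2], " x ", d[3], ")", call. = FALSE)
  }
  if (length(pages) == 1L) {
    roi_mask(pages[[1]], origin = "file", n_z = d[1])
  } else {
    if (length(pages) != d[1]) {
      stop("mask page count does not match the stack slice count", call. = FALSE)
    }
    vox <- aperm(array(unlist(pages), dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    roi_mask(vox, origin = "file")
  }
}

#' Write an ROI mask as a TIFF
#'
#' @param roi A [roi_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(roi, path) {
  d <- dim(roi$mask)
  pages <- lapply(seq_len(d[1]), function(z) (roi$mask[z, , ]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

particle_csv_columns <- c(
  "brain_id", "slice", "iteration", "centroid_x", "centroid_y",
  "area_px", "area_um2", "perimeter_px", "circularity",
  "mean_intensity", "max_intensity", "kept_after_dedup"
)

#' Write a particle table to CSV
#'
#' Columns follow a fixed contract (`brain_id, slice, iteration, centroid_x,
#' centroid_y, area_px, area_um2, perimeter_px, circularity, mean_intensity,
#' max_intensity, kept_after_dedup`); rows are ordered by slice, then
#' centroid y, then centroid x, so identical inputs yield byte-identical
#' files. Coordinates are 0-based; `area_um2` is left empty when no pixel
#' size is known.
#'
#' @param particles Particle tibble as produced by [iterative_detect()] or
#'   [detect_droplets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path) {
  df <- as.data.frame(particles)
  for (col in particle_csv_columns) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "kept_after_dedup") TRUE else NA
    }
  }
  df <- df[order(df$slice, df$centroid_y, df$centroid_x), particle_csv_columns,
           drop = FALSE]
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'",
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a particle CSV written by [write_particles()]
#'
#' @param path Path to the CSV.
#' @return A tibble with the particle-table columns.
#' @export
read_particles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(particle_csv_columns, names(df))
  if (length(missing)) {
    stop("not a particle table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$brain_id <- as.character(df$brain_id)
  df$kept_after_dedup <- as.logical(df$kept_after_dedup)
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
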
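#' Kapur maximum-entropy threshold of a 256-bin histogram
#'
#' Implements the Kapur-Sahoo-Wong criterion: the returned threshold `t`
#' (0-based bin index) maximizes the sum of the Shannon entropies of the
#' background class (bins `0..t`) and the foreground class (bins
#' `t+1..n-1`), each normalized to its own class probability. Foreground
#' pixels are those falling in bins strictly above `t`. Empty-class
#' thresholds are inadmissible; `0 * log(0)` is taken as 0; entropies use the
#' natural logarithm (the base only rescales both entropies and cannot move
#' the argmax). Ties are broken toward the smallest `t`, which favors an
#' inclusive foreground and keeps the result deterministic.
#'
#' @param counts Integer vector of bin counts (length >= 2, conventionally
#'   256).
#' @return 0-based threshold bin index (integer in `0 .. length(counts)-2`).
#'   With fewer than two populated bins no class split exists and a
#'   `dropletquant_degenerate_histogram` error is signalled; callers treat
#'   the corresponding slice as particle-free.
#' @export
max_entropy_threshold <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L || anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be a non-negative count vector", call. = FALSE)
  }
  if (sum(counts > 0) < 2L) {
    stop(degenerate_histogram_error())
  }
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  w0 <- cumsum(p)
  s0 <- cumsum(plogp)
  s_tot <- sum(plogp)
  t <- seq_len(length(counts) - 1L)    # candidate: bins 1..n-1 (1-based)
  w1 <- 1 - w0[t]
  s1 <- s_tot - s0[t]
  h <- ifelse(w0[t] > 0 & w1 > 0,
              log(w0[t]) - s0[t] / w0[t] + log(w1) - s1 / w1,
              -Inf)
  as.integer(which.max(h) - 1L)
}

degenerate_histogram_error <- function() {
  structure(
    class = c("dropletquant_degenerate_histogram", "error", "condition"),
    list(message = "degenerate histogram: fewer than two populated bins",
         call = NULL)
  )
}

#' Bin intensity values into a fixed-width histogram
#'
#' Bins span the observed min-max range of `values` so that 8- and 16-bit
#' data (and real-valued smoothed images) are treated uniformly with 256
#' bins, mirroring the histogramming convention of common image-analysis
#' platforms.
#'
#' @param values Numeric vector (e.g. within-ROI pixel values).
#' @param bins Number of bins (default 256).
#' @return A list with `counts` (length `bins`), `lo`, `hi`, `width`. When
#'   all values are equal (`lo == hi`) the histogram is degenerate: all mass
#'   in one bin.
#' @export
bin_histogram <- function(values, bins = 256L) {
  if (length(values) == 0L) stop("no values to histogram", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    counts <- c(length(values), rep(0L, bins - 1L))
    return(list(counts = counts, lo = lo, hi = hi, width = 0))
  }
  width <- (hi - lo) / bins
  idx <- pmin(bins - 1L, floor((values - lo) / width))
  list(counts = tabulate(idx + 1L, nbins = bins), lo = lo, hi = hi,
       width = width)
}

# Intensity cutoff for threshold bin t: a value is foreground iff it falls
# in a bin > t, i.e. value >= lo + (t+1)*width.
threshold_cutoff <- function(hist, t) hist$lo + (t + 1) * hist$width

#' Triangle threshold of a histogram
#'
#' Geometric method for unimodal, skewed histograms: a line is drawn from
#' the histogram peak to the far end of the longer tail, and the threshold
#' is the bin maximizing the perpendicular distance between the histogram
#' and that line. Used for tissue/background separation in
#' [delineate_roi()], where the split is unimodal-skewed and entropy-based
#' thresholds are less robust.
#'
#' @param counts Bin counts.
#' @return 0-based threshold bin index.
#' @export
triangle_threshold <- function(counts) {
  counts <- as.numeric(counts)
  nz <- which(counts > 0)
  if (length(nz) < 2L) stop(degenerate_histogram_error())
  peak <- which.max(counts)
  lo_end <- nz[1]
  hi_end <- nz[length(nz)]
  # choose the longer tail; flip so the tail is to the right of the peak
  flip <- (peak - lo_end) > (hi_end - peak)
  if (flip) {
    counts <- rev(counts)
    n <- length(counts)
    peak <- n - peak + 1L
    hi_end <- n - lo_end + 1L
  }
  if (hi_end <= peak) return(as.integer(peak - 1L))
  xs <- peak:hi_end
  # signed vertical gap below the line through (peak, h_peak) and (hi_end, 0);
  # the threshold sits where the histogram sags furthest under that line
  line_y <- counts[peak] * (hi_end - xs) / (hi_end - peak)
  d <- line_y - counts[xs]
  t <- xs[which.max(d)]
  if (flip) t <- length(counts) - t + 1L
  as.integer(t - 1L)
}
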
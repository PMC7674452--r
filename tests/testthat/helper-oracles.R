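# Independent oracles, deliberately written as direct transcriptions of the
# definitions rather than sharing any code path with the package.

# Kapur criterion by exhaustive scan: for every admissible threshold t,
# compute both class entropies directly from the normalized class
# distributions and return the argmax (first, i.e. smallest t, on ties).
kapur_brute <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  best_h <- -Inf
  best_t <- NA_integer_
  for (t in 0:(n - 2)) {
    p0 <- p[1:(t + 1)]
    p1 <- p[(t + 2):n]
    w0 <- sum(p0)
    w1 <- sum(p1)
    if (w0 <= 0 || w1 <= 0) next
    q0 <- p0[p0 > 0] / w0
    q1 <- p1[p1 > 0] / w1
    h <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (h > best_h) {
      best_h <- h
      best_t <- t
    }
  }
  best_t
}

# Doublet clustering by naive pairwise closure, then keep-largest with the
# slice / y / x tie-break.
dedup_brute <- function(df, link_radius, max_z_gap) {
  n <- nrow(df)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (cl[i] != cl[j] &&
            abs(df$slice[i] - df$slice[j]) <= max_z_gap &&
            (df$centroid_y[i] - df$centroid_y[j])^2 +
              (df$centroid_x[i] - df$centroid_x[j])^2 <= link_radius^2) {
          cl[cl == cl[j]] <- cl[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- logical(n)
  for (cc in unique(cl)) {
    idx <- which(cl == cc)
    o <- idx[order(-df$area_px[idx], df$slice[idx],
                   df$centroid_y[idx], df$centroid_x[idx])]
    keep[o[1]] <- TRUE
  }
  keep
}

random_particle_set <- function(seed, n = 30) {
  set.seed(seed)
  tibble::tibble(
    brain_id = "rand",
    slice = sample(0:5, n, replace = TRUE),
    iteration = 1L,
    centroid_y = round(stats::runif(n, 0, 40), 2),
    centroid_x = round(stats::runif(n, 0, 40), 2),
    area_px = sample(4:200, n, replace = TRUE),
    area_um2 = NA_real_,
    perimeter_px = 10,
    circularity = 0.9,
    mean_intensity = 50,
    max_intensity = 80,
    kept_after_dedup = TRUE
  )
}

random_histogram <- function(seed) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) {
    counts <- stats::rpois(256, lambda = stats::runif(1, 0.5, 50))
  } else if (kind == 1) {
    # bimodal: two gaussian-ish populations plus sparse tail
    counts <- tabulate(c(
      pmax(1, pmin(256, round(stats::rnorm(2000, 40, 10)))),
      pmax(1, pmin(256, round(stats::rnorm(300, 180, 25))))
    ), nbins = 256)
  } else {
    # sparse spiky histogram with many empty bins
    counts <- integer(256)
    idx <- sample.int(256, sample(5:40, 1))
    counts[idx] <- sample.int(500, length(idx), replace = TRUE)
  }
  if (sum(counts > 0) < 2) counts[c(10, 200)] <- c(5, 7)
  counts
}
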
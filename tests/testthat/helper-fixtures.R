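# Shared synthetic fixtures. The full benchmark scene is expensive, so it is
# generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small 4-slice scene with a wide droplet intensity range reaching down to
# just above the tissue level, so that the dimmest droplets are only found
# after the brightest have been erased.
small_spec <- function(seed = 7, ...) {
  synthetic_spec(shape = c(4L, 160L, 160L), n_droplets = 8L,
                 tissue_radius = 55, tissue_center = c(79.5, 79.5),
                 min_separation = 18, intensity_range = c(28, 240),
                 seed = seed, ...)
}

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    sim <- generate_stack(small_spec())
    det <- detect_droplets(sim$stack, brain_id = "small")
    .fixture_cache$small <- list(sim = sim, det = det)
  }
  .fixture_cache$small
}

# The standard benchmark: K = 60 droplets over 12 x 512 x 512, intensities
# 3-20x background, noise sd = background / 5, fixed seed.
bench_fixture <- function() {
  if (is.null(.fixture_cache$bench)) {
    sim <- generate_stack(benchmark_spec())
    det3 <- detect_droplets(sim$stack, brain_id = "bench")
    det1 <- detect_droplets(sim$stack,
                            config = detect_config(max_iterations = 1L),
                            brain_id = "bench")
    .fixture_cache$bench <- list(
      sim = sim, det3 = det3, det1 = det1,
      ev3 = match_and_score(det3, sim$truth, tol = 4),
      ev1 = match_and_score(det1, sim$truth, tol = 4)
    )
  }
  .fixture_cache$bench
}

# Deterministic flat-background test slice with two planted discs.
two_blob_slice <- function(bright = 200L, dim = 60L, n = 128L) {
  set.seed(7)
  img <- pmin(pmax(round(matrix(stats::rnorm(n * n, 10, 2), n, n)), 0), 255)
  yy <- row(img)
  xx <- col(img)
  img[(yy - 40)^2 + (xx - 40)^2 <= 16] <- bright
  img[(yy - 90)^2 + (xx - 90)^2 <= 16] <- dim
  img
}

digital_disc <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad + 1L
  cy <- r + pad + 1L
  outer(seq_len(n), seq_len(n), function(y, x) (y - cy)^2 + (x - cy)^2 <= r^2)
}
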
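test_that("gaussian smoothing preserves constants, identity and mass", {
  img <- matrix(7, 30, 30)
  expect_equal(smooth_slice(img, 2), img)            # constant unchanged
  set.seed(1)
  noisy <- matrix(runif(900), 30, 30)
  expect_identical(smooth_slice(noisy, 0), noisy)    # sigma 0 is identity
  impulse <- matrix(0, 41, 41)
  impulse[21, 21] <- 10
  out <- smooth_slice(impulse, 2)
  expect_equal(sum(out), 10, tolerance = 1e-6)       # normalized kernel
  # reflect boundary conserves total mass even at the border
  edge <- matrix(0, 20, 20)
  edge[1, 1] <- 5
  expect_equal(sum(smooth_slice(edge, 1.5)), 5, tolerance = 1e-9)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE   # touches only diagonally
  lab <- dropletquant:::label_components(m)
  expect_equal(max(lab), 1)
  m[5, 5] <- TRUE   # separate object
  expect_equal(max(dropletquant:::label_components(m)), 2)
})

test_that("extraction filters by area and ROI containment", {
  binary <- matrix(FALSE, 20, 30)
  binary[3:4, 3:5] <- TRUE          # area 6... make it 5: drop one pixel
  binary[4, 5] <- FALSE             # blob A: area 5
  binary[10:13, 10:12] <- TRUE      # blob B: area 12
  original <- matrix(50, 20, 30)
  roi <- matrix(TRUE, 20, 30)
  cfg <- detect_config(min_area = 6)
  got <- extract_particles(binary, original, roi, cfg, z = 0, iteration = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$area_px, 12L)
  expect_equal(got$mean_intensity, 50)

  # same scene, but the big blob's centroid falls outside the ROI
  roi2 <- roi
  roi2[8:15, 8:15] <- FALSE
  got2 <- extract_particles(binary, original, roi2, detect_config(min_area = 1),
                            z = 0, iteration = 1)
  expect_equal(nrow(got2), 1)       # only the small blob survives
  expect_equal(got2$area_px, 5L)

  none <- extract_particles(matrix(FALSE, 20, 30), original, roi, cfg,
                            z = 0, iteration = 1)
  expect_equal(nrow(none), 0)
})

test_that("full containment requires every pixel inside the ROI", {
  binary <- matrix(FALSE, 10, 10)
  binary[4:6, 4:6] <- TRUE
  original <- matrix(1, 10, 10)
  roi <- matrix(TRUE, 10, 10)
  roi[, 6:10] <- FALSE              # blob straddles the ROI edge
  cfg_cent <- detect_config(min_area = 1, containment = "centroid")
  cfg_full <- detect_config(min_area = 1, containment = "full")
  expect_equal(nrow(extract_particles(binary, original, roi, cfg_cent, 0, 1)), 1)
  expect_equal(nrow(extract_particles(binary, original, roi, cfg_full, 0, 1)), 0)
})

test_that("erasure touches exactly the particle pixels", {
  img <- matrix(100, 10, 10)
  expect_identical(erase_particles(img, dropletquant:::empty_particles(), 0), img)
  px <- cbind(c(2, 2, 3), c(2, 3, 2))
  out <- erase_particles(img, px, 0)
  expect_equal(sum(out == 0), 3)
  expect_equal(sum(out), 100 * 97)
})

test_that("brightest particles are found first, dimmer ones in later passes", {
  fx <- small_fixture()
  parts <- tidy(fx$det)
  kept <- parts[parts$kept_after_dedup, ]
  truth <- fx$sim$truth
  ev <- match_and_score(fx$det, truth, tol = 4)
  expect_equal(ev$metrics$recall, 1)
  expect_equal(ev$metrics$precision, 1)
  # the dimmest planted droplets only surface after the first pass
  m <- merge(as.data.frame(kept), as.data.frame(truth),
             by.x = c("slice"), by.y = c("central_slice"))
  first_pass <- kept[kept$iteration == 1, ]
  later_pass <- kept[kept$iteration > 1, ]
  expect_gt(nrow(later_pass), 0)
  expect_lt(max(later_pass$max_intensity), max(first_pass$max_intensity))
  # per-slice threshold sequences decrease after the first iteration
  thr <- fx$det$thresholds
  for (s in unique(thr$slice)) {
    tt <- thr$threshold[thr$slice == s & thr$status %in% c("ok", "no-particles")]
    if (length(tt) > 1) expect_true(all(diff(tt) < 0), info = paste("slice", s))
  }
})

test_that("particle pixel sets are disjoint across iterations of a slice", {
  fx <- small_fixture()
  parts <- fx$det$particles
  for (s in unique(parts$slice)) {
    px <- parts$pixels[parts$slice == s]
    keys <- unlist(lapply(px, function(m) m[, 1] * 1e5 + m[, 2]))
    expect_false(any(duplicated(keys)), info = paste("slice", s))
  }
})

test_that("an all-background stack yields no particles and stops early", {
  spec0 <- synthetic_spec(shape = c(3, 160, 160), n_droplets = 0,
                          tissue_radius = 60, tissue_center = c(79.5, 79.5),
                          seed = 5)
  sim0 <- generate_stack(spec0)
  det0 <- detect_droplets(sim0$stack)
  expect_equal(nrow(det0$particles), 0)
  # every slice terminates on its first iteration, via the degeneracy guards
  expect_true(all(det0$thresholds$iteration == 1))
  expect_true(all(det0$thresholds$status %in% c("saturated", "degenerate",
                                                "no-particles")))
})

test_that("detection is fully deterministic", {
  fx <- small_fixture()
  again <- detect_droplets(fx$sim$stack, brain_id = "small")
  expect_identical(tidy(again), tidy(fx$det))
  expect_identical(again$thresholds, fx$det$thresholds)
})

test_that("a uniform zero stack is handled as particle-free", {
  st <- image_stack(array(0L, dim = c(2, 32, 32)))
  det <- suppressWarnings(detect_droplets(st))
  expect_equal(nrow(det$particles), 0)
})
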
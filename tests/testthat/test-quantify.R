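test_that("circularity follows its closed form and conventions", {
  expect_equal(circularity(100, 40), 4 * pi * 100 / 1600, tolerance = 1e-12)
  expect_equal(round(circularity(100, 40), 4), 0.7854)
  # a continuous circle is exactly circular
  r <- 3.7
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  # clamped at 1, and single pixels (zero perimeter) are circular
  expect_equal(circularity(100, 10), 1)
  expect_equal(circularity(1, 0), 1)
})

test_that("a digital disc measures as nearly circular", {
  disc <- digital_disc(15L)
  idx <- which(disc, arr.ind = TRUE)
  per <- dropletquant:::trace_perimeter(idx[, 1], idx[, 2])
  circ <- circularity(sum(disc), per)
  expect_gte(circ, 0.85)
  expect_lte(circ, 1.0)
  # regression pin for the chain-code estimator on this fixture
  expect_equal(per, 98.9116882, tolerance = 1e-6)
  expect_equal(circ, 0.910669665, tolerance = 1e-7)
})

mk_kept <- function(areas, circs = NULL) {
  n <- length(areas)
  tibble::tibble(
    brain_id = "b", slice = rep(0L, n), iteration = 1L,
    centroid_y = seq_len(n), centroid_x = seq_len(n),
    area_px = as.integer(areas), area_um2 = NA_real_, perimeter_px = 10,
    circularity = circs %||% rep(0.9, n),
    mean_intensity = 1, max_intensity = 1, kept_after_dedup = TRUE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("summaries report density and surfaces as defined", {
  s <- summarize_droplets(mk_kept(rep(10, 50)), roi = 10000)
  expect_equal(s$n_particles, 50)
  expect_equal(s$density_per_px2, 5e-3)

  s2 <- summarize_droplets(mk_kept(c(30, 70)), roi = 1000)
  expect_equal(s2$total_surface_px2, 100)
  expect_equal(s2$mean_surface_px2, 50)

  empty <- summarize_droplets(mk_kept(numeric(0)), roi = 1000)
  expect_equal(empty$n_particles, 0)
  expect_equal(empty$density_per_px2, 0)
  expect_equal(empty$total_surface_px2, 0)
  expect_true(is.na(empty$circularity_mean))

  expect_error(summarize_droplets(mk_kept(10), roi = 0), "positive")
})

test_that("discarded doublets are excluded from summaries", {
  p <- mk_kept(c(10, 99))
  p$kept_after_dedup[2] <- FALSE
  s <- summarize_droplets(p, roi = 100)
  expect_equal(s$n_particles, 1)
  expect_equal(s$total_surface_px2, 10)
})

test_that("density is invariant to empty-mask padding slices", {
  mask <- array(FALSE, dim = c(4, 10, 10))
  mask[2, 3:7, 3:7] <- TRUE
  padded <- array(FALSE, dim = c(7, 10, 10))   # empty slices added around
  padded[4, 3:7, 3:7] <- TRUE
  p <- mk_kept(c(10, 12))
  expect_equal(summarize_droplets(p, roi_mask(mask))$density_per_px2,
               summarize_droplets(p, roi_mask(padded))$density_per_px2)
})

test_that("fold changes normalize to the control mean", {
  df <- tibble::tibble(
    brain_id = c("c1", "c2", "t1"),
    group = c("ctrl", "ctrl", "mut"),
    n_particles = c(8, 12, 25),
    total_surface_px2 = c(100, 300, 800)
  )
  fc <- fold_change(df, control = "ctrl",
                    metrics = c("n_particles", "total_surface_px2"))
  ctrl <- fc[fc$group == "ctrl", ]
  for (m in unique(ctrl$metric)) {
    expect_equal(mean(ctrl$fold_change[ctrl$metric == m]), 1)
  }
  expect_equal(fc$fold_change[fc$brain_id == "t1" & fc$metric == "n_particles"],
               2.5)   # 25 / mean(8, 12)
})

test_that("fold changes are scale equivariant", {
  df <- tibble::tibble(brain_id = letters[1:4],
                       group = c("ctrl", "ctrl", "mut", "mut"),
                       n_particles = c(5, 15, 30, 40))
  f1 <- fold_change(df, control = "ctrl", metrics = "n_particles")
  df2 <- dplyr::mutate(df, n_particles = n_particles * 17)
  f2 <- fold_change(df2, control = "ctrl", metrics = "n_particles")
  expect_equal(f1$fold_change, f2$fold_change)
})

test_that("an all-zero control is a normalization error", {
  df <- tibble::tibble(brain_id = c("c1", "t1"), group = c("ctrl", "mut"),
                       n_particles = c(0, 10))
  expect_error(fold_change(df, control = "ctrl", metrics = "n_particles"),
               "zero")
  expect_error(fold_change(df, control = "nope", metrics = "n_particles"),
               "empty")
})

test_that("total surface agrees with an independent recount of the table", {
  fx <- small_fixture()
  parts <- tidy(fx$det)
  s <- summarize_droplets(fx$det$particles, fx$det$roi)
  expect_equal(s$total_surface_px2,
               sum(parts$area_px[parts$kept_after_dedup]))
  expect_equal(s$n_particles, sum(parts$kept_after_dedup))
})
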
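delta_hist <- function(n_lo, n_hi, lo = 10, hi = 200)
  intensity_histogram(c(rep(lo, n_lo), rep(hi, n_hi)),
                      breaks = seq(lo - 0.5, hi + 0.5, by = 1))

test_that("moment-preserving threshold solves the two-delta cases", {
  # symmetric: p0 = 1/2, cut strictly between the deltas
  th <- moment_preserving_threshold(delta_hist(4, 4))
  expect_equal(attr(th, "p0"), 0.5, tolerance = 1e-12)
  expect_equal(c(attr(th, "z0"), attr(th, "z1")), c(10, 200), tolerance = 1e-9)
  expect_gt(as.numeric(th), 10); expect_lt(as.numeric(th), 200)
  # 3:1 mixture: p0 = 3/4, and the binarised below-fraction is 3/4
  th2 <- moment_preserving_threshold(delta_hist(6, 2))
  expect_equal(attr(th2, "p0"), 0.75, tolerance = 1e-12)
  x <- c(rep(10, 6), rep(200, 2))
  expect_equal(mean(x <= as.numeric(th2)), 0.75)
  expect_equal(as.numeric(th2), oracle_tsai_threshold(delta_hist(6, 2)))
})

test_that("threshold agrees with the brute-force p0 oracle on mixtures", {
  for (seed in c(2, 7, 19)) {
    set.seed(seed)
    x <- c(rnorm(3000, 30, 5), rnorm(1000, 160, 12))
    h <- intensity_histogram(x, bins = 256)
    th <- moment_preserving_threshold(h)
    expect_equal(attr(th, "p0"), oracle_tsai_p0(h), tolerance = 2e-4)
    expect_equal(as.numeric(th), oracle_tsai_threshold(h))
    expect_gt(as.numeric(th), 30); expect_lt(as.numeric(th), 160)
  }
})

test_that("degenerate histograms are refused", {
  expect_error(moment_preserving_threshold(intensity_histogram(rep(7, 10))),
               "degenerate")
})

test_that("thresholding uses a strict > comparison", {
  g <- voxel_geometry(c(2, 2, 1), 100, 100)
  vol <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_true(all(apply_threshold(vol, 0.5, g)$mask))     # below the minimum
  expect_false(any(apply_threshold(vol, 4, g)$mask))      # at the maximum
  m <- apply_threshold(vol, 2, g)                         # 2 itself truncated
  expect_identical(sum(m$mask), 2L)
  expect_identical(m$threshold_used, 2)
})

test_that("segmentation of a clean phantom recovers the truth mask", {
  ph <- test_phantom(so2 = 0.4, background = 5)
  vol800 <- cube_volume(ph$cube, 800)
  floor_mid <- (max(vol800[!ph$truth$vessel_mask]) +
                  min(vol800[ph$truth$vessel_mask])) / 2
  mask <- apply_threshold(vol800, floor_mid, ph$cube$geometry)
  expect_identical(mask$mask, ph$truth$vessel_mask)
})

test_that("vascular volume is count times voxel volume, exactly", {
  g <- default_geometry()                    # 80 x 80 x 50 um voxels
  one <- array(FALSE, c(2, 2, 2)); one[1] <- TRUE
  gm <- voxel_geometry(c(2, 2, 2), 80, 50)
  v1 <- vascular_volume(structure(list(mask = one, threshold_used = 0,
                                       geometry = gm), class = "vessel_mask"))
  expect_equal(v1$total_volume_mm3, 3.2e-4, tolerance = 1e-12)
  v0 <- vascular_volume(structure(list(mask = !one & FALSE, threshold_used = 0,
                                       geometry = gm), class = "vessel_mask"))
  expect_identical(v0$total_volume_mm3, 0)
  # inverting the volume formula at the printed healthy-control scale
  n <- round(115.6 / voxel_volume_mm3(g))
  expect_equal(n * voxel_volume_mm3(g), 115.6, tolerance = 1e-5)
})

test_that("raising the threshold never grows the segmentation", {
  set.seed(31)
  g <- voxel_geometry(c(8, 8, 8), 100, 100)
  vol <- array(rnorm(512, 50, 20), c(8, 8, 8))
  ths <- sort(runif(10, 0, 100))
  ns <- vapply(ths, function(t)
    vascular_volume(apply_threshold(vol, t, g))$n_voxels, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("the threshold depends on the histogram only, not voxel order", {
  set.seed(13)
  x <- c(rnorm(2000, 20, 4), rnorm(500, 90, 9))
  r <- range(x)
  h1 <- intensity_histogram(x, breaks = seq(r[1], r[2], length.out = 257))
  h2 <- intensity_histogram(sample(x), breaks = seq(r[1], r[2], length.out = 257))
  expect_identical(as.numeric(moment_preserving_threshold(h1)),
                   as.numeric(moment_preserving_threshold(h2)))
})

test_that("mean over fingers handles missing digits explicitly", {
  expect_equal(mean_over_fingers(rep(117.2, 8)), 117.2)
  expect_warning(m <- mean_over_fingers(c(100, NA, 140, NA, NA, NA, NA, NA)),
                 "6 missing")
  expect_equal(m, 120)
  expect_error(mean_over_fingers(rep(NA_real_, 8)), "all fingers missing")
  expect_error(mean_over_fingers(numeric(0)), "no finger")
})

test_that("moment threshold recovers phantom vessel volume end to end", {
  # reduced field of view at the native 80/50 um spacing, then 2x coarser
  run <- function(g) {
    v <- vessel_spec(c(0, 3.2, 1.5), c(g$extent_mm[1], 3.2, 1.5), 0.6,
                     hb = 0.6, hbo2 = 0.4)
    ph <- make_finger_phantom(phantom_spec(
      g, list(v), wavelengths = c(700, 800),
      fluence_decay_constant = 0, noise_sigma = 3, seed = 2))
    vol800 <- cube_volume(ph$cube, 800)
    th <- moment_preserving_threshold(intensity_histogram(vol800))
    est <- vascular_volume(apply_threshold(vol800, th, g))$total_volume_mm3
    abs(est - ph$truth$total_vessel_volume_mm3) /
      ph$truth$total_vessel_volume_mm3
  }
  expect_lt(run(voxel_geometry(c(80, 80, 60), 80, 50)), 0.05)
  expect_lt(run(voxel_geometry(c(40, 40, 30), 160, 100)), 0.10)
})
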
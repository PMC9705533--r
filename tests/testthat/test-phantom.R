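test_that("vessel and phantom specs enforce their invariants", {
  expect_error(vessel_spec(c(0, 0, 0), c(1, 0, 0), 0), "radius")
  expect_error(vessel_spec(c(0, 0, 0), c(1, 0, 0), 1, hb = 0, hbo2 = 0),
               "not both zero")
  v <- vessel_spec(c(0, 0, 0), c(1, 0, 0), 1, hb = 1, hbo2 = 3)
  expect_equal(v$true_so2, 0.75)
  g <- voxel_geometry(c(10, 10, 10), 500, 500)
  expect_error(phantom_spec(g, wavelengths = c(500, 700)), "range")
  expect_error(phantom_spec(g, wavelengths = c(800, 700)), "increasing")
  expect_error(phantom_spec(g, noise_sigma = -1), ">= 0")
  expect_error(voxel_geometry(c(0, 5, 5)), ">= 1")
  expect_error(voxel_geometry(c(5, 5, 5), lateral_um = 0), "positive")
})

test_that("noiseless in-vessel spectra follow the extinction mixture", {
  # ratio of intensities at two wavelengths equals the extinction-mixture
  # ratio when fluence decay, background and noise are all off
  ph <- test_phantom(so2 = 0.38, fluence = 0)
  A <- build_design_matrix(c(700, 850))
  mix <- unname(log(10) * (A[, "eps_hb"] * 0.62 + A[, "eps_hbo2"] * 0.38))
  iv <- ph$truth$vessel_mask
  i700 <- ph$cube$intensities[, , , 1][iv]
  i850 <- ph$cube$intensities[, , , 5][iv]
  expect_equal(i700 / i850, rep(mix[1] / mix[2], sum(iv)), tolerance = 1e-12)
})

test_that("empty phantom is background plus noise with zero vessel volume", {
  g <- voxel_geometry(c(12, 12, 8), 500, 500)
  ph <- make_finger_phantom(phantom_spec(g, list(), background_level = 5,
                                         noise_sigma = 0))
  expect_true(all(ph$cube$intensities == 5))
  expect_false(any(ph$truth$vessel_mask))
  expect_identical(ph$truth$total_vessel_volume_mm3, 0)
  expect_true(all(is.na(ph$truth$so2_map)))
})

test_that("ground truth is internally consistent", {
  ph <- test_phantom(so2 = 0.7)
  tr <- ph$truth
  expect_equal(tr$total_vessel_volume_mm3,
               sum(tr$vessel_mask) * voxel_volume_mm3(ph$cube$geometry))
  inside <- tr$vessel_mask
  expect_true(all(tr$so2_map[inside] >= 0 & tr$so2_map[inside] <= 1))
  expect_equal(unique(tr$so2_map[inside]), 0.7)
  expect_true(all(is.na(tr$so2_map[!inside])))
})

test_that("voxelised cylinder volume converges to pi r^2 L", {
  analytic <- pi * 0.5^2 * 10
  v <- vessel_spec(c(5, 10, 5), c(15, 10, 5), 0.5, 0.6, 0.4)
  err <- vapply(list(voxel_geometry(c(125, 125, 100), 160, 100),
                     default_geometry()), function(g) {
    ras <- rasterise_vessels(g, list(v))
    abs(sum(ras$mask) * voxel_volume_mm3(g) - analytic) / analytic
  }, numeric(1))
  expect_lt(err[2], 0.05)          # fine grid within 5%
  expect_lt(err[2], err[1] / 2)    # error halves (or better) on refinement
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- test_phantom(noise_sigma = 50, seed = 7)
  b <- test_phantom(noise_sigma = 50, seed = 7)
  c <- test_phantom(noise_sigma = 50, seed = 8)
  expect_identical(a$cube$intensities, b$cube$intensities)
  expect_false(identical(a$cube$intensities, c$cube$intensities))
})

test_that("noiseless unmixing inverts the forward model up to ln(10)", {
  # the forward model converts decadic extinction to absorption with a
  # ln(10) factor; the pure pseudo-inverse therefore recovers ln(10) * C
  for (so2 in c(0.2, 0.8)) {
    ph <- test_phantom(so2 = so2, fluence = 0)
    maps <- unmix_pseudo_inverse(ph$cube,
                                 build_design_matrix(ph$cube$wavelengths))
    ora <- oracle_lsq_unmix(ph$cube, build_design_matrix(ph$cube$wavelengths))
    expect_equal(c(maps$hb), unname(ora[, "hb"]), tolerance = 1e-10)
    expect_equal(maps$hb, log(10) * ph$truth$hb_map, tolerance = 1e-10)
    expect_equal(maps$hbo2, log(10) * ph$truth$hbo2_map, tolerance = 1e-10)
  }
})

test_that("occlusion series generator hits its landmarks", {
  ev <- occlusion_events(60, 180, 240)
  # degenerate flat series
  flat <- make_occlusion_series(0.38, 0.38, 0.38, ev, noise_sigma = 0)
  expect_true(all(flat$so2 == 0.38))
  # trough and peak attained exactly, noiseless
  s <- make_occlusion_series(0.377, 0.355, 0.382, ev, noise_sigma = 0)
  occ <- s$timestamp_s >= 60 & s$timestamp_s < 180
  rel <- s$timestamp_s >= 180
  expect_equal(min(s$so2[occ]), 0.355)
  expect_equal(max(s$so2[rel]), 0.382)
  expect_true(all(s$so2[s$timestamp_s < 60] == 0.377))
  # seeding contract
  n1 <- make_occlusion_series(0.377, 0.355, 0.382, ev, noise_sigma = 0.01, seed = 1)
  n2 <- make_occlusion_series(0.377, 0.355, 0.382, ev, noise_sigma = 0.01, seed = 1)
  n3 <- make_occlusion_series(0.377, 0.355, 0.382, ev, noise_sigma = 0.01, seed = 2)
  expect_identical(n1$so2, n2$so2)
  expect_false(identical(n1$so2, n3$so2))
  # window misconfiguration
  expect_error(occlusion_events(100, 80, 240), "contiguous")
  expect_error(make_occlusion_series(0.3, 0.35, 0.4, ev), "trough")
})

test_that("frame sequence generator crops the truth at constant steps", {
  set.seed(11)
  truth <- matrix(runif(30 * 400), 30, 400)
  expect_error(make_frame_sequence(truth, 5, frame_width = 10, step = 10),
               "overlap")
  expect_error(make_frame_sequence(truth, 60, frame_width = 50, step = 7),
               "extent")
  fs0 <- make_frame_sequence(truth, 4, frame_width = 20, step = 0)
  expect_true(all(vapply(fs0$frames, identical, TRUE, fs0$frames[[1]])))
  fs <- make_frame_sequence(truth, 40, frame_width = 50, step = 7)
  expect_identical(diff(fs$true_offsets), rep(7, 39))
  expect_identical(fs$frames[[3]], truth[, 15:64])
  # a 200-frame acquisition, the scale of a whole-finger scan
  long <- matrix(0, 5, 200 * 3 + 30)
  fs200 <- make_frame_sequence(long, 200, frame_width = 30, step = 3)
  expect_length(fs200$frames, 200)
})

test_that("phantom specs round trip through the JSON config", {
  g <- voxel_geometry(c(20, 22, 10), 300, 200)
  spec <- phantom_spec(g, list(vessel_spec(c(0, 3, 1), c(6, 3, 1), 0.7,
                                           hb = 0.5, hbo2 = 0.25)),
                       wavelengths = c(700, 800),
                       fluence_decay_constant = 0.3,
                       background_level = 2, noise_sigma = 1.5, seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$geometry$shape, spec$geometry$shape)
  expect_equal(back$wavelengths, spec$wavelengths)
  expect_equal(back$vessels[[1]]$radius_mm, 0.7)
  expect_equal(back$vessels[[1]]$true_so2, 1 / 3)
  a <- make_finger_phantom(spec); b <- make_finger_phantom(back)
  expect_identical(a$cube$intensities, b$cube$intensities)
})
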
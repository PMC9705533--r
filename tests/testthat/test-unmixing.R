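test_that("design matrix interpolates the bundled extinction table", {
  tab <- hb_extinction()
  # tabulated wavelengths are returned verbatim
  A <- build_design_matrix(c(700, 760, 850), tab)
  expect_equal(unname(A[, "eps_hb"]),
               tab$eps_hb[match(c(700, 760, 850), tab$wavelength_nm)])
  expect_equal(unname(A[, "eps_hbo2"]),
               tab$eps_hbo2[match(c(700, 760, 850), tab$wavelength_nm)])
  # midpoints are arithmetic means of the bracketing rows
  M <- build_design_matrix(c(705, 845), tab)
  expect_equal(unname(M[1, ]),
               c(mean(tab$eps_hb[tab$wavelength_nm %in% c(700, 710)]),
                 mean(tab$eps_hbo2[tab$wavelength_nm %in% c(700, 710)])))
  expect_error(build_design_matrix(c(600, 800)), "outside")
  expect_error(build_design_matrix(800), "at least 2")
})

test_that("the table crosses near 800 nm (isosbestic point)", {
  tab <- hb_extinction()
  d760 <- with(tab, eps_hb[wavelength_nm == 760] - eps_hbo2[wavelength_nm == 760])
  d850 <- with(tab, eps_hb[wavelength_nm == 850] - eps_hbo2[wavelength_nm == 850])
  expect_true(sign(d760) != sign(d850))
  iso <- isosbestic_wavelength(tab)
  expect_gt(iso, 780); expect_lt(iso, 820)
  Aiso <- build_design_matrix(c(700, iso), tab)
  expect_lt(abs(Aiso[2, "eps_hb"] - Aiso[2, "eps_hbo2"]) / Aiso[2, "eps_hb"],
            0.05)
})

test_that("pseudo-inverse unmixing solves constructed spectra exactly", {
  A <- build_design_matrix(c(700, 730, 760, 800, 850))
  g <- voxel_geometry(c(2, 1, 1), 100, 100)
  # voxel 1: spectrum = A (2,3) exactly; voxel 2: all-zero spectrum
  specs <- rbind(as.vector(A %*% c(2, 3)), rep(0, 5))
  cube <- msot_cube(array(specs, c(2, 1, 1, 5)), g,
                    c(700, 730, 760, 800, 850))
  maps <- unmix_pseudo_inverse(cube, A)
  expect_equal(maps$hb[1, 1, 1], 2, tolerance = 1e-10)
  expect_equal(maps$hbo2[1, 1, 1], 3, tolerance = 1e-10)
  expect_lt(maps$residual[1, 1, 1], 1e-9)
  expect_identical(c(maps$hb[2, 1, 1], maps$hbo2[2, 1, 1],
                     maps$residual[2, 1, 1]), c(0, 0, 0))
})

test_that("orthogonal perturbations land in the residual, not the solution", {
  A <- build_design_matrix(c(700, 730, 760, 800, 850))
  base <- as.vector(A %*% c(1, 1))
  # perturbation orthogonal to the column space
  Q <- qr.Q(qr(A), complete = TRUE)[, 3:5]
  pert <- as.vector(Q %*% c(3, -2, 1))
  expect_lt(max(abs(crossprod(A, pert))), 1e-9)
  g <- voxel_geometry(c(1, 1, 1), 100, 100)
  cube <- msot_cube(array(base + pert, c(1, 1, 1, 5)), g,
                    c(700, 730, 760, 800, 850))
  maps <- unmix_pseudo_inverse(cube, A)
  expect_equal(c(maps$hb, maps$hbo2), c(1, 1), tolerance = 1e-9)
  expect_equal(c(maps$residual), sqrt(sum(pert^2)), tolerance = 1e-9)
})

test_that("unmixing agrees with an independent least-squares oracle", {
  set.seed(42)
  A <- build_design_matrix(c(700, 730, 760, 800, 850))
  g <- voxel_geometry(c(10, 10, 10), 200, 200)
  cube <- msot_cube(array(abs(rnorm(5000, 100, 40)), c(10, 10, 10, 5)), g,
                    c(700, 730, 760, 800, 850))
  maps <- unmix_pseudo_inverse(cube, A)
  ora <- oracle_lsq_unmix(cube, A)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-6))
  expect_lt(rel(c(maps$hb), ora[, "hb"]), 1e-8)
  expect_lt(rel(c(maps$hbo2), ora[, "hbo2"]), 1e-8)
})

test_that("rank-deficient designs are refused with named columns", {
  bad <- cbind(eps_hb = c(1, 2, 3), eps_hbo2 = c(2, 4, 6))
  g <- voxel_geometry(c(2, 2, 1), 100, 100)
  cube <- msot_cube(array(1, c(2, 2, 1, 3)), g, c(700, 800, 850))
  expect_error(unmix_pseudo_inverse(cube, bad), "eps_hb and eps_hbo2")
  expect_error(unmix_pseudo_inverse(cube, bad[1:2, ]), "2 rows")
})

test_that("noise floor masking separates vessel from background", {
  ph <- test_phantom(so2 = 0.4, background = 10)
  maps <- unmix_pseudo_inverse(ph$cube, build_design_matrix(ph$cube$wavelengths))
  tot <- maps$hb + maps$hbo2
  # floor 0: every voxel with any signal valid (background gives signal too)
  expect_true(all(noise_floor_mask(maps, 0)))
  # saturating floor: empty mask
  expect_false(any(noise_floor_mask(maps, max(tot) + 1)))
  # floor between background and in-vessel totals recovers the truth mask
  floor_mid <- (max(tot[!ph$truth$vessel_mask]) +
                  min(tot[ph$truth$vessel_mask])) / 2
  expect_identical(noise_floor_mask(maps, floor_mid), ph$truth$vessel_mask)
  expect_error(noise_floor_mask(maps, -1), ">= 0")
})

test_that("sO2 follows the saturation ratio with clamping", {
  g <- voxel_geometry(c(2, 2, 1), 100, 100)
  maps <- structure(list(
    hb   = array(c(1, 0, 1, -2), c(2, 2, 1)),
    hbo2 = array(c(1, 2, 3, -1), c(2, 2, 1)),
    residual = array(0, c(2, 2, 1)), geometry = g),
    class = "chromophore_maps")
  om <- compute_so2(maps)
  expect_equal(c(om$so2[1, 1, 1], om$so2[2, 1, 1], om$so2[1, 2, 1]),
               c(0.5, 1.0, 0.75))
  # both clamped to zero: removed from the valid mask, sO2 undefined
  expect_false(om$valid_mask[2, 2, 1])
  expect_true(is.na(om$so2[2, 2, 1]))
  # pure deoxy voxel
  maps$hb[1, 1, 1] <- 4; maps$hbo2[1, 1, 1] <- 0
  expect_equal(compute_so2(maps)$so2[1, 1, 1], 0)
})

test_that("mean sO2 averages valid voxels and refuses empty masks", {
  ph <- test_phantom(so2 = 0.373, fluence = 0.25)
  maps <- unmix_pseudo_inverse(ph$cube, build_design_matrix(ph$cube$wavelengths))
  om <- compute_so2(maps, ph$truth$vessel_mask)
  expect_equal(mean_so2(om), 0.373, tolerance = 1e-6)
  # two-level mean
  g <- voxel_geometry(c(2, 1, 1), 100, 100)
  m2 <- structure(list(hb = array(c(7, 5), c(2, 1, 1)),
                       hbo2 = array(c(3, 5), c(2, 1, 1)),
                       residual = array(0, c(2, 1, 1)), geometry = g),
                  class = "chromophore_maps")
  expect_equal(mean_so2(compute_so2(m2)), 0.4)
  expect_error(mean_so2(compute_so2(m2), array(FALSE, c(2, 1, 1))),
               "no valid voxels")
})

test_that("sO2 is scale invariant; concentrations scale linearly", {
  ph <- test_phantom(so2 = 0.62, noise_sigma = 30, seed = 5)
  A <- build_design_matrix(ph$cube$wavelengths)
  m1 <- unmix_pseudo_inverse(ph$cube, A)
  scaled <- msot_cube(ph$cube$intensities * 7.5, ph$cube$geometry,
                      ph$cube$wavelengths)
  m2 <- unmix_pseudo_inverse(scaled, A)
  expect_equal(m2$hb, m1$hb * 7.5, tolerance = 1e-12)
  expect_equal(m2$hbo2, m1$hbo2 * 7.5, tolerance = 1e-12)
  o1 <- compute_so2(m1); o2 <- compute_so2(m2)
  expect_equal(o2$so2, o1$so2, tolerance = 1e-12)
  expect_identical(o1$valid_mask, o2$valid_mask)
})

test_that("outputs are invariant to wavelength-axis permutation", {
  ph <- test_phantom(so2 = 0.45, noise_sigma = 20, seed = 3)
  A <- build_design_matrix(ph$cube$wavelengths)
  perm <- c(3, 1, 5, 2, 4)
  permuted <- ph$cube
  permuted$intensities <- ph$cube$intensities[, , , perm]
  m1 <- unmix_pseudo_inverse(ph$cube, A)
  m2 <- unmix_pseudo_inverse(permuted, A[perm, ])
  expect_equal(m1$hb, m2$hb, tolerance = 1e-12)
  expect_equal(m1$hbo2, m2$hbo2, tolerance = 1e-12)
  expect_equal(m1$residual, m2$residual, tolerance = 1e-12)
})

test_that("auto noise floor is mean + 3 SD of the background region", {
  ph <- test_phantom(so2 = 0.4, noise_sigma = 15, seed = 9)
  maps <- unmix_pseudo_inverse(ph$cube, build_design_matrix(ph$cube$wavelengths))
  bg <- !ph$truth$vessel_mask
  fl <- auto_noise_floor(maps, bg)
  tot <- (maps$hb + maps$hbo2)[bg]
  expect_equal(fl, mean(tot) + 3 * sd(tot))
})
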
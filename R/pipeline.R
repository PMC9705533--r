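#' Reduced-size geometry for desk-scale pipeline demos
#'
#' Same physical 2 x 2 x 1 cm field of view as [default_geometry()] but on
#' a 48 x 48 x 32 grid, so a full synthetic cohort runs in minutes on one
#' CPU. Physical vessel volumes are grid-independent (up to voxelisation
#' error), so cohort comparisons are unaffected by the coarser grid.
#' @return A [voxel_geometry()].
#' @export
demo_geometry <- function() voxel_geometry(c(48L, 48L, 32L), 20000 / 48, 10000 / 32)

#' Single-finger analysis: volume and baseline oxygenation from one cube
#'
#' The per-cube analysis applied to every finger: (1) segment the 800 nm
#' (isosbestic, structural) volume with the moment-preserving histogram
#' threshold and convert the voxel count to mm^3; (2) unmix the
#' multispectral cube, mask to the noise floor, and average sO2 over the
#' valid voxels.
#'
#' @param cube an [msot_cube()] containing an 800 nm plane.
#' @param noise_floor absolute noise floor for [noise_floor_mask()], or
#'   `"auto"` to derive `mean + 3 SD` from `background_region`.
#' @param background_region logical array of known signal-free voxels
#'   (required for `"auto"`).
#' @param bins histogram bin count for the segmentation threshold.
#' @return List: `volume` (a `volume_result`), `mean_so2`, `threshold`,
#'   `noise_floor`.
#' @export
analyse_finger_cube <- function(cube, noise_floor = "auto",
                                background_region = NULL, bins = 256L) {
  stopifnot(inherits(cube, "msot_cube"))
  vol800 <- cube_volume(cube, 800)
  th <- moment_preserving_threshold(intensity_histogram(vol800, bins = bins))
  mask <- apply_threshold(vol800, th, cube$geometry)
  vres <- vascular_volume(mask)
  maps <- unmix_pseudo_inverse(cube, build_design_matrix(cube$wavelengths))
  if (identical(noise_floor, "auto")) {
    if (is.null(background_region))
      stop("noise_floor = 'auto' needs a background_region", call. = FALSE)
    noise_floor <- auto_noise_floor(maps, background_region)
  }
  omap <- compute_so2(maps, noise_floor_mask(maps, noise_floor))
  list(volume = vres, mean_so2 = mean_so2(omap),
       threshold = as.numeric(th), noise_floor = noise_floor)
}

# In-vessel signal scale at the cube's wavelengths for a vessel spec:
# used to express noise as a fraction of peak signal.
vessel_peak_signal <- function(vessel, wavelengths, depth_mm, k) {
  A <- build_design_matrix(wavelengths)
  max(log(10) * (A[, "eps_hb"] * vessel$hb + A[, "eps_hbo2"] * vessel$hbo2) *
        exp(-k * depth_mm))
}

#' Simulate and analyse a full synthetic cohort study
#'
#' Desk-scale, fully seeded emulation of the study design: `n_hc` healthy
#' controls and `n_ssc` SSc subjects (of which `n_ssc_isch` with a history
#' of severe digital ischaemia), eight fingers each. Every finger is a
#' two-artery phantom ([make_finger_phantom()]) pushed through the full
#' analysis ([analyse_finger_cube()]); an occlusion challenge
#' ([make_occlusion_series()] then [occlusion_metrics()]) is analysed for
#' a subset of subjects mirroring the study's data loss. SSc subjects have
#' their true sO2 shifted down by `so2_shift`; vascular volume is drawn
#' from a common distribution for both groups (the study found no volume
#' difference). Outputs are the three results-table-shaped comparisons:
#' vascular volume, baseline sO2 (both mean of 8 fingers), and the
#' occlusion baseline/minimum/maximum.
#'
#' @param n_hc,n_ssc,n_ssc_isch group sizes (defaults: the study's 32 HC,
#'   22 SSc including 6 with ischaemia history).
#' @param n_occ_hc,n_occ_ssc occlusion subset sizes (defaults 17 and 10).
#' @param so2_shift downward shift of true SSc sO2 (saturation units).
#' @param geometry phantom grid (default [demo_geometry()]).
#' @param seed integer master seed; everything derives from it.
#' @param noise_frac phantom noise SD as a fraction of peak vessel signal.
#' @param outdir optional directory: if given, cohort records, the three
#'   comparison tables and a run manifest are written there as CSV/JSON.
#' @return List with `records` (a [cohort_records()] table), `tables`
#'   (named list of `group_comparison` data.frames), and `files` (paths
#'   written, if any).
#' @export
run_demo_study <- function(n_hc = 32L, n_ssc = 22L,
                           n_ssc_isch = min(6L, n_ssc),
                           n_occ_hc = min(17L, n_hc),
                           n_occ_ssc = min(10L, n_ssc),
                           so2_shift = 0.008, geometry = demo_geometry(),
                           seed = 1L, noise_frac = 0.02, outdir = NULL) {
  groups <- c(rep("HC", n_hc), rep("SSc", n_ssc))
  subgroups <- c(rep("none", n_hc),
                 rep("SSc_isch", n_ssc_isch),
                 rep("SSc_no_isch", n_ssc - n_ssc_isch))
  ids <- sprintf("S%02d", seq_along(groups))
  ext <- geometry$extent_mm
  # background region for the auto noise floor: the deepest quarter of the
  # volume, below any vessel
  nz <- geometry$shape[3]
  bg <- array(FALSE, geometry$shape)
  bg[, , (nz - max(1, nz %/% 4) + 1):nz] <- TRUE

  rec <- list(); occ_rec <- list()
  for (s in seq_along(ids)) {
    sub_seed <- (seed * 1000L + s) %% .Machine$integer.max
    pars <- with_seed(sub_seed, list(
      so2 = min(0.95, max(0.05,
        stats::rnorm(1, 0.381, 0.009) - if (groups[s] == "SSc") so2_shift else 0)),
      radius = max(0.5, stats::rnorm(1, 0.96, 0.10)),
      finger_r_jit = stats::rnorm(8, 1, 0.03),
      finger_so2_jit = stats::rnorm(8, 0, 0.004),
      occ_jit = stats::rnorm(1, 0, 0.004)))
    for (f in 1:8) {
      so2_f <- min(0.95, max(0.05, pars$so2 + pars$finger_so2_jit[f]))
      r_f <- max(0.3, pars$radius * pars$finger_r_jit[f])
      vessels <- list(
        vessel_spec(c(0, ext[2] * 0.4, 4.0), c(ext[1], ext[2] * 0.4, 4.0),
                    r_f, hb = 1 - so2_f, hbo2 = so2_f),
        vessel_spec(c(0, ext[2] * 0.6, 5.0), c(ext[1], ext[2] * 0.6, 5.0),
                    r_f * 0.9, hb = 1 - so2_f, hbo2 = so2_f))
      k <- 0.25
      sigma <- noise_frac * vessel_peak_signal(vessels[[1]],
                                               c(700, 730, 760, 800, 850), 4.0, k)
      ph <- make_finger_phantom(phantom_spec(
        geometry, vessels, fluence_decay_constant = k,
        noise_sigma = sigma, seed = (sub_seed + f) %% .Machine$integer.max))
      res <- analyse_finger_cube(ph$cube, noise_floor = "auto",
                                 background_region = bg)
      rec[[length(rec) + 1]] <- data.frame(
        subject_id = ids[s], group = groups[s], subgroup = subgroups[s],
        finger = f,
        vascular_volume_mm3 = res$volume$total_volume_mm3,
        baseline_so2 = res$mean_so2)
    }
  }
  occ_idx <- c(seq_len(n_occ_hc), n_hc + seq_len(n_occ_ssc))
  for (s in occ_idx) {
    sub_seed <- (seed * 1000L + s) %% .Machine$integer.max
    jit <- with_seed(sub_seed + 500L, stats::rnorm(1, 0, 0.004))
    shift <- if (groups[s] == "SSc") c(0.001, 0.003, 0.003) else c(0, 0, 0)
    base <- 0.377 + jit - shift[1]
    trough <- 0.364 + jit - shift[2]
    peak <- 0.382 + jit - shift[3]
    ser <- make_occlusion_series(base, trough, peak,
                                 noise_sigma = 0.005,
                                 seed = (sub_seed + 900L) %% .Machine$integer.max)
    met <- occlusion_metrics(ser, attr(ser, "truth")$events)
    occ_rec[[length(occ_rec) + 1]] <- data.frame(
      subject_id = ids[s], group = groups[s], subgroup = subgroups[s],
      occlusion_baseline_so2 = met$baseline_so2,
      occlusion_min_so2 = met$min_so2,
      occlusion_max_so2 = met$max_so2)
  }
  finger_df <- do.call(rbind, rec)
  occ_df <- do.call(rbind, occ_rec)
  records <- rbind(
    cohort_records(finger_df$subject_id, finger_df$group,
                   "vascular_volume_mm3", finger_df$vascular_volume_mm3,
                   finger_df$finger, finger_df$subgroup),
    cohort_records(finger_df$subject_id, finger_df$group,
                   "baseline_so2", finger_df$baseline_so2,
                   finger_df$finger, finger_df$subgroup),
    cohort_records(occ_df$subject_id, occ_df$group,
                   "occlusion_baseline_so2", occ_df$occlusion_baseline_so2,
                   NA_integer_, occ_df$subgroup),
    cohort_records(occ_df$subject_id, occ_df$group,
                   "occlusion_min_so2", occ_df$occlusion_min_so2,
                   NA_integer_, occ_df$subgroup),
    cohort_records(occ_df$subject_id, occ_df$group,
                   "occlusion_max_so2", occ_df$occlusion_max_so2,
                   NA_integer_, occ_df$subgroup))
  class(records) <- c("cohort_records", "data.frame")
  tables <- list(
    vascular_volume = build_comparison_table(records, "vascular_volume_mm3"),
    baseline_so2 = build_comparison_table(records, "baseline_so2"),
    occlusion = do.call(rbind, lapply(
      c("occlusion_baseline_so2", "occlusion_min_so2", "occlusion_max_so2"),
      function(m) build_comparison_table(records, m))))
  class(tables$occlusion) <- c("group_comparison", "data.frame")
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(outdir, c("cohort_records.csv",
                                 "table2_vascular_volume.csv",
                                 "table3_baseline_so2.csv",
                                 "table4_occlusion.csv"))
    utils::write.csv(as.data.frame(records), files[1], row.names = FALSE)
    utils::write.csv(as.data.frame(tables$vascular_volume), files[2], row.names = FALSE)
    utils::write.csv(as.data.frame(tables$baseline_so2), files[3], row.names = FALSE)
    utils::write.csv(as.data.frame(tables$occlusion), files[4], row.names = FALSE)
    write_manifest(list(n_hc = n_hc, n_ssc = n_ssc, n_ssc_isch = n_ssc_isch,
                        n_occ_hc = n_occ_hc, n_occ_ssc = n_occ_ssc,
                        so2_shift = so2_shift, noise_frac = noise_frac,
                        shape = geometry$shape),
                   files, file.path(outdir, "manifest.json"), seed = seed)
    files <- c(files, file.path(outdir, "manifest.json"))
  }
  list(records = records, tables = tables, files = files)
}
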
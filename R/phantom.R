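#' Specify a cylindrical digital-artery segment
#'
#' A finite cylinder in physical (mm) coordinates with homogeneous
#' haemoglobin content. The true oxygen saturation of the vessel is
#' `hbo2 / (hb + hbo2)`. Concentrations are in arbitrary units, mirroring an
#' uncalibrated system; only their ratio (sO2) and their spatial support
#' matter downstream.
#'
#' @param axis_start,axis_end numeric length-3 points (mm) on the cylinder
#'   axis.
#' @param radius_mm cylinder radius in mm, > 0.
#' @param hb,hbo2 deoxy-/oxy-haemoglobin concentration (arbitrary units,
#'   >= 0, not both zero).
#' @return Object of class `vessel_spec`; `$true_so2` holds
#'   `hbo2 / (hb + hbo2)`.
#' @export
vessel_spec <- function(axis_start, axis_end, radius_mm,
                        hb = 0.62, hbo2 = 0.38) {
  axis_start <- as.numeric(axis_start); axis_end <- as.numeric(axis_end)
  if (length(axis_start) != 3L || length(axis_end) != 3L ||
      !all(is.finite(c(axis_start, axis_end))))
    stop("vessel axis endpoints must be finite 3-D points (mm)", call. = FALSE)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("vessel radius must be > 0", call. = FALSE)
  if (hb < 0 || hbo2 < 0 || (hb == 0 && hbo2 == 0))
    stop("concentrations must be >= 0 and not both zero", call. = FALSE)
  structure(list(axis_start = axis_start, axis_end = axis_end,
                 radius_mm = radius_mm, hb = hb, hbo2 = hbo2,
                 true_so2 = hbo2 / (hb + hbo2)),
            class = "vessel_spec")
}

#' Specify a synthetic multispectral finger phantom
#'
#' Collects everything [make_finger_phantom()] needs: the voxel grid, the
#' digital-artery cylinders, the acquisition wavelengths, and the nuisance
#' parameters of the forward model (depth-dependent fluence decay, constant
#' background offset, additive Gaussian noise). Defaults emulate the study
#' acquisitions: 700/730/760/800/850 nm on the 80 um / 50 um grid.
#'
#' @param geometry a [voxel_geometry()].
#' @param vessels list of [vessel_spec()]s (may be empty: background-only
#'   phantom).
#' @param wavelengths strictly increasing nm values inside the bundled
#'   extinction table's range.
#' @param fluence_decay_constant exponential decay rate of the optical
#'   fluence with depth, mm^-1 (>= 0). Default 0.25 mm^-1, a soft-tissue
#'   near-infrared effective-attenuation scale.
#' @param background_level constant intensity offset (arbitrary units).
#' @param noise_sigma SD of additive zero-mean Gaussian noise, independent
#'   per voxel and wavelength (>= 0).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @param table extinction table used by the forward model.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = default_geometry(), vessels = list(),
                         wavelengths = c(700, 730, 760, 800, 850),
                         fluence_decay_constant = 0.25,
                         background_level = 0, noise_sigma = 0,
                         seed = 1L, table = hb_extinction()) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (inherits(vessels, "vessel_spec")) vessels <- list(vessels)
  if (!all(vapply(vessels, inherits, TRUE, "vessel_spec")))
    stop("`vessels` must be a list of vessel_spec objects", call. = FALSE)
  if (length(wavelengths) == 0 || is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be non-empty and strictly increasing", call. = FALSE)
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop(sprintf("wavelength(s) outside extinction table range [%g, %g] nm",
                 rng[1], rng[2]), call. = FALSE)
  if (fluence_decay_constant < 0 || noise_sigma < 0)
    stop("fluence_decay_constant and noise_sigma must be >= 0", call. = FALSE)
  structure(list(geometry = geometry, vessels = vessels,
                 wavelengths = as.numeric(wavelengths),
                 fluence_decay_constant = fluence_decay_constant,
                 background_level = background_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 table = table),
            class = "phantom_spec")
}

#' Rasterise vessel cylinders onto a voxel grid
#'
#' A voxel belongs to a vessel iff its centre lies inside the finite
#' cylinder: radial distance to the axis line at most the radius, axial
#' projection within the segment (no hemispherical end caps, so the
#' voxelised volume converges to the analytic `pi * r^2 * L` as the
#' spacing shrinks). Where vessels overlap, concentrations add.
#'
#' @param geometry a [voxel_geometry()].
#' @param vessels list of [vessel_spec()]s.
#' @return List with 3-D arrays `hb`, `hbo2` (concentrations) and logical
#'   `mask` (any-vessel support).
#' @export
rasterise_vessels <- function(geometry, vessels) {
  shp <- geometry$shape
  hb <- array(0, shp); hbo2 <- array(0, shp)
  cx <- axis_centres_mm(geometry, 1)
  cy <- axis_centres_mm(geometry, 2)
  cz <- axis_centres_mm(geometry, 3)
  for (v in vessels) {
    p0 <- v$axis_start; p1 <- v$axis_end; r <- v$radius_mm
    # bounding box of the capsule, clipped to the grid
    lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
    ix <- which(cx >= lo[1] & cx <= hi[1])
    iy <- which(cy >= lo[2] & cy <= hi[2])
    iz <- which(cz >= lo[3] & cz <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    px <- rep(cx[ix], times = ny * nz)
    py <- rep(rep(cy[iy], each = nx), times = nz)
    pz <- rep(cz[iz], each = nx * ny)
    w <- p1 - p0; L2 <- sum(w^2)
    if (L2 == 0) {                      # degenerate axis: sphere
      d2 <- (px - p0[1])^2 + (py - p0[2])^2 + (pz - p0[3])^2
      inside <- d2 <= r^2
    } else {
      # finite cylinder (no end caps): radial distance to the axis line
      # within r AND axial projection inside the segment, so the voxelised
      # volume converges to the analytic pi * r^2 * L
      t <- ((px - p0[1]) * w[1] + (py - p0[2]) * w[2] + (pz - p0[3]) * w[3]) / L2
      d2 <- (px - (p0[1] + t * w[1]))^2 +
            (py - (p0[2] + t * w[2]))^2 +
            (pz - (p0[3] + t * w[3]))^2
      inside <- d2 <= r^2 & t >= 0 & t <= 1
    }
    if (!any(inside)) next
    sub <- array(FALSE, c(nx, ny, nz)); sub[inside] <- TRUE
    hb  [ix, iy, iz] <- hb  [ix, iy, iz] + v$hb   * sub
    hbo2[ix, iy, iz] <- hbo2[ix, iy, iz] + v$hbo2 * sub
  }
  list(hb = hb, hbo2 = hbo2, mask = (hb + hbo2) > 0)
}

#' Generate a synthetic multispectral finger phantom with ground truth
#'
#' Forward model per voxel and wavelength:
#' `intensity = exp(-k * depth) * ln(10) * (eps_hb(lambda) * Hb +
#' eps_hbo2(lambda) * HbO2) + background + noise`, i.e. initial-pressure
#' contrast proportional to the absorption coefficient of the haemoglobin
#' mixture under a depth-only exponential fluence. No acoustic propagation
#' is modelled: the phantom stands in for an already-reconstructed cube.
#'
#' @param spec a [phantom_spec()].
#' @return List with `cube` (an [msot_cube()]) and `truth`, a `ground_truth`
#'   object holding `hb_map`, `hbo2_map`, `so2_map` (NA outside vessels),
#'   logical `vessel_mask` and `total_vessel_volume_mm3`
#'   (`sum(vessel_mask) * voxel_volume_mm3`).
#' @examples
#' g <- voxel_geometry(c(40, 40, 25), 500, 400)
#' v <- vessel_spec(c(0, 10, 5), c(20, 10, 5), 1, hb = 0.62, hbo2 = 0.38)
#' ph <- make_finger_phantom(phantom_spec(g, list(v), noise_sigma = 0))
#' ph$truth$total_vessel_volume_mm3
#' @export
make_finger_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  ras <- rasterise_vessels(g, spec$vessels)
  A <- build_design_matrix(spec$wavelengths, spec$table)
  nz <- g$shape[3]; nw <- length(spec$wavelengths)
  fl <- exp(-spec$fluence_decay_constant * axis_centres_mm(g, 3))
  cube <- array(0, c(g$shape, nw))
  absorb <- log(10) * outer(c(ras$hb), A[, "eps_hb"]) +
            log(10) * outer(c(ras$hbo2), A[, "eps_hbo2"])
  dim(absorb) <- c(g$shape, nw)
  fl_arr <- aperm(array(fl, c(nz, g$shape[1], g$shape[2])), c(2, 3, 1))
  for (k in seq_len(nw))
    cube[, , , k] <- absorb[, , , k] * fl_arr + spec$background_level
  if (spec$noise_sigma > 0)
    cube <- cube + with_seed(spec$seed,
      array(stats::rnorm(length(cube), 0, spec$noise_sigma), dim(cube)))
  total <- ras$hb + ras$hbo2
  so2 <- array(NA_real_, g$shape)
  so2[total > 0] <- ras$hbo2[total > 0] / total[total > 0]
  truth <- structure(
    list(hb_map = ras$hb, hbo2_map = ras$hbo2, so2_map = so2,
         vessel_mask = ras$mask,
         total_vessel_volume_mm3 = sum(ras$mask) * voxel_volume_mm3(g)),
    class = "ground_truth")
  list(cube = msot_cube(cube, g, spec$wavelengths), truth = truth)
}

#' Generate a seeded occlusion-challenge sO2 time-course
#'
#' Emulates the cuff protocol: flat baseline before cuff inflation, decay
#' towards a trough during the occlusion window (the trough is attained
#' exactly at the window's last frame), recovery through a hyperaemic peak
#' after release, then relaxation towards baseline. Values are spatially
#' averaged sO2 (arbitrary saturation units), one per frame.
#'
#' @param baseline_so2 steady-state pre-occlusion sO2 in `[0, 1]`.
#' @param trough_so2 minimum sO2 during occlusion; `0 <= trough <= baseline`.
#' @param peak_so2 hyperaemic sO2 attained after release (usually >=
#'   baseline; smaller values are permitted, in which case the post-release
#'   maximum need not equal `peak_so2`).
#' @param events an [occlusion_events()] schedule (cuff on/off, series end).
#' @param dt frame interval in seconds (default 2 s).
#' @param rise_s nominal time from release to the hyperaemic peak (s).
#' @param recovery_tau_s relaxation time constant back to baseline (s).
#' @param noise_sigma SD of additive Gaussian noise in sO2 units; the noisy
#'   series is clipped to `[0, 1]`.
#' @param seed integer RNG seed.
#' @return An [occlusion_series()]; attribute `"truth"` holds the noiseless
#'   trajectory and the generating parameters.
#' @export
make_occlusion_series <- function(baseline_so2, trough_so2, peak_so2,
                                  events = occlusion_events(),
                                  dt = 2, rise_s = 10, recovery_tau_s = 30,
                                  noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(events, "occlusion_events"))
  if (!(trough_so2 >= 0 && trough_so2 <= baseline_so2 && baseline_so2 <= 1))
    stop("need 0 <= trough_so2 <= baseline_so2 <= 1", call. = FALSE)
  if (peak_so2 < 0 || peak_so2 > 1)
    stop("peak_so2 must be in [0, 1]", call. = FALSE)
  t <- seq(0, events$series_end, by = dt)
  so2 <- rep(baseline_so2, length(t))
  occ <- t >= events$cuff_on & t < events$cuff_off
  if (any(occ)) {
    to <- t[occ]
    span <- max(to) - events$cuff_on
    u <- if (span > 0) (to - events$cuff_on) / span else rep(1, length(to))
    shape <- (1 - exp(-3 * u)) / (1 - exp(-3))   # hits 1 exactly at u = 1
    so2[occ] <- baseline_so2 + (trough_so2 - baseline_so2) * shape
  }
  rel <- t >= events$cuff_off
  if (any(rel)) {
    tr <- t[rel]
    start <- if (any(occ)) so2[occ][sum(occ)] else baseline_so2
    # peak frame: the release frame nearest the nominal rise time
    ipk <- which.min(abs(tr - (events$cuff_off + rise_s)))
    val <- numeric(length(tr))
    if (ipk > 1) {
      u <- (seq_len(ipk) - 1) / (ipk - 1)
      val[seq_len(ipk)] <- start + (peak_so2 - start) *
        (1 - exp(-3 * u)) / (1 - exp(-3))
    } else val[1] <- peak_so2
    if (ipk < length(tr)) {
      td <- tr[(ipk + 1):length(tr)] - tr[ipk]
      val[(ipk + 1):length(tr)] <-
        baseline_so2 + (peak_so2 - baseline_so2) * exp(-td / recovery_tau_s)
    }
    so2[rel] <- val
  }
  truth <- list(baseline = baseline_so2, trough = trough_so2,
                peak = peak_so2, trajectory = so2, events = events)
  if (noise_sigma > 0)
    so2 <- with_seed(seed,
      pmin(pmax(so2 + stats::rnorm(length(so2), 0, noise_sigma), 0), 1))
  out <- occlusion_series(t, so2)
  attr(out, "truth") <- truth
  out
}

#' Generate an overlapping frame sequence along a finger
#'
#' Crops an ordered sequence of frames from a known 2-D truth image, each
#' shifted by a constant step along the travel axis (columns), optionally
#' with additive Gaussian noise — emulating the slow probe sweep down the
#' finger that yields a few hundred overlapping full-depth projections.
#' `step < frame_width` guarantees that adjacent frames share content, the
#' overlap the stitcher relies on.
#'
#' @param truth 2-D numeric matrix, the noiseless whole-finger image.
#' @param n_frames number of frames (>= 1).
#' @param frame_width frame extent along the travel axis, pixels.
#' @param step inter-frame shift in pixels; `0 <= step < frame_width`, and
#'   `n_frames * step + frame_width <= ncol(truth)`.
#' @param noise_sigma SD of additive Gaussian noise per pixel.
#' @param seed integer RNG seed.
#' @return Object of class `frame_sequence`: list of frames (matrices),
#'   `true_offsets` (pixels, starting at 0), `frame_width`, `truth_dim`.
#' @export
make_frame_sequence <- function(truth, n_frames, frame_width, step,
                                noise_sigma = 0, seed = 1L) {
  truth <- as.matrix(truth)
  if (step < 0 || step >= frame_width)
    stop("need 0 <= step < frame_width (adjacent frames must overlap)",
         call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (n_frames * step + frame_width > ncol(truth))
    stop("sequence extent exceeds the truth image width", call. = FALSE)
  offs <- (seq_len(n_frames) - 1L) * step
  frames <- with_seed(seed, lapply(offs, function(o) {
    f <- truth[, (o + 1):(o + frame_width), drop = FALSE]
    if (noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, noise_sigma), nrow(f))
    f
  }))
  structure(list(frames = frames, true_offsets = offs,
                 frame_width = as.integer(frame_width),
                 truth_dim = dim(truth)),
            class = "frame_sequence")
}

#' Read / write a phantom spec as a JSON config file
#'
#' Serialises everything except the extinction table (re-attached from the
#' bundled table on read).
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- list(
    shape = spec$geometry$shape,
    lateral_um = spec$geometry$spacing_mm[1] * 1000,
    depth_um = spec$geometry$spacing_mm[3] * 1000,
    wavelengths = spec$wavelengths,
    fluence_decay_constant = spec$fluence_decay_constant,
    background_level = spec$background_level,
    noise_sigma = spec$noise_sigma, seed = spec$seed,
    vessels = lapply(spec$vessels, function(v)
      list(axis_start = v$axis_start, axis_end = v$axis_end,
           radius_mm = v$radius_mm, hb = v$hb, hbo2 = v$hbo2)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vessels <- list()
  if (!is.null(x$vessels) && length(x$vessels)) {
    vs <- x$vessels
    if (is.data.frame(vs)) {
      vessels <- lapply(seq_len(nrow(vs)), function(i)
        vessel_spec(unlist(vs$axis_start[i]), unlist(vs$axis_end[i]),
                    vs$radius_mm[i], vs$hb[i], vs$hbo2[i]))
    } else {
      vessels <- lapply(vs, function(v)
        vessel_spec(v$axis_start, v$axis_end, v$radius_mm, v$hb, v$hbo2))
    }
  }
  phantom_spec(voxel_geometry(x$shape, x$lateral_um, x$depth_um), vessels,
               x$wavelengths, x$fluence_decay_constant, x$background_level,
               x$noise_sigma, x$seed)
}
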
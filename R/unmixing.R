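#' Pseudo-inverse linear spectral unmixing
#'
#' Solves, independently for every voxel, the linear system
#' `A %*% c(hb, hbo2) = spectrum` in the least-squares sense via the
#' Moore-Penrose pseudo-inverse of the design matrix `A` (rows = extinction
#' coefficients at the acquisition wavelengths, see
#' [build_design_matrix()]). Negative solutions are retained here — the
#' solver is a pure pseudo-inverse — and clamped only later, in
#' [compute_so2()]. Results are independent of voxel evaluation order.
#'
#' @param cube an [msot_cube()].
#' @param design `n_wavelengths x 2` design matrix; must have full column
#'   rank (an error names the collinear columns otherwise).
#' @return Object of class `chromophore_maps`: 3-D arrays `hb`, `hbo2`
#'   (arbitrary concentration units, same spatial shape as the cube) and
#'   `residual` (per-voxel Euclidean norm of `A %*% c - spectrum`), plus the
#'   cube's `geometry`.
#' @export
unmix_pseudo_inverse <- function(cube, design) {
  stopifnot(inherits(cube, "msot_cube"))
  design <- as.matrix(design)
  nw <- dim(cube$intensities)[4]
  if (nrow(design) != nw)
    stop(sprintf("design has %d rows but cube has %d wavelength planes",
                 nrow(design), nw), call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient: columns ",
         paste(colnames(design), collapse = " and "),
         " are collinear; choose wavelengths with spectral contrast",
         call. = FALSE)
  spat <- dim(cube$intensities)[1:3]
  V <- matrix(cube$intensities, ncol = nw)          # nvox x nw
  pinv <- solve(crossprod(design), t(design))       # 2 x nw
  C <- V %*% t(pinv)                                # nvox x 2
  R <- V - C %*% t(design)
  resid <- sqrt(rowSums(R^2))
  structure(list(hb = array(C[, 1], spat), hbo2 = array(C[, 2], spat),
                 residual = array(resid, spat), geometry = cube$geometry),
            class = "chromophore_maps")
}

#' Noise-floor validity mask
#'
#' Marks a voxel valid iff its total-haemoglobin signal `hb + hbo2`
#' strictly exceeds `floor` — the "thresholding to the noise level" that
#' prevents sO2 being computed from voxels containing only noise.
#'
#' @param maps a `chromophore_maps` from [unmix_pseudo_inverse()].
#' @param floor non-negative intensity threshold; see [auto_noise_floor()]
#'   for a data-driven choice.
#' @return Logical 3-D array.
#' @export
noise_floor_mask <- function(maps, floor) {
  stopifnot(inherits(maps, "chromophore_maps"))
  if (!is.finite(floor) || floor < 0)
    stop("noise floor must be a finite value >= 0", call. = FALSE)
  (maps$hb + maps$hbo2) > floor
}

#' Data-driven noise floor from a background region
#'
#' `mean + 3 * SD` of the total-haemoglobin signal over a user-designated
#' background (signal-free) region.
#'
#' @param maps a `chromophore_maps`.
#' @param background_region logical array marking background voxels.
#' @return Scalar noise floor (clamped at 0).
#' @export
auto_noise_floor <- function(maps, background_region) {
  stopifnot(inherits(maps, "chromophore_maps"))
  tot <- (maps$hb + maps$hbo2)[background_region]
  if (length(tot) < 2)
    stop("background region must contain at least 2 voxels", call. = FALSE)
  max(0, mean(tot) + 3 * stats::sd(tot))
}

#' Per-voxel oxygen saturation map
#'
#' The standard saturation ratio `sO2 = [HbO2] / ([Hb] + [HbO2])`, evaluated
#' at valid voxels after clamping negative unmixed concentrations to zero
#' (which guarantees sO2 in `[0, 1]`). Voxels whose clamped total is zero
#' are removed from the valid mask. Units are arbitrary sO2 units: the
#' instrument is uncalibrated, so only relative saturation is meaningful.
#'
#' @param maps a `chromophore_maps`.
#' @param valid_mask logical array of voxels above the noise floor (default:
#'   all voxels).
#' @return Object of class `oxygenation_map`: 3-D array `so2` (NA where
#'   invalid), logical `valid_mask`, and `geometry`.
#' @export
compute_so2 <- function(maps, valid_mask = NULL) {
  stopifnot(inherits(maps, "chromophore_maps"))
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(maps$hb))
  if (!identical(dim(valid_mask), dim(maps$hb)))
    stop("valid_mask shape does not match the maps", call. = FALSE)
  hb <- pmax(maps$hb, 0); hbo2 <- pmax(maps$hbo2, 0)
  tot <- hb + hbo2
  valid <- valid_mask & tot > 0
  so2 <- array(NA_real_, dim(hb))
  so2[valid] <- hbo2[valid] / tot[valid]
  structure(list(so2 = so2, valid_mask = valid, geometry = maps$geometry),
            class = "oxygenation_map")
}

#' Mean oxygen saturation over valid voxels
#'
#' Arithmetic mean of sO2 over the valid voxels (optionally intersected
#' with a further region mask, e.g. a segmented-vessel mask). Errors — it
#' does not silently return 0 — when no valid voxel remains.
#'
#' @param omap an [compute_so2()] result.
#' @param mask optional logical array intersected with the validity mask.
#' @return Scalar mean sO2 (arbitrary saturation units).
#' @export
mean_so2 <- function(omap, mask = NULL) {
  stopifnot(inherits(omap, "oxygenation_map"))
  sel <- omap$valid_mask
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(sel)))
      stop("mask shape does not match the map", call. = FALSE)
    sel <- sel & mask
  }
  if (!any(sel))
    stop("no valid voxels to average (noise floor removed everything?)",
         call. = FALSE)
  mean(omap$so2[sel])
}
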
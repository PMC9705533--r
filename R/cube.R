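#' Multispectral optoacoustic image cube
#'
#' The pipeline's raw input: a 4-D intensity array over `(x, y, z,
#' wavelength)` together with its voxel geometry and the acquisition
#' wavelengths. Intensities are in arbitrary units (the study system is
#' uncalibrated); the depth axis is z.
#'
#' @param intensities 4-D numeric array `(nx, ny, nz, n_wavelengths)`, all
#'   values finite.
#' @param geometry a [voxel_geometry()]; its shape must match the first three
#'   dimensions.
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm)
#'   whose length matches the fourth dimension.
#' @return An object of class `msot_cube` with elements `intensities`,
#'   `geometry`, `wavelengths`.
#' @export
msot_cube <- function(intensities, geometry, wavelengths) {
  if (!is.array(intensities) || length(dim(intensities)) != 4L)
    stop("`intensities` must be a 4-D array (x, y, z, wavelength)", call. = FALSE)
  stopifnot(inherits(geometry, "voxel_geometry"))
  d <- dim(intensities)
  if (!identical(d[1:3], as.integer(geometry$shape)))
    stop("cube spatial dimensions do not match the geometry", call. = FALSE)
  if (d[4] != length(wavelengths))
    stop(sprintf("wavelength axis has %d planes but %d wavelengths declared",
                 d[4], length(wavelengths)), call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("cube intensities must all be finite", call. = FALSE)
  structure(list(intensities = intensities, geometry = geometry,
                 wavelengths = as.numeric(wavelengths)),
            class = "msot_cube")
}

#' @export
print.msot_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("msot_cube: %d x %d x %d voxels at %d wavelengths (%s nm)\n",
              d[1], d[2], d[3], d[4],
              paste(x$wavelengths, collapse = ", ")))
  print(x$geometry)
  invisible(x)
}

#' Extract the single-wavelength volume of a cube
#'
#' @param cube an [msot_cube()].
#' @param wavelength wavelength in nm; must be one of the cube's acquisition
#'   wavelengths.
#' @return 3-D intensity array.
#' @export
cube_volume <- function(cube, wavelength = 800) {
  stopifnot(inherits(cube, "msot_cube"))
  i <- match(wavelength, cube$wavelengths)
  if (is.na(i))
    stop(sprintf("cube has no %g nm plane (available: %s)", wavelength,
                 paste(cube$wavelengths, collapse = ", ")), call. = FALSE)
  cube$intensities[, , , i, drop = TRUE]
}
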
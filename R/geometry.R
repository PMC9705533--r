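#' Voxel geometry of a reconstructed image volume
#'
#' Describes the voxel grid of a reconstructed optoacoustic image volume:
#' the number of voxels along each axis and the physical voxel spacing.
#' Spacings are accepted in micrometres at the boundary and stored in
#' millimetres internally (all package geometry is in mm). The depth axis is
#' the third axis (z), increasing away from the probe; voxel indices are
#' 0-based conceptually with voxel-centre geometry, i.e. the centre of voxel
#' `i` (1-based in R) lies at `(i - 0.5) * spacing`.
#'
#' The default matches the study system: 80 um lateral resolution, 50 um in
#' depth, over a 2 x 2 x 1 cm volume (250 x 250 x 200 voxels).
#'
#' @param shape integer vector `(nx, ny, nz)`, voxel counts per axis; all >= 1.
#' @param lateral_um voxel spacing along both in-plane axes, micrometres (> 0).
#' @param depth_um voxel spacing along the depth axis, micrometres (> 0).
#' @return An object of class `voxel_geometry` with elements `shape`
#'   (integer, length 3), `spacing_mm` (numeric, length 3: x, y, z) and
#'   `extent_mm` (`shape * spacing_mm`).
#' @examples
#' g <- voxel_geometry(c(250, 250, 200))
#' g$extent_mm          # 20 20 10 (mm)
#' voxel_volume_mm3(g)  # 3.2e-4 mm^3 per voxel
#' @export
voxel_geometry <- function(shape, lateral_um = 80, depth_um = 50) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("`shape` must be three voxel counts, each >= 1", call. = FALSE)
  if (!is.finite(lateral_um) || lateral_um <= 0 ||
      !is.finite(depth_um) || depth_um <= 0)
    stop("voxel spacings must be strictly positive", call. = FALSE)
  spacing_mm <- c(lateral_um, lateral_um, depth_um) / 1000
  structure(
    list(shape = shape, spacing_mm = spacing_mm,
         extent_mm = shape * spacing_mm),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d x %d x %d voxels, spacing %g x %g x %g um (extent %g x %g x %g mm)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1] * 1000, x$spacing_mm[2] * 1000, x$spacing_mm[3] * 1000,
              x$extent_mm[1], x$extent_mm[2], x$extent_mm[3]))
  invisible(x)
}

#' Default acquisition geometry
#'
#' The study system's reconstruction grid: 2 x 2 x 1 cm at 80 um lateral and
#' 50 um depth spacing, i.e. 250 x 250 x 200 voxels.
#' @return A [voxel_geometry()].
#' @export
default_geometry <- function() voxel_geometry(c(250L, 250L, 200L), 80, 50)

#' Physical volume of one voxel in cubic millimetres
#'
#' `lateral^2 * depth`, converted to mm^3; with the default 80 x 80 x 50 um
#' voxel this is 3.2e-4 mm^3.
#' @param geometry a [voxel_geometry()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  prod(geometry$spacing_mm)
}

#' Voxel-centre coordinates along one axis (mm)
#' @noRd
axis_centres_mm <- function(geometry, axis) {
  (seq_len(geometry$shape[axis]) - 0.5) * geometry$spacing_mm[axis]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) && all(abs(a$spacing_mm - b$spacing_mm) < tol)
}
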
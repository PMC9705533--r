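#' Intensity histogram of a volume
#'
#' Equal-width binning over the data range (256 bins by default, the 8-bit
#' convention the moment-preserving method originated with). The upper edge
#' of the last bin is closed so the maximum lands in the last bin.
#'
#' @param x numeric vector or array of intensities (finite).
#' @param bins number of bins (>= 2) for continuous data; ignored if
#'   `breaks` is given.
#' @param breaks optional strictly increasing vector of bin edges covering
#'   the data range.
#' @return Object of class `intensity_histogram`: `bin_edges` (length
#'   `n + 1`), `counts` (length `n`), `mids`, `total`.
#' @export
intensity_histogram <- function(x, bins = 256L, breaks = NULL) {
  x <- as.numeric(x)
  if (!length(x) || !all(is.finite(x)))
    stop("intensities must be a non-empty finite vector", call. = FALSE)
  if (is.null(breaks)) {
    r <- range(x)
    if (r[1] == r[2])                    # constant data: one degenerate bin
      breaks <- c(r[1] - 0.5, r[1] + 0.5)
    else
      breaks <- seq(r[1], r[2], length.out = bins + 1L)
  }
  if (is.unsorted(breaks, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(bin_edges = breaks, counts = counts,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 total = length(x)),
            class = "intensity_histogram")
}

#' Moment-preserving (Tsai) histogram threshold
#'
#' Chooses the binarisation level such that a two-level image preserves the
#' first three raw moments `m1, m2, m3` of the histogram. Solving the
#' moment-preservation system gives two representative levels `z0 < z1` and
#' the below-fraction `p0 = (z1 - m1) / (z1 - z0)`; the threshold is placed
#' at the histogram quantile `p0` using the left-continuous empirical CDF
#' (smallest bin whose CDF reaches `p0`), and the returned cut-off is that
#' bin's upper edge so that a strict `>` comparison truncates the below
#' population including the selected level itself. Deterministic; depends
#' only on the histogram, never on voxel order.
#'
#' @param hist an [intensity_histogram()].
#' @return Scalar threshold (intensity units) with attributes `p0`, `z0`,
#'   `z1` and `bin` (index of the selected bin).
#' @examples
#' h <- intensity_histogram(c(rep(10, 6), rep(200, 2)),
#'                          breaks = seq(9.5, 200.5, by = 1))
#' th <- moment_preserving_threshold(h)   # p0 = 0.75, cut between 10 and 200
#' @export
moment_preserving_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  if (hist$total < 1) stop("empty histogram", call. = FALSE)
  p <- hist$counts / hist$total
  z <- hist$mids
  if (sum(hist$counts > 0) < 2)
    stop("degenerate histogram: all mass in one bin, no threshold separates anything",
         call. = FALSE)
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2                        # variance
  if (cd <= 0)
    stop("degenerate histogram: zero variance", call. = FALSE)
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc <= 0)
    stop("degenerate histogram: moment system has no two distinct levels",
         call. = FALSE)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("degenerate histogram: moment-preserving fraction outside (0, 1)",
         call. = FALSE)
  cdf <- cumsum(p)
  k <- which(cdf >= p0 - 1e-12)[1]       # left-continuous ECDF inversion
  th <- hist$bin_edges[k + 1L]
  structure(th, p0 = p0, z0 = z0, z1 = z1, bin = k)
}

#' Apply an intensity threshold to a volume
#'
#' Strict `>` comparison: voxels at or below the cut-off are truncated
#' (removed), voxels above it are retained as vessel.
#'
#' @param volume 3-D intensity array.
#' @param threshold finite cut-off (e.g. from
#'   [moment_preserving_threshold()]).
#' @param geometry the volume's [voxel_geometry()].
#' @return Object of class `vessel_mask`: logical `mask`, `threshold_used`,
#'   `geometry`.
#' @export
apply_threshold <- function(volume, threshold, geometry) {
  stopifnot(is.array(volume), inherits(geometry, "voxel_geometry"))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (!identical(dim(volume), as.integer(geometry$shape)))
    stop("volume shape does not match the geometry", call. = FALSE)
  structure(list(mask = volume > as.numeric(threshold),
                 threshold_used = as.numeric(threshold),
                 geometry = geometry),
            class = "vessel_mask")
}

#' Vascular volume of a segmentation
#'
#' Voxels above threshold multiplied by the physical voxel volume:
#' `total_volume = n_voxels * lateral^2 * depth` in mm^3 (exactly, no
#' rounding in the machine result; printed tables round to 1 decimal
#' place).
#'
#' @param mask a [apply_threshold()] result (or any `vessel_mask`).
#' @return Object of class `volume_result`: integer `n_voxels`,
#'   `voxel_volume_mm3`, `total_volume_mm3`.
#' @export
vascular_volume <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  n <- sum(mask$mask)
  vv <- voxel_volume_mm3(mask$geometry)
  structure(list(n_voxels = as.integer(n), voxel_volume_mm3 = vv,
                 total_volume_mm3 = n * vv),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("vascular volume: %.1f mm^3 (%d voxels x %g mm^3)\n",
              x$total_volume_mm3, x$n_voxels, x$voxel_volume_mm3))
  invisible(x)
}

#' Mean over the (up to eight) imaged fingers
#'
#' Per-subject summary used by the cohort tables: the arithmetic mean over
#' the fingers with a measurement. Missing fingers (e.g. amputation,
#' failed acquisition) are excluded from the numerator and the denominator,
#' with a warning so the exclusion is logged, never silent.
#'
#' @param values numeric vector of per-finger values; `NA` marks a missing
#'   finger.
#' @return Scalar mean over non-missing values.
#' @export
mean_over_fingers <- function(values) {
  if (!length(values)) stop("no finger values supplied", call. = FALSE)
  miss <- is.na(values)
  if (all(miss)) stop("all fingers missing: no mean can be formed", call. = FALSE)
  if (any(miss))
    warning(sprintf("%d missing finger(s) excluded from the mean", sum(miss)),
            call. = FALSE)
  mean(values[!miss])
}
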
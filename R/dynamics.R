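#' Occlusion-challenge event schedule
#'
#' Times (seconds from the first frame) of cuff inflation, cuff release,
#' and the end of the recording. The defaults follow the study protocol: a
#' 60 s baseline, a two-minute suprasystolic occlusion (cuff at 200 mmHg),
#' and a 60 s post-release window. The three analysis windows are
#' contiguous and non-overlapping by construction: baseline `[0, cuff_on)`,
#' occlusion `[cuff_on, cuff_off)`, release `[cuff_off, series_end]`.
#'
#' @param cuff_on cuff inflation time (s), > 0.
#' @param cuff_off cuff release time (s), > `cuff_on` (default 120 s later).
#' @param series_end end of the recording (s), > `cuff_off`.
#' @return Object of class `occlusion_events`.
#' @export
occlusion_events <- function(cuff_on = 60, cuff_off = cuff_on + 120,
                             series_end = cuff_off + 60) {
  if (!(0 < cuff_on && cuff_on < cuff_off && cuff_off < series_end))
    stop("need 0 < cuff_on < cuff_off < series_end: windows must be ",
         "contiguous and non-overlapping", call. = FALSE)
  structure(list(cuff_on = cuff_on, cuff_off = cuff_off,
                 series_end = series_end),
            class = "occlusion_events")
}

#' Spatially-averaged sO2 time series
#'
#' One sO2 value per acquired frame (already averaged over the region of
#' interest), with per-frame validity flags: frames lost to noise or
#' artefacts are flagged invalid and excluded from window statistics, never
#' dropped from the series.
#'
#' @param timestamps strictly increasing times in seconds.
#' @param so2 per-frame sO2 (arbitrary saturation units); must lie in
#'   `[0, 1]` wherever valid.
#' @param valid logical validity flags (default: finite sO2).
#' @return Object of class `occlusion_series` (a data.frame with columns
#'   `timestamp_s`, `so2`, `valid`).
#' @export
occlusion_series <- function(timestamps, so2, valid = NULL) {
  if (length(timestamps) != length(so2))
    stop("timestamps and so2 lengths differ", call. = FALSE)
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(so2)
  valid <- valid & is.finite(so2)
  if (any(so2[valid] < 0 | so2[valid] > 1))
    stop("valid sO2 values must lie in [0, 1]", call. = FALSE)
  structure(data.frame(timestamp_s = as.numeric(timestamps),
                       so2 = as.numeric(so2), valid = valid),
            class = c("occlusion_series", "data.frame"))
}

#' Extract an sO2 time series from a sequence of cubes
#'
#' Runs the single-cube oxygenation analysis (pseudo-inverse unmixing,
#' noise-floor masking, ROI mean) at every time point. All frames must
#' share geometry and wavelengths. A frame with no voxel surviving the
#' noise floor (or containing non-finite values) is flagged invalid with an
#' `NA` value; the series length is preserved.
#'
#' @param cubes list of [msot_cube()]s, one per time point.
#' @param timestamps acquisition times (s); default `0, dt, 2 dt, ...`.
#' @param roi_mask optional logical array restricting the spatial average.
#' @param noise_floor absolute noise floor passed to [noise_floor_mask()].
#' @param design design matrix; defaults to the bundled table at the cubes'
#'   wavelengths.
#' @param dt frame interval (s) used when `timestamps` is `NULL`.
#' @return An [occlusion_series()].
#' @export
extract_series <- function(cubes, timestamps = NULL, roi_mask = NULL,
                           noise_floor = 0, design = NULL, dt = 2) {
  if (!length(cubes)) stop("no cubes supplied", call. = FALSE)
  ref <- cubes[[1]]
  stopifnot(inherits(ref, "msot_cube"))
  if (is.null(design)) design <- build_design_matrix(ref$wavelengths)
  if (is.null(timestamps)) timestamps <- (seq_along(cubes) - 1) * dt
  so2 <- rep(NA_real_, length(cubes))
  ok <- logical(length(cubes))
  for (i in seq_along(cubes)) {
    ci <- cubes[[i]]
    if (!same_geometry(ci$geometry, ref$geometry) ||
        !identical(ci$wavelengths, ref$wavelengths))
      stop(sprintf("frame %d geometry/wavelengths differ from frame 1", i),
           call. = FALSE)
    maps <- unmix_pseudo_inverse(ci, design)
    omap <- compute_so2(maps, noise_floor_mask(maps, noise_floor))
    val <- tryCatch(mean_so2(omap, roi_mask), error = function(e) NA_real_)
    if (is.finite(val)) { so2[i] <- val; ok[i] <- TRUE }
  }
  occlusion_series(timestamps, so2, ok)
}

#' Baseline, occlusion-trough and post-release-peak metrics
#'
#' Window statistics of an occlusion challenge: the baseline is the mean of
#' valid frames before cuff inflation (a steady state, so a mean is
#' robust), while the occlusion minimum and post-release maximum are
#' extrema of transients. Invalid frames are excluded; a window left with
#' no valid frame raises an error naming the window. Optional moving-median
#' smoothing (window 3) is available as an artefact-rejection knob but is
#' off by default.
#'
#' @param series an [occlusion_series()].
#' @param events an [occlusion_events()].
#' @param smooth logical; apply a 3-frame moving median before the extrema.
#' @return Object of class `occlusion_metrics`: `baseline_so2`, `min_so2`,
#'   `max_so2`, `t_min_s`, `t_max_s`.
#' @export
occlusion_metrics <- function(series, events, smooth = FALSE) {
  stopifnot(inherits(series, "occlusion_series"),
            inherits(events, "occlusion_events"))
  s <- series
  if (smooth) {
    sm <- stats::runmed(s$so2, 3, endrule = "keep")
    sm[!s$valid] <- s$so2[!s$valid]
    s$so2 <- sm
  }
  t <- s$timestamp_s
  win <- list(
    baseline  = s$valid & t < events$cuff_on,
    occlusion = s$valid & t >= events$cuff_on & t < events$cuff_off,
    release   = s$valid & t >= events$cuff_off & t <= events$series_end)
  for (w in names(win))
    if (!any(win[[w]]))
      stop(sprintf("no valid frame in the %s window", w), call. = FALSE)
  i_min <- which(win$occlusion)[which.min(s$so2[win$occlusion])]
  i_max <- which(win$release)[which.max(s$so2[win$release])]
  structure(list(baseline_so2 = mean(s$so2[win$baseline]),
                 min_so2 = s$so2[i_min], max_so2 = s$so2[i_max],
                 t_min_s = t[i_min], t_max_s = t[i_max]),
            class = "occlusion_metrics")
}

#' @export
print.occlusion_metrics <- function(x, ...) {
  cat(sprintf(
    "occlusion metrics: baseline %.3f, min %.3f (t = %g s), max %.3f (t = %g s)\n",
    x$baseline_so2, x$min_so2, x$t_min_s, x$max_so2, x$t_max_s))
  invisible(x)
}

#' Read / write an occlusion series as CSV
#'
#' Columns `timestamp_s, so2, valid` (comma-separated, UTF-8, header row).
#' @param series an [occlusion_series()].
#' @param path file path.
#' @return `write_occlusion_series` returns `path` invisibly;
#'   `read_occlusion_series` returns an [occlusion_series()].
#' @export
write_occlusion_series <- function(series, path) {
  stopifnot(inherits(series, "occlusion_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occlusion_series
#' @export
read_occlusion_series <- function(path) {
  d <- utils::read.csv(path)
  occlusion_series(d$timestamp_s, d$so2, as.logical(d$valid))
}
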
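#' Full-depth projection of a single-wavelength volume
#'
#' Compresses the 3-D layers of a volume into a single 2-D image by
#' projecting along the depth axis. Vessels are bright against background
#' in optoacoustic intensity, so the default is a maximum-intensity
#' projection (MIP), the standard vascular projection; a sum projection is
#' available behind the `method` flag. For whole-finger scans the input is
#' the 800 nm (isosbestic) volume, so the projection is a purely structural
#' image, independent of oxygenation.
#'
#' @param x an [msot_cube()] (the `wavelength` plane is projected) or a 3-D
#'   array.
#' @param wavelength wavelength (nm) selected when `x` is a cube.
#' @param method `"max"` (MIP, default) or `"sum"`.
#' @return 2-D matrix over the in-plane axes.
#' @export
project_cube <- function(x, wavelength = 800, method = c("max", "sum")) {
  method <- match.arg(method)
  vol <- if (inherits(x, "msot_cube")) cube_volume(x, wavelength) else x
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("projection input must be a 3-D single-wavelength volume", call. = FALSE)
  apply(vol, c(1, 2), if (method == "max") max else sum)
}

#' Estimate the offset between two overlapping frames
#'
#' Finds the integer shift along the travel axis (columns) that maximises
#' the normalised cross-correlation (Pearson correlation of the overlapping
#' pixels) between two equally-shaped frames. The peak correlation, in
#' `[-1, 1]`, doubles as a reliability score: pairs scoring below a
#' threshold should not be trusted (see [stitch()]).
#'
#' @param frame_a,frame_b 2-D matrices of identical shape; `frame_b` is
#'   assumed to lie at a non-negative shift ahead of `frame_a` unless
#'   `min_shift < 0`.
#' @param max_shift largest shift searched (pixels); must leave at least
#'   two overlapping columns.
#' @param min_shift smallest shift searched (default 0: the probe travels
#'   one way).
#' @return List with `offset` (pixels) and `score` (peak correlation; 0 is
#'   substituted where the correlation is undefined, e.g. constant
#'   overlap).
#' @export
estimate_offset <- function(frame_a, frame_b,
                            max_shift = floor(ncol(frame_a) / 2),
                            min_shift = 0L) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must share shape", call. = FALSE)
  W <- ncol(frame_a)
  if (max_shift >= W - 1 || max_shift < min_shift)
    stop("search range exceeds the frame extent", call. = FALSE)
  shifts <- seq.int(min_shift, max_shift)
  scores <- vapply(shifts, function(s) {
    if (s >= 0) { a <- frame_a[, (s + 1):W]; b <- frame_b[, 1:(W - s)] }
    else        { a <- frame_a[, 1:(W + s)]; b <- frame_b[, (-s + 1):W] }
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) 0 else stats::cor(c(a), c(b))
  }, numeric(1))
  i <- which.max(scores)
  list(offset = shifts[i], score = scores[i])
}

#' Stitch an overlapping frame sequence into a whole-finger mosaic
#'
#' Estimates pairwise offsets between consecutive frames by normalised
#' cross-correlation, accumulates them into per-frame positions, and
#' composites the frames by per-pixel maximum (which avoids seam artefacts;
#' when offsets are misestimated it reproduces the characteristic duplicate
#' "ghosting" of vessels rather than hiding the failure). Pairs whose peak
#' correlation falls below `reliability_threshold` have the median of the
#' reliable offsets imputed and are flagged; if no pair is reliable the
#' stitcher refuses and advises manual offsets. Stitching is best-effort
#' and for qualitative assessment only — no quantitative measure is
#' derived from a mosaic.
#'
#' @param sequence a [make_frame_sequence()] result, or a plain list of
#'   equally-shaped matrices.
#' @param reliability_threshold minimum acceptable pairwise correlation.
#' @param max_shift search range passed to [estimate_offset()].
#' @param manual_offsets optional integer vector of `n_frames - 1` pairwise
#'   offsets overriding estimation entirely.
#' @return Object of class `mosaic`: `image` (2-D matrix), `offsets`
#'   (cumulative per-frame offsets, non-decreasing), `overlap_scores`
#'   (`n - 1` pairwise correlations), `imputed` (logical flags).
#' @export
stitch <- function(sequence, reliability_threshold = 0.5,
                   max_shift = NULL, manual_offsets = NULL) {
  frames <- if (inherits(sequence, "frame_sequence")) sequence$frames else sequence
  n <- length(frames)
  if (n < 1) stop("empty sequence", call. = FALSE)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), c(H, W)), TRUE)))
    stop("all frames must share shape", call. = FALSE)
  if (n == 1) {
    return(structure(list(image = frames[[1]], offsets = 0L,
                          overlap_scores = numeric(0), imputed = logical(0)),
                     class = "mosaic"))
  }
  if (is.null(max_shift)) max_shift <- floor(W / 2)
  if (is.null(manual_offsets)) {
    est <- lapply(seq_len(n - 1), function(i)
      estimate_offset(frames[[i]], frames[[i + 1]], max_shift = max_shift))
    pair <- vapply(est, `[[`, numeric(1), "offset")
    scores <- vapply(est, `[[`, numeric(1), "score")
    imputed <- scores < reliability_threshold
    if (all(imputed))
      stop("no reliable frame pair (all correlations below threshold); ",
           "supply `manual_offsets`", call. = FALSE)
    if (any(imputed)) pair[imputed] <- stats::median(pair[!imputed])
  } else {
    if (length(manual_offsets) != n - 1)
      stop("`manual_offsets` must have n_frames - 1 entries", call. = FALSE)
    pair <- as.numeric(manual_offsets)
    scores <- rep(NA_real_, n - 1)
    imputed <- rep(FALSE, n - 1)
  }
  offsets <- as.integer(round(c(0, cumsum(pair))))
  canvas <- matrix(-Inf, H, W + offsets[n])
  for (i in seq_len(n)) {
    cols <- (offsets[i] + 1):(offsets[i] + W)
    canvas[, cols] <- pmax(canvas[, cols], frames[[i]])
  }
  canvas[!is.finite(canvas)] <- 0
  structure(list(image = canvas, offsets = offsets,
                 overlap_scores = scores, imputed = imputed),
            class = "mosaic")
}

#' @export
print.mosaic <- function(x, ...) {
  cat(sprintf("mosaic: %d x %d pixels from %d frame(s); %d/%d pair offset(s) imputed\n",
              nrow(x$image), ncol(x$image), length(x$offsets),
              sum(x$imputed), length(x$imputed)))
  invisible(x)
}

#' Write mosaic offsets and reliability scores as a CSV sidecar
#'
#' @param mosaic a [stitch()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mosaic_offsets <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "mosaic"))
  n <- length(mosaic$offsets)
  utils::write.csv(data.frame(
    frame = seq_len(n), offset_px = mosaic$offsets,
    pair_score = c(NA, mosaic$overlap_scores),
    imputed = c(NA, mosaic$imputed)), path, row.names = FALSE)
  invisible(path)
}
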
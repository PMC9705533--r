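#' Write / read a multispectral cube
#'
#' Two volumetric on-disk formats are supported:
#' \describe{
#'   \item{`"text"`}{one ASCII value per line in column-major (x fastest)
#'     order, full `%.17g` precision (round trips are bit-identical), plus a
#'     JSON sidecar `<path>.json` carrying shape, spacings (um), wavelengths
#'     and the stored axis order.}
#'   \item{`"nifti"`}{a minimal single-file NIfTI-1 image (`.nii`, FLOAT64,
#'     spacings in mm in `pixdim`), readable by standard neuroimaging
#'     tools; wavelengths still travel in the JSON sidecar because NIfTI
#'     has no wavelength axis metadata.}
#' }
#' On read the cube is normalised to the canonical `(x, y, z, wavelength)`
#' axis order whatever order it was stored in (the sidecar's `axis_order`
#' declares the stored permutation). A missing sidecar, or a sidecar whose
#' wavelength count disagrees with the stored axis, is an error.
#'
#' @param cube an [msot_cube()].
#' @param path output path (the sidecar is written next to it).
#' @param format `"text"` or `"nifti"`.
#' @param axis_order permutation of `c("x","y","z","w")` in which to store
#'   the array (mainly for interchange tests).
#' @return `write_cube` returns `path` invisibly; `read_cube` an
#'   [msot_cube()].
#' @export
write_cube <- function(cube, path, format = c("text", "nifti"),
                       axis_order = c("x", "y", "z", "w")) {
  stopifnot(inherits(cube, "msot_cube"))
  format <- match.arg(format)
  if (!setequal(axis_order, c("x", "y", "z", "w")))
    stop("axis_order must be a permutation of x, y, z, w", call. = FALSE)
  perm <- match(axis_order, c("x", "y", "z", "w"))
  arr <- aperm(cube$intensities, perm)
  sidecar <- list(
    format = format,
    shape = cube$geometry$shape,
    lateral_um = cube$geometry$spacing_mm[1] * 1000,
    depth_um = cube$geometry$spacing_mm[3] * 1000,
    wavelengths_nm = cube$wavelengths,
    axis_order = axis_order)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (format == "text") {
    writeLines(sprintf("%.17g", as.vector(arr)), path)
  } else {
    write_nifti(arr, path, pixdim_mm = cube$geometry$spacing_mm[perm[perm <= 3]])
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, format = c("text", "nifti")) {
  format <- match.arg(format)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing wavelength metadata: a JSON sidecar '", side_path,
         "' is required", call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  wl <- side$wavelengths_nm
  geom <- voxel_geometry(side$shape, side$lateral_um, side$depth_um)
  axis_order <- if (is.null(side$axis_order)) c("x", "y", "z", "w") else side$axis_order
  perm <- match(axis_order, c("x", "y", "z", "w"))
  stored_dim <- c(geom$shape, length(wl))[perm]
  if (format == "text") {
    vals <- scan(path, what = double(), quiet = TRUE)
    if (length(vals) != prod(stored_dim))
      stop(sprintf("corrupt cube file: %d values but %d expected from the sidecar",
                   length(vals), prod(stored_dim)), call. = FALSE)
    arr <- array(vals, stored_dim)
  } else {
    nif <- read_nifti(path)
    if (!identical(as.integer(dim(nif$data)), as.integer(stored_dim)))
      stop(sprintf(
        "sidecar declares %d wavelength planes but the stored axis disagrees (file dim: %s)",
        length(wl), paste(dim(nif$data), collapse = " x ")), call. = FALSE)
    arr <- nif$data
  }
  arr <- aperm(arr, order(perm))   # back to canonical (x, y, z, w)
  msot_cube(arr, geom, wl)
}

#' Write / read a single 3-D volume as text
#'
#' Same text convention as [write_cube()] but for one 3-D array (masks are
#' stored as 0/1). The sidecar records shape and spacings.
#' @param volume 3-D numeric or logical array.
#' @param path file path.
#' @param geometry a [voxel_geometry()].
#' @return `write_volume` returns `path` invisibly; `read_volume` a list
#'   with `volume` and `geometry`.
#' @export
write_volume <- function(volume, path, geometry) {
  stopifnot(is.array(volume), inherits(geometry, "voxel_geometry"))
  jsonlite::write_json(list(shape = dim(volume),
                            lateral_um = geometry$spacing_mm[1] * 1000,
                            depth_um = geometry$spacing_mm[3] * 1000),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("%.17g", as.vector(as.numeric(volume))), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- scan(path, what = double(), quiet = TRUE)
  if (length(vals) != prod(side$shape))
    stop("corrupt volume file: value count disagrees with the sidecar",
         call. = FALSE)
  list(volume = array(vals, side$shape),
       geometry = voxel_geometry(side$shape, side$lateral_um, side$depth_um))
}

# ---- minimal NIfTI-1 (single-file .nii, FLOAT64) ------------------------

# NIfTI-1: fixed 348-byte header, 4-byte extension flag, data at offset 352.
# Only what this package needs: dim, datatype 64 (float64), pixdim in mm.
write_nifti <- function(arr, path, pixdim_mm) {
  nd <- length(dim(arr))
  con <- file(path, "wb"); on.exit(close(con))
  dims <- rep(1L, 8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(arr)
  pd <- rep(0, 8); pd[2:4] <- rep_len(pixdim_mm, 3)
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused (data_type..dim_info)
  writeBin(as.integer(dims), con, size = 2)           # dim[8]
  writeBin(raw(14), con)                              # intent_p1..intent_code
  writeBin(64L, con, size = 2)                        # datatype = FLOAT64
  writeBin(64L, con, size = 2)                        # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(as.numeric(pd), con, size = 4)             # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset (float)
  writeBin(1, con, size = 4)                          # scl_slope
  writeBin(0, con, size = 4)                          # scl_inter
  writeBin(raw(3), con)                               # slice_end, slice_code
  writeBin(as.integer(2L), con, size = 1)             # xyzt_units = mm
  writeBin(raw(0), con)
  writeBin(raw(220), con)                             # cal_max .. srow/intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                               # extension flag
  writeBin(as.vector(arr), con, size = 8)
  invisible(path)
}

read_nifti <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (readBin(hdr[1:4], "integer", 1, 4) != 348L)
    stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  if (rawToChar(hdr[345:347]) != "n+1")
    stop("not a single-file NIfTI-1 image (bad magic)", call. = FALSE)
  dims <- readBin(hdr[41:56], "integer", 8, 2)
  datatype <- readBin(hdr[71:72], "integer", 1, 2)
  if (datatype != 64L)
    stop("unsupported NIfTI datatype ", datatype, " (only FLOAT64)", call. = FALSE)
  pixdim <- readBin(hdr[77:108], "numeric", 8, 4)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, 4)
  nd <- dims[1]; shape <- dims[2:(1 + nd)]
  seek(con, vox_offset)
  data <- readBin(con, "numeric", prod(shape), 8)
  list(data = array(data, shape), pixdim_mm = pixdim[2:4])
}

#' Run manifest for reproducibility
#'
#' Records the configuration snapshot, package version, seed, timestamps
#' and MD5 checksums of every output file, so a re-run under the same
#' config and seed can be verified bit-for-bit for deterministic stages.
#'
#' @param config named list: the configuration used.
#' @param output_files character vector of produced files.
#' @param path where to write the JSON manifest.
#' @param seed the RNG seed used.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, output_files, path, seed = NULL) {
  sums <- tools::md5sum(output_files)
  manifest <- list(
    package = "msotfinger",
    version = as.character(utils::packageVersion("msotfinger")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    checksums = as.list(sums))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
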
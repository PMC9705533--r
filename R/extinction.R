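#' Bundled haemoglobin extinction table
#'
#' Molar extinction coefficients of deoxy-haemoglobin (Hb) and
#' oxy-haemoglobin (HbO2) on a 10 nm grid from 650 to 900 nm, in
#' cm^-1 M^-1. The table is a synthetic compilation representative of the
#' standard literature tabulations (see the packaged TSV header): it carries
#' the deoxy-Hb shoulder near 760 nm and the isosbestic crossing near
#' 797 nm, where the two chromophores absorb equally so that optoacoustic
#' intensity is independent of oxygenation. Absolute scale is immaterial to
#' sO2 (a ratio), which is why the pipeline works on an uncalibrated system
#' in arbitrary units.
#'
#' @param path optional path to an alternative table (TSV with columns
#'   `wavelength_nm`, `eps_hb`, `eps_hbo2`; `#` comments allowed).
#' @return An object of class `extinction_table`: a data.frame with columns
#'   `wavelength_nm`, `eps_hb`, `eps_hbo2`, strictly increasing wavelengths,
#'   strictly positive coefficients.
#' @seealso [build_design_matrix()], [isosbestic_wavelength()]
#' @export
hb_extinction <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("extinction_cache", envir = .msot_env)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "hb_extinction_synthetic.tsv",
                        package = "msotfinger", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- as_extinction_table(tab)
  if (grepl("hb_extinction_synthetic", path)) assign("extinction_cache", tab, envir = .msot_env)
  tab
}

.msot_env <- new.env(parent = emptyenv())

#' Validate and class a haemoglobin extinction table
#'
#' @param tab data.frame with columns `wavelength_nm`, `eps_hb`, `eps_hbo2`.
#' @return The validated table with class `extinction_table` prepended.
#' @export
as_extinction_table <- function(tab) {
  need <- c("wavelength_nm", "eps_hb", "eps_hbo2")
  if (!all(need %in% names(tab)))
    stop("extinction table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- tab[need]
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE))
    stop("extinction table wavelengths must be strictly increasing", call. = FALSE)
  if (any(tab$eps_hb <= 0) || any(tab$eps_hbo2 <= 0))
    stop("extinction coefficients must be strictly positive", call. = FALSE)
  class(tab) <- c("extinction_table", class(tab))
  tab
}

#' Build the spectral unmixing design matrix
#'
#' Row i of the returned matrix holds the molar extinction coefficients
#' `(eps_hb(lambda_i), eps_hbo2(lambda_i))`, linearly interpolated between
#' the table's grid points. With two or more distinct wavelengths on either
#' side of the isosbestic point the matrix has full column rank and the
#' per-voxel system `A %*% c(hb, hbo2) = spectrum` is solvable in the
#' least-squares sense.
#'
#' @param wavelengths numeric vector of wavelengths in nm, length >= 2, all
#'   inside the table's grid range.
#' @param table an [hb_extinction()] table.
#' @return `length(wavelengths) x 2` matrix, columns `eps_hb`, `eps_hbo2`,
#'   rows named by wavelength.
#' @examples
#' A <- build_design_matrix(c(700, 730, 760, 800, 850))
#' @export
build_design_matrix <- function(wavelengths, table = hb_extinction()) {
  if (length(wavelengths) < 2L)
    stop("at least 2 wavelengths are required (the two-chromophore system ",
         "is underdetermined otherwise)", call. = FALSE)
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop(sprintf("wavelength(s) outside the extinction table range [%g, %g] nm: %s",
                 rng[1], rng[2],
                 paste(wavelengths[wavelengths < rng[1] | wavelengths > rng[2]],
                       collapse = ", ")), call. = FALSE)
  A <- cbind(
    eps_hb   = stats::approx(table$wavelength_nm, table$eps_hb,   xout = wavelengths)$y,
    eps_hbo2 = stats::approx(table$wavelength_nm, table$eps_hbo2, xout = wavelengths)$y
  )
  rownames(A) <- as.character(wavelengths)
  A
}

#' Isosbestic wavelength of the bundled table
#'
#' The wavelength where the interpolated Hb and HbO2 extinction curves
#' cross, found by linear interpolation of `eps_hb - eps_hbo2` between the
#' bracketing grid points. For haemoglobin this lies near 800 nm; imaging at
#' it yields oxygenation-independent (purely structural) contrast.
#'
#' @param table an [hb_extinction()] table.
#' @param window wavelength range (nm) searched for the sign change.
#' @return Crossing wavelength in nm.
#' @export
isosbestic_wavelength <- function(table = hb_extinction(), window = c(750, 860)) {
  sel <- table$wavelength_nm >= window[1] & table$wavelength_nm <= window[2]
  w <- table$wavelength_nm[sel]
  d <- table$eps_hb[sel] - table$eps_hbo2[sel]
  flip <- which(d[-length(d)] * d[-1] <= 0)
  if (length(flip) == 0)
    stop("no isosbestic crossing inside the search window", call. = FALSE)
  i <- flip[1]
  # linear root between grid points i and i+1
  w[i] + (w[i + 1] - w[i]) * d[i] / (d[i] - d[i + 1])
}
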
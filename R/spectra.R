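## Reflectance spectra: reading, cleaning, resampling.

#' The common 1-nm wavelength grid
#'
#' All visual-model integration happens on this grid.
#' @return integer vector 300:700 (nm).
#' @export
spectralGrid <- function() 300:700

.asSpectrum <- function(wl, refl) {
  o <- order(wl)
  wl <- wl[o]; refl <- refl[o]
  if (anyDuplicated(wl)) {
    refl <- as.numeric(tapply(refl, wl, mean))
    wl <- sort(unique(wl))
  }
  data.frame(wavelength = wl, reflectance = refl)
}

#' Read a two-column reflectance spectrum file
#'
#' Plain whitespace- or comma-delimited text with two numeric columns:
#' wavelength (nm) and reflectance (percent). Rows are sorted by
#' wavelength; duplicated wavelengths are averaged.
#'
#' @param path file path.
#' @return data.frame with columns \code{wavelength}, \code{reflectance}.
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  raw <- read.table(path, header = grepl("[A-Za-z]", first), sep = sep,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("spectrum file must have at least two columns: ", path)
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  refl <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(!is.finite(wl)) || any(!is.finite(refl)))
    stop("non-numeric values in spectrum file: ", path)
  .asSpectrum(wl, refl)
}

#' Clean a spectrum and resample it to the 1-nm grid
#'
#' Linearly interpolates the spectrum onto the 300-700 nm 1-nm grid and
#' clamps negative reflectance (instrument noise) to zero. Values above
#' 100% are retained, since specular glare can genuinely exceed the
#' white standard.
#'
#' @param spectrum data.frame from [readSpectrum()] (columns
#'   \code{wavelength}, \code{reflectance}).
#' @param grid target wavelength grid; defaults to [spectralGrid()].
#' @return resampled, clamped spectrum data.frame.
#' @export
cleanAndResample <- function(spectrum, grid = spectralGrid()) {
  wl <- spectrum$wavelength
  if (min(wl) > min(grid) || max(wl) < max(grid))
    stop(sprintf("spectrum spans [%g, %g] nm; must cover [%g, %g]",
                 min(wl), max(wl), min(grid), max(grid)))
  refl <- approx(wl, spectrum$reflectance, xout = grid)$y
  refl[refl < 0] <- 0
  data.frame(wavelength = grid, reflectance = refl)
}
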
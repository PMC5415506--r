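## Receptor-noise limited model of avian tetrachromatic colour vision:
## quantum catches, receptor noise, chromatic distance (delta S, jnd) and
## an isometric xyz coordinate embedding.

.CONE_ORDER <- c("vs", "s", "m", "l")

#' Visual-pigment absorbance template
#'
#' Vitamin-A1 rhodopsin/cone-opsin absorbance as a function of wavelength
#' for a given peak wavelength, using the standard alpha+beta band
#' template (Govardovskii-type nomogram). Normalised to peak 1.
#'
#' @param lambdaMax peak absorbance wavelength (nm).
#' @param wl wavelengths (nm) at which to evaluate.
#' @return numeric vector of relative absorbances in [0, 1].
#' @export
pigmentTemplate <- function(lambdaMax, wl = spectralGrid()) {
  x <- lambdaMax / wl
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambdaMax
  bwd <- -40.5 + 0.195 * lambdaMax
  beta <- 0.26 * exp(-((wl - lmb) / bwd)^2)
  s <- alpha + beta
  s / max(s)
}

#' Smooth daylight-like irradiance (synthetic d65 stand-in)
#'
#' A smooth standard-daylight approximation: the 6504 K Planck spectral
#' radiance, normalised to unit maximum on the 300-700 nm grid. It is a
#' synthetic stand-in for the tabulated CIE D65 illuminant, adequate here
#' because von Kries normalisation cancels the illuminant in all chromatic
#' distances; only the achromatic point depends on it.
#'
#' @param wl wavelengths (nm).
#' @return numeric irradiance in arbitrary units, max 1.
#' @export
daylightIrradiance <- function(wl = spectralGrid()) {
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23
  lam <- wl * 1e-9
  T <- 6504
  rad <- (2 * h * c0^2 / lam^5) / (exp(h * c0 / (lam * kB * T)) - 1)
  rad / max(rad)
}

#' Construct an avian visual system
#'
#' Builds a [VisualSystem-class] for a violet-sensitive (V-type) eye. By
#' default cone spectral sensitivities are generated from the vitamin-A1
#' pigment template at standard V-type single-cone peaks (VS 416, S 478,
#' M 542, L 607 nm), the irradiance is the bundled daylight-like spectrum,
#' the Weber fraction is the field-standard 0.1, and the cone proportions
#' are a placeholder honeyeater-type average (1 : 2 : 2 : 4 for
#' VS : S : M : L). The placeholder proportions are NOT measured values
#' for any particular species; supply measured proportions (e.g. retinal
#' counts for the study taxa) via \code{proportions} to mirror a specific
#' visual system.
#'
#' @param sensitivities optional numeric matrix (rows = grid wavelengths,
#'   4 columns vs/s/m/l) of cone sensitivities; overrides the template.
#' @param proportions named numeric(4), relative cone abundances.
#' @param weber Weber fraction of the most abundant cone class.
#' @param irradiance optional numeric irradiance on the grid.
#' @param peaks named numeric(4), template peak wavelengths (nm), used
#'   only when \code{sensitivities} is NULL.
#' @return a \code{VisualSystem}.
#' @export
#' @examples
#' vs <- visualSystem()
#' vs
visualSystem <- function(sensitivities = NULL,
                         proportions = c(vs = 1, s = 2, m = 2, l = 4),
                         weber = 0.1,
                         irradiance = NULL,
                         peaks = c(vs = 416, s = 478, m = 542, l = 607)) {
  wl <- spectralGrid()
  if (is.null(sensitivities)) {
    sensitivities <- vapply(.CONE_ORDER,
                            function(k) pigmentTemplate(peaks[[k]], wl),
                            numeric(length(wl)))
  }
  colnames(sensitivities) <- .CONE_ORDER
  if (is.null(irradiance)) irradiance <- daylightIrradiance(wl)
  proportions <- proportions[.CONE_ORDER]
  new("VisualSystem", wavelengths = as.numeric(wl),
      sensitivities = sensitivities,
      proportions = setNames(as.numeric(proportions), .CONE_ORDER),
      weber = weber, irradiance = as.numeric(irradiance))
}

#' Read a wavelength-indexed sensitivity or irradiance table
#'
#' Multi-column delimited text: first column wavelength (nm), remaining
#' columns values (e.g. one per cone class). Interpolated to the 1-nm grid.
#'
#' @param path file path.
#' @param grid target grid.
#' @return numeric matrix, one column per value column.
#' @export
readWavelengthTable <- function(path, grid = spectralGrid()) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  raw <- read.table(path, header = grepl("[A-Za-z]", first), sep = sep)
  wl <- raw[[1]]
  out <- vapply(seq_len(ncol(raw) - 1L),
                function(j) approx(wl, raw[[j + 1L]], xout = grid)$y,
                numeric(length(grid)))
  colnames(out) <- names(raw)[-1]
  if (any(!is.finite(out))) stop("table does not cover the grid: ", path)
  out
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Cone quantum catches of a reflectance spectrum
#'
#' For each cone class \eqn{i}, the quantum catch is
#' \eqn{Q_i = \int R(\lambda) I(\lambda) C_i(\lambda) d\lambda}
#' (trapezoid rule, 300-700 nm). Von Kries chromatic adaptation divides
#' by the illuminant catch \eqn{\int I C_i}, and \eqn{f_i} is the natural
#' log of the normalised catch, the quantity the receptor-noise model
#' works with.
#'
#' @param spectrum cleaned spectrum on the 1-nm grid
#'   (see [cleanAndResample()]).
#' @param vs a [VisualSystem-class].
#' @return list with components \code{Q} (raw catches), \code{qn}
#'   (von-Kries normalised catches) and \code{f} (log normalised catches),
#'   each named vs/s/m/l.
#' @export
quantumCatch <- function(spectrum, vs) {
  stopifnot(is(vs, "VisualSystem"))
  wl <- vs@wavelengths
  if (!isTRUE(all.equal(spectrum$wavelength, wl)))
    spectrum <- cleanAndResample(spectrum, wl)
  R <- spectrum$reflectance
  I <- vs@irradiance
  Q <- vapply(.CONE_ORDER, function(k) {
    .trapz(wl, R * I * vs@sensitivities[, k])
  }, numeric(1))
  if (any(Q <= 0))
    stop("zero quantum catch for cone(s): ",
         paste(.CONE_ORDER[Q <= 0], collapse = ", "),
         " (log-catch undefined)")
  K <- vapply(.CONE_ORDER, function(k) .trapz(wl, I * vs@sensitivities[, k]),
              numeric(1))
  qn <- Q / K
  list(Q = Q, qn = qn, f = log(qn))
}

#' Receptor noise per cone class
#'
#' Noise in each channel scales with the inverse square root of cone
#' abundance: \eqn{\omega_i = \nu \sqrt{\eta_{max}/\eta_i}}, so the most
#' abundant cone class has noise exactly the Weber fraction \eqn{\nu}.
#'
#' @param vs a [VisualSystem-class].
#' @return named numeric(4) of noise values \eqn{\omega_i}.
#' @export
receptorNoise <- function(vs) {
  stopifnot(is(vs, "VisualSystem"))
  eta <- vs@proportions
  vs@weber * sqrt(max(eta) / eta)
}

#' Chromatic discriminability delta S (jnd)
#'
#' The receptor-noise limited chromatic distance between two stimuli for
#' a tetrachromat, from the log catch differences
#' \eqn{\Delta f_i = f_i(a) - f_i(b)} and the channel noises
#' \eqn{\omega_i}. One jnd is approximately the discrimination threshold.
#'
#' @param a,b quantum-catch lists from [quantumCatch()].
#' @param noise numeric(4) from [receptorNoise()].
#' @return non-negative chromatic distance in jnd.
#' @export
deltaS <- function(a, b, noise) {
  df <- a$f - b$f
  w <- as.numeric(noise)
  num <- (w[1] * w[2])^2 * (df[4] - df[3])^2 +
         (w[1] * w[3])^2 * (df[4] - df[2])^2 +
         (w[1] * w[4])^2 * (df[3] - df[2])^2 +
         (w[2] * w[3])^2 * (df[4] - df[1])^2 +
         (w[2] * w[4])^2 * (df[3] - df[1])^2 +
         (w[3] * w[4])^2 * (df[2] - df[1])^2
  den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
         (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
  sqrt(num / den)
}

## The 4x4 quadratic form M with dS^2 = df' M df. M annihilates the
## uniform-shift direction (each difference vector is orthogonal to 1),
## so it has rank 3; its square root gives the isometric xyz embedding.
.deltaSForm <- function(noise) {
  w <- as.numeric(noise)
  terms <- list(
    list(c = (w[1] * w[2])^2, i = 4L, j = 3L),
    list(c = (w[1] * w[3])^2, i = 4L, j = 2L),
    list(c = (w[1] * w[4])^2, i = 3L, j = 2L),
    list(c = (w[2] * w[3])^2, i = 4L, j = 1L),
    list(c = (w[2] * w[4])^2, i = 3L, j = 1L),
    list(c = (w[3] * w[4])^2, i = 2L, j = 1L)
  )
  den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
         (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
  M <- matrix(0, 4, 4)
  for (tm in terms) {
    v <- numeric(4); v[tm$i] <- 1; v[tm$j] <- -1
    M <- M + tm$c * tcrossprod(v)
  }
  M / den
}

#' Linear map from log catches to xyz chromatic coordinates
#'
#' Returns the fixed 3x4 matrix B such that \code{B \%*\% f} gives xyz
#' coordinates whose Euclidean distances reproduce [deltaS()] exactly and
#' which ignore uniform (intensity) shifts of f. Built by
#' eigendecomposition of the delta-S quadratic form: the three non-null
#' eigenvectors, scaled by the square roots of their eigenvalues. Signs
#' are fixed deterministically (largest-magnitude entry of each row
#' positive).
#'
#' @param noise numeric(4) from [receptorNoise()].
#' @return 3x4 numeric matrix (rows x, y, z).
#' @export
coordinateMap <- function(noise) {
  M <- .deltaSForm(noise)
  eg <- eigen(M, symmetric = TRUE)
  vals <- pmax(eg$values[1:3], 0)
  B <- sqrt(vals) * t(eg$vectors[, 1:3, drop = FALSE])
  for (r in 1:3) {
    k <- which.max(abs(B[r, ]))
    if (B[r, k] < 0) B[r, ] <- -B[r, ]
  }
  dimnames(B) <- list(c("x", "y", "z"), .CONE_ORDER)
  B
}

#' Chromatic coordinates (xyz, jnd units) of a stimulus
#'
#' Position of a quantum-catch quadruple in avian perceptual colour space.
#' The achromatic point (equal normalised catches) maps to the origin;
#' Euclidean distances between coordinates equal [deltaS()].
#'
#' @param q quantum-catch list from [quantumCatch()].
#' @param noise numeric(4) from [receptorNoise()].
#' @param map optional precomputed [coordinateMap()] (saves recomputation
#'   in loops).
#' @return named numeric(3): x, y, z in jnd.
#' @export
chromaticCoords <- function(q, noise, map = coordinateMap(noise)) {
  setNames(as.numeric(map %*% q$f), c("x", "y", "z"))
}

#' Chromatic coordinates of a plumage patch from replicate spectra
#'
#' Each replicate spectrum is scored independently through the visual
#' model; the patch value is the arithmetic mean of the per-replicate
#' xyz coordinates (not of the spectra).
#'
#' @param spectra list of spectra (data.frames); five replicates expected.
#' @param vs a [VisualSystem-class].
#' @return named numeric(3) mean coordinates.
#' @export
patchCoordinates <- function(spectra, vs) {
  if (length(spectra) == 0L) stop("no replicate spectra supplied")
  if (length(spectra) < 5L)
    warning("only ", length(spectra), " replicate spectrum(s); 5 expected")
  noise <- receptorNoise(vs)
  map <- coordinateMap(noise)
  coords <- vapply(spectra, function(sp)
    chromaticCoords(quantumCatch(sp, vs), noise, map), numeric(3))
  rowMeans(coords)
}

#' Carotenoid chroma of a reflectance spectrum
#'
#' Spectral index of yellow carotenoid deposition:
#' \eqn{(R_{700} - R_{450})/R_{700}}. Deeper carotenoid absorption around
#' 450 nm gives values closer to 1.
#'
#' @param spectrum spectrum data.frame covering 450 and 700 nm.
#' @return dimensionless ratio.
#' @export
carotenoidChroma <- function(spectrum) {
  wl <- spectrum$wavelength
  if (min(wl) > 450 || max(wl) < 700)
    stop("spectrum must cover 450 and 700 nm")
  r450 <- approx(wl, spectrum$reflectance, xout = 450)$y
  r700 <- approx(wl, spectrum$reflectance, xout = 700)$y
  if (r700 <= 0) stop("R700 <= 0: carotenoid chroma undefined")
  (r700 - r450) / r700
}
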
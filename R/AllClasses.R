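## Central S4 containers.

#' Avian visual system for receptor-noise modelling
#'
#' Bundles everything the receptor-noise limited colour-vision model needs:
#' spectral sensitivities of the four single-cone classes (violet-sensitive
#' VS, short S, medium M, long L), their relative abundances in the retina,
#' the Weber fraction of the most abundant cone class, and the illuminant
#' irradiance spectrum. All spectral tables live on the common 1-nm grid
#' from 300 to 700 nm.
#'
#' @slot wavelengths numeric, the 1-nm wavelength grid (nm).
#' @slot sensitivities numeric matrix, one column per cone class
#'   (\code{vs}, \code{s}, \code{m}, \code{l}), rows matching
#'   \code{wavelengths}; arbitrary non-negative units.
#' @slot proportions named numeric of length 4, relative cone abundances
#'   \eqn{\eta_i > 0}.
#' @slot weber numeric(1), Weber fraction \eqn{\nu} of the most abundant
#'   cone class.
#' @slot irradiance numeric, illuminant spectrum on the same grid
#'   (arbitrary units; it cancels in chromatic distances after von Kries
#'   normalisation).
#'
#' @seealso [visualSystem()] for the constructor with bundled defaults.
#' @export
setClass("VisualSystem",
  representation(
    wavelengths  = "numeric",
    sensitivities = "matrix",
    proportions  = "numeric",
    weber        = "numeric",
    irradiance   = "numeric"
  )
)

setValidity("VisualSystem", function(object) {
  wl <- object@wavelengths
  msg <- character(0)
  if (length(wl) < 2L || any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (min(wl) > 300 || max(wl) < 700)
    msg <- c(msg, "wavelength grid must cover [300, 700] nm")
  if (!is.numeric(object@sensitivities) ||
      nrow(object@sensitivities) != length(wl) ||
      ncol(object@sensitivities) != 4L)
    msg <- c(msg, "sensitivities must be a length(wavelengths) x 4 matrix")
  else if (any(object@sensitivities < 0))
    msg <- c(msg, "cone sensitivities must be non-negative")
  if (length(object@proportions) != 4L || any(object@proportions <= 0))
    msg <- c(msg, "proportions must be 4 positive numbers")
  if (length(object@weber) != 1L || object@weber <= 0)
    msg <- c(msg, "weber must be a single positive number")
  if (length(object@irradiance) != length(wl) || any(object@irradiance < 0))
    msg <- c(msg, "irradiance must be non-negative and match the grid")
  if (length(msg)) msg else TRUE
})

#' Per-species effect sizes with known sampling variances
#'
#' One effect (a temporal slope, in trait units per year) per species,
#' together with its standard error. The squared standard errors act as
#' fixed measurement-error variances in the meta-analytic model. An
#' optional moderator (a second trait's slope per species) supports
#' effect-on-effect meta-regression.
#'
#' @slot species character, unique species labels matching phylogeny tips.
#' @slot effect numeric, effect sizes (units/year).
#' @slot se numeric, standard errors (> 0, same units).
#' @slot moderator numeric, optional covariate effect sizes; length 0 when
#'   absent.
#'
#' @seealso [effectSizeSet()], [readEffectSizes()]
#' @export
setClass("EffectSizeSet",
  representation(
    species   = "character",
    effect    = "numeric",
    se        = "numeric",
    moderator = "numeric"
  )
)

setValidity("EffectSizeSet", function(object) {
  k <- length(object@species)
  msg <- character(0)
  if (anyDuplicated(object@species))
    msg <- c(msg, "species labels must be unique")
  if (length(object@effect) != k || length(object@se) != k)
    msg <- c(msg, "effect and se must match species in length")
  if (any(!is.finite(object@effect)))
    msg <- c(msg, "effects must be finite")
  if (any(!is.finite(object@se)) || any(object@se <= 0))
    msg <- c(msg, "standard errors must be finite and > 0")
  if (length(object@moderator) && length(object@moderator) != k)
    msg <- c(msg, "moderator must be empty or match species in length")
  if (length(msg)) msg else TRUE
})

#' Posterior sample from the phylogenetic meta-analytic model
#'
#' Holds the retained Markov-chain draws of the meta-analytic location
#' parameters and variance components, plus the typical sampling variance
#' used for heterogeneity. Columns of \code{samples}: the fixed effects
#' (\code{mu}, and \code{b} for meta-regression), \code{sigma2_p}
#' (phylogenetic variance) and \code{sigma2_s} (non-phylogenetic
#' species variance).
#'
#' @slot samples numeric matrix of posterior draws, one row per retained
#'   sample.
#' @slot sigma2m numeric(1), typical sampling variance (Nakagawa-Santos).
#' @slot model character(1), \code{"intercept"} or \code{"regression"}.
#' @export
setClass("MetaChain",
  representation(
    samples = "matrix",
    sigma2m = "numeric",
    model   = "character"
  )
)

setValidity("MetaChain", function(object) {
  msg <- character(0)
  need <- c("mu", "sigma2_p", "sigma2_s")
  if (!all(need %in% colnames(object@samples)))
    msg <- c(msg, "samples must have columns mu, sigma2_p, sigma2_s")
  else if (any(object@samples[, c("sigma2_p", "sigma2_s")] < 0))
    msg <- c(msg, "variance draws must be non-negative")
  if (length(object@sigma2m) != 1L || object@sigma2m <= 0)
    msg <- c(msg, "sigma2m must be a single positive number")
  if (!object@model %in% c("intercept", "regression"))
    msg <- c(msg, "model must be 'intercept' or 'regression'")
  if (length(msg)) msg else TRUE
})

#' Posterior summaries of a phylogenetic meta-analysis
#'
#' Posterior mean, 95% credible interval and pMCMC for the focal location
#' parameter (meta-analytic mean or meta-regression slope), together with
#' heterogeneity I2 and phylogenetic signal summaries.
#'
#' @slot term character(1), name of the summarised location parameter.
#' @slot estimate numeric(1) posterior mean.
#' @slot lower,upper numeric(1), bounds of the 95% credible interval.
#' @slot pMCMC numeric(1), two-sided tail probability of crossing zero.
#' @slot i2 named numeric(3) (\code{mean}, \code{lower}, \code{upper}).
#' @slot signal named numeric(3), phylogenetic signal (lambda-equivalent).
#' @slot sigma2m numeric(1), typical sampling variance.
#' @export
setClass("MetaResult",
  representation(
    term     = "character",
    estimate = "numeric",
    lower    = "numeric",
    upper    = "numeric",
    pMCMC    = "numeric",
    i2       = "numeric",
    signal   = "numeric",
    sigma2m  = "numeric"
  )
)

setValidity("MetaResult", function(object) {
  msg <- character(0)
  if (object@lower > object@upper)
    msg <- c(msg, "credible interval bounds out of order")
  if (object@pMCMC <= 0 || object@pMCMC > 1)
    msg <- c(msg, "pMCMC must lie in (0, 1]")
  if (any(object@i2 < 0 | object@i2 > 1))
    msg <- c(msg, "I2 summaries must lie in [0, 1]")
  if (any(object@signal < 0 | object@signal > 1))
    msg <- c(msg, "phylogenetic signal summaries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname MetaResult-class
#' @param x a \code{MetaResult}
#' @param name slot name
#' @export
setMethod("$", "MetaResult", function(x, name) slot(x, name))
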
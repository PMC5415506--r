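#' Accessors for carotrend S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an S4 object from this package
#' @param ... passed to methods
#' @return the extracted component; see the method-specific sections.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object, ...) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("effectTable", function(object, ...) standardGeneric("effectTable"))

#' @rdname accessors
#' @export
setGeneric("chainSamples", function(object, ...) standardGeneric("chainSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingVariance", function(object, ...) standardGeneric("samplingVariance"))

#' @rdname accessors
#' @export
setGeneric("coneProportions", function(object, ...) standardGeneric("coneProportions"))

#' @rdname accessors
#' @export
setGeneric("weberFraction", function(object, ...) standardGeneric("weberFraction"))

#' @rdname accessors
#' @export
setMethod("speciesNames", "EffectSizeSet", function(object, ...) object@species)

#' @rdname accessors
#' @export
setMethod("effectTable", "EffectSizeSet", function(object, ...) {
  out <- data.frame(
    species = object@species,
    beta    = object@effect,
    se      = object@se,
    stringsAsFactors = FALSE
  )
  if (length(object@moderator)) out$moderator <- object@moderator
  out
})

#' @rdname accessors
#' @export
setMethod("chainSamples", "MetaChain", function(object, ...) object@samples)

#' @rdname accessors
#' @export
setMethod("samplingVariance", "MetaChain", function(object, ...) object@sigma2m)

#' @rdname accessors
#' @export
setMethod("samplingVariance", "MetaResult", function(object, ...) object@sigma2m)

#' @rdname accessors
#' @export
setMethod("coneProportions", "VisualSystem", function(object, ...) object@proportions)

#' @rdname accessors
#' @export
setMethod("weberFraction", "VisualSystem", function(object, ...) object@weber)

setMethod("show", "VisualSystem", function(object) {
  cat("VisualSystem (violet-sensitive tetrachromat)\n")
  cat(sprintf("  grid: %g-%g nm (%d points)\n",
              min(object@wavelengths), max(object@wavelengths),
              length(object@wavelengths)))
  cat("  cone proportions (vs:s:m:l): ",
      paste(signif(object@proportions, 3), collapse = " : "), "\n", sep = "")
  cat(sprintf("  Weber fraction (most abundant cone): %g\n", object@weber))
})

setMethod("show", "EffectSizeSet", function(object) {
  cat(sprintf("EffectSizeSet with %d species%s\n", length(object@species),
              if (length(object@moderator)) " (+ moderator)" else ""))
  print(head(effectTable(object), 5))
  if (length(object@species) > 5) cat("  ...\n")
})

setMethod("show", "MetaChain", function(object) {
  cat(sprintf("MetaChain (%s model): %d retained draws\n",
              object@model, nrow(object@samples)))
  cat(sprintf("  typical sampling variance sigma2_m = %.3g\n", object@sigma2m))
})

setMethod("show", "MetaResult", function(object) {
  cat("Phylogenetic meta-analysis posterior summary\n")
  cat(sprintf("  %s = %.4g  [95%% CI %.4g, %.4g]  pMCMC = %.3g\n",
              object@term, object@estimate, object@lower, object@upper,
              object@pMCMC))
  cat(sprintf("  I2     = %.3f [%.3f, %.3f]\n",
              object@i2["mean"], object@i2["lower"], object@i2["upper"]))
  cat(sprintf("  signal = %.3f [%.3f, %.3f]\n",
              object@signal["mean"], object@signal["lower"],
              object@signal["upper"]))
})
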
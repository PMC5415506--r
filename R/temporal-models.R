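## Per-species temporal models: spatially corrected linear mixed models
## and penalized-spline (GAMM) nonlinearity screening.

#' @importFrom nlme lme gls varIdent lmeControl glsControl
NULL

.prepPredictors <- function(records, response, includeSeason) {
  need <- c(response, "decade", "sex", "altitude", "latitude", "longitude")
  if (includeSeason) need <- c(need, "season")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required column(s): ", paste(miss, collapse = ", "))
  d <- records[is.finite(records[[response]]), , drop = FALSE]
  d$sex <- factor(d$sex)
  if (is.null(d$subspecies)) d$subspecies <- "nominate"
  d$subspecies <- factor(d$subspecies)
  ## decade in decade units so the slope is per decade; per-year on output
  d$dec10 <- d$decade / 10
  if (includeSeason) {
    d$season_c <- d$season - mean(d$season, na.rm = TRUE)
    d$season2 <- d$season_c^2
    d <- d[is.finite(d$season_c), , drop = FALSE]
  }
  d
}

## standardize a numeric column in place, remembering centre/scale
.standardize <- function(d, cols) {
  scales <- list()
  for (cl in cols) {
    m <- mean(d[[cl]]); s <- sd(d[[cl]])
    if (!is.finite(s) || s == 0)
      stop("predictor '", cl, "' is constant: singular design")
    d[[paste0(cl, "_z")]] <- (d[[cl]] - m) / s
    scales[[cl]] <- c(centre = m, scale = s)
  }
  list(data = d, scales = scales)
}

.checkDesign <- function(formula, data) {
  X <- stats::model.matrix(formula, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

.fixedFormula <- function(response, includeSeason, useRac) {
  rhs <- c("dec10_z", "sex", "altitude_z")
  if (useRac) rhs <- c(rhs, "rac_z")
  if (includeSeason) rhs <- c(rhs, "season_c", "season2")
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

.fitOnce <- function(fixed, d, hasRe, bySex, method = "REML") {
  if (hasRe) {
    wt <- if (bySex) varIdent(form = ~ 1 | sex) else NULL
    lme(fixed, random = ~ 1 | subspecies, weights = wt, data = d,
        method = method,
        control = lmeControl(opt = "optim", returnObject = TRUE))
  } else if (bySex) {
    gls(fixed, weights = varIdent(form = ~ 1 | sex), data = d,
        method = method)
  } else {
    lm(fixed, data = d)
  }
}

.fixefTable <- function(fit) {
  if (inherits(fit, "lme")) {
    tt <- summary(fit)$tTable
    data.frame(term = rownames(tt), estimate = tt[, "Value"],
               se = tt[, "Std.Error"], row.names = NULL)
  } else if (inherits(fit, "gls")) {
    tt <- summary(fit)$tTable
    data.frame(term = rownames(tt), estimate = tt[, "Value"],
               se = tt[, "Std.Error"], row.names = NULL)
  } else {
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               row.names = NULL)
  }
}

#' Choose between homoscedastic and sex-stratified residual variances
#'
#' Fits the model with a single residual variance and with one residual
#' variance per sex (both by maximum likelihood) and adopts the
#' stratified structure only if it improves AIC by more than 2; ties and
#' small differences keep the simpler model.
#'
#' @param fixed model formula (standardised predictors).
#' @param d prepared data.
#' @param hasRe whether a subspecies random intercept is used.
#' @return list with \code{bySex} (logical) and the two AIC values.
#' @export
selectVarianceStructure <- function(fixed, d, hasRe) {
  homo <- .fitOnce(fixed, d, hasRe, bySex = FALSE, method = "ML")
  strat <- tryCatch(.fitOnce(fixed, d, hasRe, bySex = TRUE, method = "ML"),
                    error = function(e) NULL)
  aicHomo <- AIC(homo)
  aicStrat <- if (is.null(strat)) Inf else AIC(strat)
  list(bySex = is.finite(aicStrat) && (aicHomo - aicStrat) > 2,
       aic = c(homoscedastic = aicHomo, by_sex = aicStrat))
}

#' Fit the per-species temporal linear mixed model
#'
#' REML linear mixed model of one trait against decade of collection,
#' controlling for sex and altitude (and, for colour, season and
#' season squared, capturing post-molt abrasion), with a subspecies
#' random intercept and a residual autocovariate (RAC) replacing raw
#' coordinates. The model is fitted in two stages: first without the
#' RAC, then refitted with the RAC computed from the first-stage
#' residuals. Continuous predictors are standardised internally;
#' coefficients are reported on their original scales. Wald t tests use
#' df = n - (number of fixed coefficients).
#'
#' @param records specimen data.frame (filtered, one species) with
#'   columns for the response, \code{decade}, \code{sex},
#'   \code{altitude}, \code{latitude}, \code{longitude},
#'   \code{subspecies}, and \code{season} for colour.
#' @param response \code{"wing_length"} or \code{"pc1"}.
#' @param useRac apply the two-stage RAC correction.
#' @param racCell RAC raster cell size in degrees.
#' @param varStruct \code{"auto"} (AIC selection), \code{"homoscedastic"}
#'   or \code{"by_sex"}.
#' @return object of class \code{carotrendLmm}: list with the fitted
#'   model, a coefficient table on original scales (estimate, se, df, t,
#'   p), residuals, the RAC values, and bookkeeping.
#' @export
fitLmm <- function(records, response = c("wing_length", "pc1"),
                   useRac = TRUE, racCell = 1,
                   varStruct = c("auto", "homoscedastic", "by_sex")) {
  response <- match.arg(response)
  varStruct <- match.arg(varStruct)
  includeSeason <- response == "pc1"
  d <- .prepPredictors(records, response, includeSeason)

  hasRe <- nlevels(d$subspecies) >= 2L
  if (!hasRe && length(unique(records$subspecies)) > 1L)
    warning("fewer than 2 subspecies levels after filtering; ",
            "random intercept dropped")

  std <- .standardize(d, c("dec10", "altitude"))
  d <- std$data; scales <- std$scales

  ## stage 1: no RAC
  f1 <- .fixedFormula(response, includeSeason, useRac = FALSE)
  .checkDesign(f1, d)
  fit1 <- .fitOnce(f1, d, hasRe, bySex = FALSE)
  rac <- NULL
  if (useRac) {
    r1 <- resid(fit1, type = "response")
    rac <- computeRac(as.numeric(r1), d$latitude, d$longitude, cell = racCell)
    d$rac <- rac
    if (sd(rac) == 0) {
      useRac <- FALSE           # degenerate geometry: RAC uninformative
      warning("RAC has zero variance; spatial term dropped")
    } else {
      std2 <- .standardize(d, "rac")
      d <- std2$data; scales$rac <- std2$scales$rac
    }
  }
  fixed <- .fixedFormula(response, includeSeason, useRac)
  .checkDesign(fixed, d)

  bySex <- switch(varStruct,
    homoscedastic = FALSE,
    by_sex = TRUE,
    auto = selectVarianceStructure(fixed, d, hasRe)$bySex)
  fit <- .fitOnce(fixed, d, hasRe, bySex, method = "REML")

  tab <- .fixefTable(fit)
  ## back-transform standardised slopes to original predictor units
  for (cl in names(scales)) {
    zi <- tab$term == paste0(cl, "_z")
    tab$estimate[zi] <- tab$estimate[zi] / scales[[cl]]["scale"]
    tab$se[zi] <- tab$se[zi] / scales[[cl]]["scale"]
    tab$term[zi] <- cl
  }
  n <- nrow(d)
  tab$df <- n - nrow(tab)
  tab$t <- tab$estimate / tab$se
  tab$p <- 2 * pt(-abs(tab$t), tab$df)

  structure(list(
    fit = fit, coefficients = tab, n = n, response = response,
    residuals = as.numeric(resid(fit, type = "response")),
    data = d, rac = rac, bySex = bySex, hasRe = hasRe, scales = scales
  ), class = "carotrendLmm")
}

#' @export
print.carotrendLmm <- function(x, ...) {
  cat(sprintf("Temporal mixed model: %s, n = %d%s%s\n", x$response, x$n,
              if (x$hasRe) ", subspecies random intercept" else "",
              if (x$bySex) ", sex-stratified residual variance" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Extract the per-year temporal effect from a fitted model
#'
#' Converts the decade-scale slope to trait units per year (decade
#' coefficient / 10, SE likewise); t, df and p are carried over from the
#' Wald test (the t statistic is scale-invariant).
#'
#' @param fit a \code{carotrendLmm} from [fitLmm()].
#' @param species species label for the output row.
#' @param edf optional effective degrees of freedom from [fitGamm()].
#' @return one-row data.frame: species, trait, edf, beta (units/year),
#'   se, df, t, p.
#' @export
extractEffect <- function(fit, species = NA_character_, edf = NA_real_) {
  tab <- fit$coefficients
  row <- tab[tab$term == "dec10", , drop = FALSE]
  if (nrow(row) != 1L) stop("decade coefficient not found in model")
  data.frame(
    species = species, trait = fit$response, edf = edf,
    beta = row$estimate / 10, se = row$se / 10,
    df = row$df, t = row$t, p = row$p,
    stringsAsFactors = FALSE
  )
}

#' Penalized-spline screen for nonlinear temporal change
#'
#' Generalized additive mixed model with the same covariates as
#' [fitLmm()] but a penalized cubic regression spline on year of
#' collection (basis dimension 10, smoothing parameter by REML; the
#' subspecies random intercept enters as a random-effect smooth). The
#' effective degrees of freedom (EDF) of the year smooth measure
#' departure from linearity: EDF near 1 is linear, above 3 clearly
#' nonlinear.
#'
#' @param records one species' specimen data.frame (needs \code{year}).
#' @param response \code{"wing_length"} or \code{"pc1"}.
#' @param useRac include the residual autocovariate (computed by a
#'   first-pass smooth model when no \code{rac} column is present).
#' @param racCell RAC cell size, degrees.
#' @param k basis dimension of the year spline.
#' @param sp optional fixed smoothing parameter for the year smooth
#'   (other smooths keep REML selection); large values force the year
#'   smooth to linearity.
#' @return list with \code{edf}, \code{nonlinear} (EDF > 3) and the
#'   mgcv fit.
#' @export
fitGamm <- function(records, response = c("wing_length", "pc1"),
                    useRac = TRUE, racCell = 1, k = 10, sp = NULL) {
  response <- match.arg(response)
  includeSeason <- response == "pc1"
  if (is.null(records$year)) stop("records need a 'year' column")
  d <- .prepPredictors(records, response, includeSeason)
  if (length(unique(d$year)) < 15L)
    stop("GAMM needs at least 15 distinct collection years")
  std <- .standardize(d, "altitude")
  d <- std$data
  hasRe <- nlevels(d$subspecies) >= 2L

  rhs <- sprintf("s(year, bs = 'cr', k = %d)", k)
  covs <- c("sex", "altitude_z")
  if (includeSeason) covs <- c(covs, "season_c", "season2")
  base <- paste(c(rhs, covs), collapse = " + ")
  if (hasRe) base <- paste(base, "+ s(subspecies, bs = 're')")

  if (useRac && is.null(d$rac)) {
    f0 <- as.formula(paste(response, "~", base))
    fit0 <- mgcv::gam(f0, data = d, method = "REML")
    d$rac <- computeRac(resid(fit0, type = "response"),
                        d$latitude, d$longitude, cell = racCell)
  }
  if (useRac && sd(d$rac) > 0) base <- paste(base, "+ rac")
  f <- as.formula(paste(response, "~", base))
  spVec <- NULL
  if (!is.null(sp)) {
    ## the year smooth is first in the formula; -1 leaves the rest to REML
    spVec <- c(sp[1], if (hasRe) -1)
  }
  fit <- mgcv::gam(f, data = d, method = "REML", sp = spVec)
  st <- summary(fit)$s.table
  edf <- unname(st[grep("^s\\(year", rownames(st)), "edf"][1])
  list(edf = edf, nonlinear = edf > 3, fit = fit)
}

#' Per-species temporal effects for every species in a study
#'
#' Runs [fitLmm()] (slope, SE, Wald test) and [fitGamm()] (EDF) for each
#' species and stacks the [extractEffect()] rows into the standard
#' per-species results table.
#'
#' @param records filtered specimen data.frame with a \code{species}
#'   column (and \code{pc1} when \code{response = "pc1"}).
#' @param response trait to model.
#' @param gamm also run the nonlinearity screen (needs >= 15 distinct
#'   years per species).
#' @param ... passed to [fitLmm()].
#' @return data.frame, one row per species: species, trait, edf, beta,
#'   se, df, t, p.
#' @export
fitSpeciesEffects <- function(records, response = c("wing_length", "pc1"),
                              gamm = TRUE, ...) {
  response <- match.arg(response)
  rows <- lapply(split(records, records$species), function(d) {
    fit <- fitLmm(d, response, ...)
    edf <- if (gamm)
      tryCatch(fitGamm(d, response)$edf, error = function(e) NA_real_)
    else NA_real_
    extractEffect(fit, species = d$species[1], edf = edf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
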
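## Shared fixtures, all built in code.

## flat spectrum at a given reflectance level
flatSpectrum <- function(level = 1) {
  data.frame(wavelength = spectralGrid(), reflectance = level)
}

## visual system with boxcar sensitivities and flat irradiance, for
## closed-form integral oracles
boxcarVisualSystem <- function() {
  wl <- spectralGrid()
  box <- function(lo, hi) as.numeric(wl >= lo & wl <= hi)
  sens <- cbind(vs = box(300, 400), s = box(400, 500),
                m = box(500, 600), l = box(600, 700))
  visualSystem(sensitivities = sens, irradiance = rep(1, length(wl)))
}

## random positive quantum-catch quadruple (as returned by quantumCatch)
randomCatch <- function() {
  q <- exp(rnorm(4, 0, 1))
  list(Q = q, qn = q, f = log(q))
}

## minimal specimen records with a known linear trend, no nuisance
## structure unless asked for
makeRecords <- function(n = 150, slope = 0, sd = 1, seed = 1,
                        intercept = 65, twoSubspecies = TRUE,
                        sexEffect = 0, spatial = FALSE) {
  set.seed(seed)
  year <- round(runif(n, 1900, 2008))
  lon <- runif(n, 115, 153)
  lat <- runif(n, -43, -11)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  month <- sample(1:12, n, replace = TRUE)
  resp <- intercept + slope * (year - 1954) + sexEffect * (sex == "male") +
    rnorm(n, 0, sd)
  if (spatial) resp <- resp + 0.05 * (lon - mean(lon))
  data.frame(
    specimen_id = sprintf("s%04d", seq_len(n)), species = "spA",
    subspecies = if (twoSubspecies) ifelse(lon < 134, "w", "e") else "nominate",
    year = year, decade = decadeFromYear(year),
    latitude = lat, longitude = lon,
    altitude = runif(n, 0, 1500), sex = sex, month = month,
    season = seasonFromMonth(month), wing_length = resp, pc1 = resp,
    stringsAsFactors = FALSE
  )
}

## a small labelled identity correlation matrix
starCorr <- function(labels) {
  A <- diag(length(labels))
  dimnames(A) <- list(labels, labels)
  A
}

## synthetic MetaChain with prescribed variance draws, for the algebraic
## I2 / signal identities
chainWithVariances <- function(sigma2p, sigma2s, sigma2m = 1) {
  n <- length(sigma2p)
  new("MetaChain",
      samples = cbind(mu = rnorm(n), sigma2_p = sigma2p, sigma2_s = sigma2s),
      sigma2m = sigma2m, model = "intercept")
}
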
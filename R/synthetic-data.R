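## Synthetic-study generator: trees, species-level true temporal effects,
## specimen records with spatial and seasonal structure, and
## carotenoid-like reflectance spectra, all with known ground truth.

#' Fan a master seed out to per-stage child seeds
#'
#' Deterministic derivation of stage seeds from one master seed, keeping
#' every derived seed a valid positive 32-bit integer.
#'
#' @param master integer master seed.
#' @param offset integer stage offset.
#' @return a derived integer seed.
#' @export
childSeed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset * 104729) %% 2147483629 + 1)
}

#' Configuration of a synthetic museum-specimen study
#'
#' Returns the full parameter set of the generator. The defaults emulate
#' the real study's conditions: 15 species, 65-162 specimens per
#' species collected 1900-2008 across a continental extent, a weak
#' overall size decline with large between-species heterogeneity and low
#' phylogenetic signal, sex and altitude effects on wing length,
#' seasonal abrasion effects on colour, spatially autocorrelated
#' residuals, duplicate wing measurements with small measurement error,
#' and carotenoid-like reflectance spectra whose 450-nm absorption depth
#' carries the planted colour trend.
#'
#' @param nSpecies number of species.
#' @param muStar true meta-analytic mean wing trend (mm/year).
#' @param sigma2p,sigma2s true phylogenetic and non-phylogenetic
#'   between-species variances of the wing trend ((mm/year)^2).
#' @param colourSigma2 between-species variance of the colour-depth
#'   trend ((depth %/year)^2; mean 0).
#' @param nSpecimenRange min/max specimens per species.
#' @param yearRange collection-year span.
#' @param lonRange,latRange sampling box (decimal degrees).
#' @param altRange altitude range (m).
#' @param sexEffect male-female wing difference (mm).
#' @param altEffect wing change per metre altitude (mm/m).
#' @param residSd residual wing SD (mm); \code{residSdMale} optionally
#'   different for a heteroscedastic study.
#' @param spatialSill,spatialRange SD (mm) and e-folding range (degrees)
#'   of the exponential-covariance spatial field.
#' @param measureSd SD of one wing measurement around the specimen's
#'   true wing (mm); drives repeatability.
#' @param wingInterceptRange species mean wing length range (mm).
#' @param subspEffect subspecies intercept offset (mm).
#' @param spectrumBase,spectrumPlateau short- and long-wave reflectance
#'   levels (percent).
#' @param sigmoidMid,sigmoidSlope midpoint (nm) and slope (nm) of the
#'   sigmoid rise.
#' @param depth0 baseline carotenoid absorption depth (percent).
#' @param seasonDepth,seasonDepth2 linear and quadratic effect of
#'   (centred) season on absorption depth (abrasion curve).
#' @param replicateSd replicate spectral noise SD (percent).
#' @param masterSeed master RNG seed.
#' @return a named list of class \code{studyConfig}.
#' @export
studyConfig <- function(nSpecies = 15,
                        muStar = -0.007,
                        sigma2p = 1e-5,
                        sigma2s = 6e-5,
                        colourSigma2 = 4e-4,
                        nSpecimenRange = c(65, 162),
                        yearRange = c(1900, 2008),
                        lonRange = c(115, 153),
                        latRange = c(-43, -11),
                        altRange = c(0, 1500),
                        sexEffect = 1.5,
                        altEffect = 0.001,
                        residSd = 1.5,
                        residSdMale = NULL,
                        spatialSill = 0.8,
                        spatialRange = 5,
                        measureSd = 0.25,
                        wingInterceptRange = c(55, 75),
                        subspEffect = 1,
                        spectrumBase = 10,
                        spectrumPlateau = 50,
                        sigmoidMid = 490,
                        sigmoidSlope = 25,
                        depth0 = 8,
                        seasonDepth = -0.3,
                        seasonDepth2 = -0.05,
                        replicateSd = 0.5,
                        masterSeed = 20260101) {
  cfg <- as.list(environment())
  stopifnot(cfg$sigma2p >= 0, cfg$sigma2s >= 0,
            cfg$yearRange[1] >= 1900, cfg$yearRange[2] <= 2008)
  class(cfg) <- "studyConfig"
  cfg
}

#' Simulate an ultrametric study phylogeny
#'
#' Pure-birth tree over the study species, rescaled to unit depth.
#' Deterministic given the seed.
#'
#' @param nSpecies number of tips.
#' @param seed RNG seed.
#' @return an ultrametric \code{ape::phylo} with tip labels
#'   \code{sp01..spNN} and depth 1.
#' @export
simulateTree <- function(nSpecies, seed = 1) {
  set.seed(seed)
  tree <- ape::rphylo(nSpecies, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(nSpecies))
  tree
}

#' Simulate true per-species temporal effects on a phylogeny
#'
#' Draws species slopes from the meta-analytic generating model:
#' \eqn{slope_i = \mu^* + a_i + u_i} with \eqn{a \sim N(0, \sigma^2_p A)}
#' (A the Brownian correlation matrix of the tree) and
#' \eqn{u_i \sim N(0, \sigma^2_s)}.
#'
#' @param tree an \code{ape::phylo}.
#' @param muStar true mean (units/year).
#' @param sigma2p,sigma2s variance components.
#' @param seed RNG seed.
#' @return named numeric of true slopes, one per tip.
#' @export
simulateSpeciesEffects <- function(tree, muStar, sigma2p, sigma2s, seed = 1) {
  A <- phyloCorrelation(tree)
  set.seed(seed)
  n <- nrow(A)
  a <- if (sigma2p > 0)
    as.numeric(mvrnorm(1, mu = rep(0, n), Sigma = sigma2p * A))
  else numeric(n)
  u <- rnorm(n, 0, sqrt(sigma2s))
  setNames(muStar + a + u, rownames(A))
}

.spatialField <- function(lat, lon, sill, range, seed) {
  if (sill <= 0) return(numeric(length(lat)))
  set.seed(seed)
  d <- as.matrix(dist(cbind(lon, lat)))
  S <- sill^2 * exp(-d / range)
  diag(S) <- sill^2 + 1e-8
  as.numeric(t(chol(S)) %*% rnorm(length(lat)))
}

#' Simulate one species' specimen records
#'
#' Years uniform over the span; locations uniform in the sampling box;
#' a Gaussian spatial field with exponential covariance added to the
#' wing residuals; wing length built from the species intercept, the
#' planted temporal slope (about year 1954), sex, altitude and
#' subspecies effects (two subspecies split at the species' median
#' longitude); two wing measurements per specimen with independent
#' measurement error; carotenoid absorption depth built from the
#' planted colour-depth slope plus the seasonal abrasion curve.
#'
#' @param species species label.
#' @param wingSlope planted wing trend (mm/year).
#' @param depthSlope planted colour-depth trend (percent/year).
#' @param cfg a [studyConfig()].
#' @param seed RNG seed.
#' @param n number of specimens (default drawn from the config range).
#' @return data.frame of specimen records with true values attached as
#'   columns \code{true_wing} and \code{depth}.
#' @export
simulateSpecimens <- function(species, wingSlope, depthSlope, cfg,
                              seed = 1, n = NULL) {
  set.seed(seed)
  if (is.null(n))
    n <- sample(seq(cfg$nSpecimenRange[1], cfg$nSpecimenRange[2]), 1)
  year <- round(runif(n, cfg$yearRange[1], cfg$yearRange[2]))
  lon <- runif(n, cfg$lonRange[1], cfg$lonRange[2])
  lat <- runif(n, cfg$latRange[1], cfg$latRange[2])
  alt <- runif(n, cfg$altRange[1], cfg$altRange[2])
  sex <- sample(c("male", "female"), n, replace = TRUE)
  month <- sample(1:12, n, replace = TRUE)
  subsp <- ifelse(lon < median(lon), "western", "eastern")
  yr0 <- mean(cfg$yearRange)

  intercept <- runif(1, cfg$wingInterceptRange[1], cfg$wingInterceptRange[2])
  sdResid <- rep(cfg$residSd, n)
  if (!is.null(cfg$residSdMale)) sdResid[sex == "male"] <- cfg$residSdMale
  spat <- .spatialField(lat, lon, cfg$spatialSill, cfg$spatialRange,
                        childSeed(seed, 17))
  trueWing <- intercept + wingSlope * (year - yr0) +
    cfg$sexEffect * (sex == "male") + cfg$altEffect * alt +
    cfg$subspEffect * (subsp == "eastern") + spat +
    rnorm(n, 0, sdResid)
  wing1 <- trueWing + rnorm(n, 0, cfg$measureSd)
  wing2 <- trueWing + rnorm(n, 0, cfg$measureSd)

  seasonC <- seasonFromMonth(month) - 3.5
  depth <- pmax(cfg$depth0 + depthSlope * (year - yr0) +
                cfg$seasonDepth * seasonC + cfg$seasonDepth2 * seasonC^2, 0)

  data.frame(
    specimen_id = sprintf("%s_%04d", species, seq_len(n)),
    species = species, subspecies = subsp, year = year,
    latitude = lat, longitude = lon, altitude = alt,
    sex = sex, month = month,
    season = seasonFromMonth(month), decade = decadeFromYear(year),
    wing1 = wing1, wing2 = wing2, wing_length = (wing1 + wing2) / 2,
    juvenile = FALSE, molting = FALSE, damaged = FALSE, unsexed = FALSE,
    true_wing = trueWing, depth = depth,
    stringsAsFactors = FALSE
  )
}

#' Simulate replicate carotenoid-like reflectance spectra
#'
#' A low short-wave baseline rising sigmoidally to a long-wave plateau,
#' minus a Gaussian carotenoid absorption trough centred at 450 nm
#' (SD 30 nm) of the given depth, clamped at zero; replicates add
#' independent Gaussian noise. Increasing \code{depth} strictly
#' increases carotenoid chroma.
#'
#' @param depth absorption depth (percent reflectance units).
#' @param cfg a [studyConfig()] supplying the shape parameters.
#' @param seed RNG seed.
#' @param nRep number of replicates (5 by default).
#' @return list of \code{nRep} spectrum data.frames on the 1-nm grid.
#' @export
simulateSpectrum <- function(depth, cfg = studyConfig(), seed = 1,
                             nRep = 5) {
  wl <- spectralGrid()
  base <- cfg$spectrumBase +
    (cfg$spectrumPlateau - cfg$spectrumBase) *
      plogis((wl - cfg$sigmoidMid) / cfg$sigmoidSlope) -
    depth * exp(-(wl - 450)^2 / (2 * 30^2))
  set.seed(seed)
  lapply(seq_len(nRep), function(i) {
    refl <- pmax(base + rnorm(length(wl), 0, cfg$replicateSd), 0)
    data.frame(wavelength = wl, reflectance = refl)
  })
}

#' Simulate a complete synthetic study
#'
#' Tree, true species effects, specimen records for every species, and
#' (optionally) replicate reflectance spectra per specimen.
#'
#' @param cfg a [studyConfig()].
#' @param spectra also generate the per-specimen replicate spectra
#'   (memory-heavier; needed for the full colour pipeline).
#' @return list with \code{tree}, \code{records} (all species stacked),
#'   \code{truth} (per-species true wing and colour-depth slopes), and
#'   when requested \code{spectra} (a list, one entry of 5 replicate
#'   spectra per specimen, named by specimen_id).
#' @export
simulateStudy <- function(cfg = studyConfig(), spectra = FALSE) {
  tree <- simulateTree(cfg$nSpecies, childSeed(cfg$masterSeed, 1))
  wingSlopes <- simulateSpeciesEffects(tree, cfg$muStar, cfg$sigma2p,
                                       cfg$sigma2s,
                                       childSeed(cfg$masterSeed, 2))
  set.seed(childSeed(cfg$masterSeed, 3))
  depthSlopes <- setNames(
    rnorm(cfg$nSpecies, 0, sqrt(cfg$colourSigma2)), tree$tip.label)

  recs <- lapply(seq_len(cfg$nSpecies), function(i) {
    sp <- tree$tip.label[i]
    simulateSpecimens(sp, wingSlopes[[sp]], depthSlopes[[sp]], cfg,
                      seed = childSeed(cfg$masterSeed, 100 + i))
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  out <- list(tree = tree,
              records = records,
              truth = data.frame(species = tree$tip.label,
                                 wing_slope = as.numeric(wingSlopes),
                                 depth_slope = as.numeric(depthSlopes)))
  if (spectra) {
    out$spectra <- setNames(lapply(seq_len(nrow(records)), function(j) {
      simulateSpectrum(records$depth[j], cfg,
                       seed = childSeed(cfg$masterSeed, 10000 + j))
    }), records$specimen_id)
  }
  out
}

#' Write a synthetic study to disk in the reader formats
#'
#' Emits exactly the files the readers consume: the specimen table
#' (\code{specimens.csv}), one two-column text file per replicate
#' spectrum (\code{<specimen_id>_<k>.txt} under \code{spectra/}), the
#' tree (\code{tree.nwk}), and a plain-text echo of the configuration.
#'
#' @param cfg a [studyConfig()].
#' @param dir output directory (created).
#' @param spectra write the replicate spectra too (many small files).
#' @return invisibly, the study list from [simulateStudy()].
#' @export
generateStudy <- function(cfg = studyConfig(), dir, spectra = TRUE) {
  study <- simulateStudy(cfg, spectra = spectra)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(study$records, file.path(dir, "specimens.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(x) paste(x, collapse = " "), "")),
             file.path(dir, "config_echo.txt"))
  if (spectra) {
    spDir <- file.path(dir, "spectra")
    dir.create(spDir, showWarnings = FALSE)
    for (id in names(study$spectra)) {
      reps <- study$spectra[[id]]
      for (kk in seq_along(reps)) {
        write.table(reps[[kk]], file.path(spDir, sprintf("%s_%d.txt", id, kk)),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(study)
}
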
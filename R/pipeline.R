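## End-to-end orchestration: colour scoring, per-species models,
## meta-analysis, and the meta-only entry point for published effect
## sizes.

#' Bundled fixture phylogeny of the 15 study species
#'
#' A synthetic stand-in for the study's real posterior tree sample: the
#' study-species topology (assembled from family- and genus-level
#' taxonomy) with Grafen branch lengths rescaled to unit depth, or a
#' star tree for sensitivity runs. Because the estimated phylogenetic
#' signal of the temporal effects is near zero, results are insensitive
#' to the branch-length details.
#'
#' @param mode \code{"topology"} (ultrametric fixture) or \code{"star"}.
#' @return an \code{ape::phylo} of depth 1.
#' @export
fixtureTree <- function(mode = c("topology", "star")) {
  mode <- match.arg(mode)
  path <- system.file("extdata", "fixture_tree_synthetic.nwk",
                      package = "carotrend")
  tree <- ape::read.tree(path)
  if (mode == "star") {
    star <- ape::stree(length(tree$tip.label), type = "star")
    star$tip.label <- tree$tip.label
    star$edge.length <- rep(1, nrow(star$edge))
    return(star)
  }
  tree <- ape::compute.brlen(tree, method = "Grafen")
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Bundled per-species temporal effect sizes
#'
#' The published per-species slopes (trait units per year), standard
#' errors and GAMM effective degrees of freedom for wing length and
#' plumage-colour PC1 across the 15 study species; the input of the
#' across-species meta-analytic stage.
#'
#' @param trait \code{"wing"} or \code{"colour"}.
#' @param excludeNonlinear drop species whose GAMM EDF for this trait
#'   exceeds 3 (strongly nonlinear temporal pattern).
#' @param moderatorTrait optional second trait whose slopes are attached
#'   as the meta-regression moderator.
#' @return an [EffectSizeSet-class].
#' @export
fixtureEffects <- function(trait = c("wing", "colour"),
                           excludeNonlinear = FALSE,
                           moderatorTrait = NULL) {
  trait <- match.arg(trait)
  path <- system.file("extdata", "meliphagoidea_temporal_effects.tsv",
                      package = "carotrend")
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tw <- df[df$trait == trait, ]
  keep <- tw$species
  if (excludeNonlinear) keep <- tw$species[tw$edf <= 3]
  tw <- tw[tw$species %in% keep, ]
  moderator <- NULL
  if (!is.null(moderatorTrait)) {
    tm <- df[df$trait == moderatorTrait, ]
    moderator <- tm$beta[match(tw$species, tm$species)]
  }
  effectSizeSet(tw$species, tw$beta, tw$se, moderator = moderator)
}

#' Meta-analysis directly from a table of effect sizes
#'
#' The meta-only entry point: accepts an [EffectSizeSet-class] (or a
#' delimited file with columns species, beta, se) plus a phylogeny, and
#' runs the chained Bayesian phylogenetic meta-analysis. A single tree
#' is replicated \code{nTrees} times, which is equivalent to one long
#' chain sampled every \code{itersPerTree} iterations.
#'
#' @param effects an [EffectSizeSet-class] or path to an effects table.
#' @param trees a tree, a list of trees, or NULL for the bundled fixture
#'   topology.
#' @param nTrees number of chained tree runs when a single tree is
#'   given.
#' @param burninTrees trees discarded as burn-in.
#' @param itersPerTree iterations per tree.
#' @param seed integer seed.
#' @param regression fit the moderator slope instead of the intercept
#'   only.
#' @return list with \code{chain} ([MetaChain-class]) and \code{result}
#'   ([MetaResult-class]).
#' @export
metaOnly <- function(effects, trees = NULL, nTrees = 130, burninTrees = 30,
                     itersPerTree = 1000, seed = 1, regression = FALSE) {
  if (is.character(effects)) effects <- readEffectSizes(effects)
  if (is.null(trees)) trees <- fixtureTree()
  if (inherits(trees, "phylo")) trees <- rep(list(trees), nTrees)
  chain <- runTreeSet(effects, trees, itersPerTree = itersPerTree,
                      burninTrees = burninTrees, seed = seed,
                      regression = regression)
  list(chain = chain, result = summarizeMeta(chain))
}

#' Score specimens through the visual model and chromatic PCA
#'
#' Converts each specimen's replicate reflectance spectra into mean xyz
#' chromatic coordinates and carotenoid chroma, then summarises them to
#' per-species PC1 scores (sign-anchored to chroma).
#'
#' @param records specimen data.frame.
#' @param spectra named list (by specimen_id) of replicate-spectrum
#'   lists.
#' @param vs a [VisualSystem-class].
#' @return records with columns \code{chroma} and \code{pc1} appended.
#' @export
scoreColour <- function(records, spectra, vs = visualSystem()) {
  ids <- records$specimen_id
  miss <- setdiff(ids, names(spectra))
  if (length(miss))
    stop("no spectra for specimen(s): ", paste(head(miss, 5), collapse = ", "))
  noise <- receptorNoise(vs)
  map <- coordinateMap(noise)
  coords <- matrix(NA_real_, nrow(records), 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  chroma <- numeric(nrow(records))
  for (i in seq_along(ids)) {
    reps <- lapply(spectra[[ids[i]]], cleanAndResample)
    cc <- vapply(reps, function(sp)
      chromaticCoords(quantumCatch(sp, vs), noise, map), numeric(3))
    coords[i, ] <- rowMeans(cc)
    meanSpec <- reps[[1]]
    meanSpec$reflectance <- rowMeans(vapply(reps, `[[`, "reflectance",
                                            FUN.VALUE = numeric(nrow(reps[[1]]))))
    chroma[i] <- carotenoidChroma(meanSpec)
  }
  records$chroma <- chroma
  scoreChromaticPc1(records, coords, chroma)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage end to end: specimen curation, visual-model
#' colour scoring, per-species temporal models for both traits (with
#' RAC correction and GAMM screening), and the phylogenetic
#' meta-analytic stage (two intercept-only models plus the
#' effect-on-effect meta-regression), optionally repeating the
#' meta-stage with strongly nonlinear species (EDF > 3) excluded.
#'
#' @param study a study list from [simulateStudy()] (with spectra), or
#'   NULL to simulate one from \code{cfg}.
#' @param cfg a [studyConfig()] used when \code{study} is NULL.
#' @param vs visual system for colour scoring.
#' @param nTrees,burninTrees,itersPerTree,seed MCMC settings for the
#'   meta stage.
#' @param excludeNonlinear also run the meta stage without EDF > 3
#'   species.
#' @param gamm run the GAMM screen (needs >= 15 distinct years per
#'   species).
#' @param outDir optional directory for the per-species results table
#'   and meta summaries.
#' @return list with \code{records}, \code{effects} (per-species table,
#'   both traits), \code{meta} (wing and colour [MetaResult-class]s and
#'   the regression), and when requested \code{metaLinearOnly}.
#' @export
runPipeline <- function(study = NULL, cfg = studyConfig(),
                        vs = visualSystem(),
                        nTrees = 130, burninTrees = 30, itersPerTree = 1000,
                        seed = cfg$masterSeed %% 100000,
                        excludeNonlinear = FALSE, gamm = TRUE,
                        outDir = NULL) {
  if (is.null(study)) study <- simulateStudy(cfg, spectra = TRUE)
  if (is.null(study$spectra)) stop("study has no spectra; rerun simulateStudy(spectra = TRUE)")
  records <- filterSpecimens(study$records, quiet = TRUE)
  records <- scoreColour(records, study$spectra, vs)

  wingEff <- fitSpeciesEffects(records, "wing_length", gamm = gamm)
  colEff <- fitSpeciesEffects(records, "pc1", gamm = gamm)
  effects <- rbind(wingEff, colEff)

  trees <- rep(list(study$tree), nTrees)
  runMeta <- function(eff, regression = FALSE, moderator = NULL, off = 0) {
    es <- effectSizeSet(eff$species, eff$beta, eff$se, moderator = moderator)
    chain <- runTreeSet(es, trees, itersPerTree = itersPerTree,
                        burninTrees = burninTrees,
                        seed = childSeed(seed, off), regression = regression)
    summarizeMeta(chain)
  }
  meta <- list(
    wing = runMeta(wingEff, off = 1),
    colour = runMeta(colEff, off = 2),
    regression = runMeta(wingEff, regression = TRUE,
                         moderator = colEff$beta[match(wingEff$species,
                                                       colEff$species)],
                         off = 3)
  )
  out <- list(records = records, effects = effects, meta = meta)

  if (excludeNonlinear) {
    lin <- function(eff) eff[is.na(eff$edf) | eff$edf <= 3, ]
    wl <- lin(wingEff); cl <- lin(colEff)
    common <- intersect(wl$species, cl$species)
    out$metaLinearOnly <- list(
      wing = runMeta(wl, off = 4),
      colour = runMeta(cl, off = 5),
      regression = runMeta(wl[wl$species %in% common, ], regression = TRUE,
                           moderator = cl$beta[match(common, cl$species)],
                           off = 6)
    )
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(effects, file.path(outDir, "species_effects.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    sink(file.path(outDir, "meta_summary.txt"))
    for (nm in names(meta)) { cat("==", nm, "==\n"); show(meta[[nm]]) }
    sink()
  }
  out
}
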
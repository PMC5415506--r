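test_that("simulated trees are deterministic unit-depth ultrametric trees", {
  t1 <- simulateTree(15, seed = 71)
  t2 <- simulateTree(15, seed = 71)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 15L)
  expect_equal(t1$Nnode, 14L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-10)

  C2 <- phyloCorrelation(simulateTree(2, seed = 72))
  expect_equal(dim(C2), c(2L, 2L))
  expect_equal(unname(diag(C2)), c(1, 1))
})

test_that("species effects follow the planted meta-analytic model", {
  tree <- simulateTree(10, seed = 73)
  fixed <- simulateSpeciesEffects(tree, -0.007, 0, 0, seed = 74)
  expect_equal(unname(fixed), rep(-0.007, 10))

  ## star tree: sample variance approaches sigma2p + sigma2s
  star <- ape::stree(800, type = "star")
  star$edge.length <- rep(1, 800)
  star$tip.label <- sprintf("sp%03d", 1:800)
  eff <- simulateSpeciesEffects(star, 0, 4e-5, 6e-5, seed = 75)
  expect_lt(abs(var(eff) / 1e-4 - 1), 0.2)

  ## deep shared branches induce the shared-path correlation
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.9,C:1);")
  draws <- t(vapply(1:800, function(s)
    simulateSpeciesEffects(tr, 0, 1e-4, 0, seed = s), numeric(3)))
  expect_lt(abs(cor(draws[, "A"], draws[, "B"]) - 0.9), 0.08)
  expect_lt(abs(cor(draws[, "A"], draws[, "C"])), 0.12)
})

test_that("specimen generation plants exact structure in the degenerate limit", {
  cfg <- studyConfig(residSd = 0, spatialSill = 0, sexEffect = 0,
                     altEffect = 0, subspEffect = 0, measureSd = 0)
  d <- simulateSpecimens("spA", -0.02, 0, cfg, seed = 76, n = 60)
  trend <- d$wing_length - (d$wing_length[1] - (-0.02) * (d$year[1] - 1954))
  expect_equal(trend, -0.02 * (d$year - 1954), tolerance = 1e-9)
  expect_equal(d$wing1, d$wing2)

  ## measurement error drives repeatability
  cfgM <- studyConfig(measureSd = 1e-6)
  dm <- simulateSpecimens("spA", 0, 0, cfgM, seed = 77, n = 50)
  pr <- data.frame(specimen_id = dm$specimen_id, first = dm$wing1,
                   second = dm$wing2)
  expect_gt(repeatability(pr), 0.999)
})

test_that("without spatial structure residuals show null Moran's I", {
  cfg <- studyConfig(spatialSill = 0)
  d <- simulateSpecimens("spA", 0, 0, cfg, seed = 78, n = 300)
  fit <- fitLmm(d, "wing_length", useRac = FALSE,
                varStruct = "homoscedastic")
  mi <- moransI(fit$residuals, d$latitude, d$longitude)
  expect_lt(abs(mi$observed - mi$expected), 0.03)
})

test_that("synthetic spectra behave like carotenoid reflectance", {
  cfg <- studyConfig(replicateSd = 0)
  pure <- simulateSpectrum(0, cfg, seed = 79, nRep = 1)[[1]]
  withTrough <- simulateSpectrum(8, cfg, seed = 79, nRep = 1)[[1]]
  expect_equal(carotenoidChroma(simulateSpectrum(0, cfg, seed = 1)[[1]]),
               carotenoidChroma(pure))
  expect_gt(carotenoidChroma(withTrough), carotenoidChroma(pure))

  reps <- simulateSpectrum(8, cfg, seed = 80, nRep = 5)
  expect_equal(reps[[1]], reps[[5]])

  cfgN <- studyConfig(replicateSd = 0.5)
  noisy <- simulateSpectrum(8, cfgN, seed = 81, nRep = 5)
  for (sp in noisy) {
    expect_true(all(sp$reflectance >= 0))
    expect_true(all(sp$reflectance <= 100 + 5 * cfgN$replicateSd))
  }
})

test_that("generated studies round-trip through the file readers", {
  cfg <- studyConfig(nSpecies = 3, nSpecimenRange = c(8, 10),
                     masterSeed = 82)
  dir <- file.path(tempdir(), "study82")
  study <- generateStudy(cfg, dir, spectra = TRUE)
  expect_true(file.exists(file.path(dir, "specimens.csv")))
  expect_true(file.exists(file.path(dir, "tree.nwk")))

  rec <- readSpecimenTable(file.path(dir, "specimens.csv"))
  expect_equal(nrow(rec), nrow(study$records))
  expect_equal(sort(unique(rec$species)), sort(study$tree$tip.label))
  expect_equal(rec$season, study$records$season)
  expect_equal(nrow(suppressMessages(filterSpecimens(rec))), nrow(rec))

  id1 <- rec$specimen_id[1]
  sp <- readSpectrum(file.path(dir, "spectra", paste0(id1, "_1.txt")))
  expect_equal(cleanAndResample(sp)$reflectance,
               pmax(study$spectra[[id1]][[1]]$reflectance, 0),
               tolerance = 1e-6)

  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(study$tree$tip.label))
  unlink(dir, recursive = TRUE)
})

test_that("master-seed fan-out is deterministic and in integer range", {
  s1 <- childSeed(123, 1); s2 <- childSeed(123, 1)
  expect_identical(s1, s2)
  expect_true(childSeed(123, 2) != s1)
  seeds <- vapply(1:1000, function(o) childSeed(2^30, o), integer(1))
  expect_true(all(seeds > 0 & seeds < 2^31))
})
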
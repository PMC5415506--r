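test_that("phylogenetic correlation follows shared-branch arithmetic", {
  star <- ape::stree(4, type = "star")
  star$edge.length <- rep(1, 4)
  expect_equal(unname(phyloCorrelation(star)), diag(4))

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phyloCorrelation(tr)
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), rep(1, 3))

  expect_error(phyloCorrelation(tr, species = c("A", "B", "D")), "missing")

  ## depth rescaling leaves the correlation matrix unchanged
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 37
  expect_equal(phyloCorrelation(tr2), C)
})

test_that("typical sampling variance reduces correctly", {
  expect_equal(typicalSamplingVariance(rep(0.37, 8)), 0.37)
  expect_equal(typicalSamplingVariance(c(1, 3)), 2)
  ## direct-formula oracle on the bundled wing SEs
  se <- effectTable(fixtureEffects("wing"))$se
  w <- 1 / se^2
  expect_equal(typicalSamplingVariance(se^2),
               sum(w) * 14 / (sum(w)^2 - sum(w^2)))
  expect_error(typicalSamplingVariance(c(1, 0)), "positive")
})

test_that("the Gibbs sampler is deterministic and nails degenerate data", {
  sp <- sprintf("sp%02d", 1:8)
  es <- effectSizeSet(sp, rep(0.42, 8), rep(1e-4, 8))
  A <- starCorr(sp)
  c1 <- gibbsMeta(es, A, nIter = 3000, burnin = 500, thin = 5, seed = 5)
  c2 <- gibbsMeta(es, A, nIter = 3000, burnin = 500, thin = 5, seed = 5)
  expect_identical(chainSamples(c1), chainSamples(c2))

  r <- summarizeMeta(c1)
  expect_lt(abs(r$estimate - 0.42), 1e-3)
  expect_equal(r$pMCMC, 2 / nrow(chainSamples(c1)))
})

test_that("the sampler recovers planted meta-analytic parameters", {
  set.seed(51)
  k <- 15
  sp <- sprintf("sp%02d", 1:k)
  A <- starCorr(sp)
  hits <- 0; nrep <- 30
  for (r in seq_len(nrep)) {
    mu <- -0.01; s2 <- 5e-5
    se <- runif(k, 0.003, 0.01)
    y <- rnorm(k, mu, sqrt(s2 + se^2))
    es <- effectSizeSet(sp, y, se)
    ch <- gibbsMeta(es, A, nIter = 4000, burnin = 1000, thin = 5,
                    seed = 5000 + r)
    sm <- summarizeMeta(ch)
    if (sm$lower <= mu && mu <= sm$upper) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.85)   # ~95% coverage within binomial error
})

test_that("without phylogeny the posterior mean matches an independent REML fit", {
  skip_if_not_installed("metafor")
  set.seed(52)
  k <- 15
  sp <- sprintf("sp%02d", 1:k)
  v <- rep(4e-5, k)
  y <- rnorm(k, -0.01, sqrt(8e-5 + v[1]))
  es <- effectSizeSet(sp, y, sqrt(v))
  ch <- gibbsMeta(es, starCorr(sp), nIter = 60000, burnin = 5000, thin = 25,
                  seed = 53, includePhylo = FALSE)
  mus <- chainSamples(ch)[, "mu"]
  mcse <- sd(mus) / sqrt(length(mus) / 5)   # conservative ESS guess
  ref <- metafor::rma(yi = y, vi = v, method = "REML")
  expect_lt(abs(mean(mus) - as.numeric(coef(ref))), 3 * mcse)
})

test_that("chained tree runs behave like a thinned long chain", {
  es <- fixtureEffects("wing")
  tr <- fixtureTree()

  expect_error(runTreeSet(es, rep(list(tr), 3), burninTrees = 3), "more trees")

  small <- runTreeSet(es, rep(list(tr), 13), itersPerTree = 200,
                      burninTrees = 3, seed = 54)
  expect_equal(nrow(chainSamples(small)), 10L)

  chained <- runTreeSet(es, rep(list(tr), 80), itersPerTree = 300,
                        burninTrees = 20, seed = 55)
  long <- gibbsMeta(es, phyloCorrelation(tr, speciesNames(es)),
                    nIter = 24000, burnin = 6000, thin = 300, seed = 56)
  m1 <- mean(chainSamples(chained)[, "mu"])
  m2 <- mean(chainSamples(long)[, "mu"])
  se1 <- sd(chainSamples(chained)[, "mu"]) / sqrt(60)
  se2 <- sd(chainSamples(long)[, "mu"]) / sqrt(60)
  expect_lt(abs(m1 - m2), 4 * sqrt(se1^2 + se2^2))
})

test_that("I2 and phylogenetic signal obey their algebraic identities", {
  ch0 <- chainWithVariances(rep(0, 50), rep(0, 50), sigma2m = 1)
  expect_equal(heterogeneityI2(ch0)$mean, 0)
  expect_equal(phyloSignal(ch0)$mean, 0)

  chHalf <- chainWithVariances(rep(0.3, 50), rep(0.7, 50), sigma2m = 1)
  expect_equal(heterogeneityI2(chHalf)$mean, 0.5)
  expect_equal(phyloSignal(chHalf)$mean, 0.3)

  chP <- chainWithVariances(rep(0.4, 50), rep(0, 50), sigma2m = 1)
  expect_equal(phyloSignal(chP)$mean, 1)

  ## bounds hold draw-wise on a real chain
  es <- fixtureEffects("colour")
  ch <- gibbsMeta(es, starCorr(speciesNames(es)), nIter = 2000, burnin = 500,
                  thin = 5, seed = 57)
  i2 <- heterogeneityI2(ch)$draws
  sg <- phyloSignal(ch)$draws
  expect_true(all(i2 >= 0 & i2 <= 1))
  expect_true(all(sg >= 0 & sg <= 1))
})

test_that("planted heterogeneity is recovered", {
  set.seed(58)
  k <- 50
  sp <- sprintf("sp%02d", 1:k)
  v0 <- 2e-5
  tau2 <- 4 * v0          # I2 = 0.8 with equal sampling variances
  y <- rnorm(k, 0, sqrt(tau2 + v0))
  es <- effectSizeSet(sp, y, rep(sqrt(v0), k))
  ch <- gibbsMeta(es, starCorr(sp), nIter = 6000, burnin = 1000, thin = 5,
                  seed = 59)
  expect_lt(abs(heterogeneityI2(ch)$mean - 0.8), 0.1)
})

test_that("strong Brownian structure yields high phylogenetic signal", {
  set.seed(60)
  tree <- simulateTree(50, seed = 61)
  A <- phyloCorrelation(tree)
  a <- as.numeric(MASS::mvrnorm(1, rep(0, 50), 4e-4 * A))
  es <- effectSizeSet(tree$tip.label, a + rnorm(50, 0, 1e-3),
                      rep(1e-3, 50))
  ch <- gibbsMeta(es, A, nIter = 6000, burnin = 1000, thin = 5, seed = 62)
  expect_gt(phyloSignal(ch)$mean, 0.5)
})

test_that("posterior scales with the data (equivariance) and reordering is safe", {
  es <- fixtureEffects("wing")
  tab <- effectTable(es)
  A <- phyloCorrelation(fixtureTree(), tab$species)
  ch1 <- gibbsMeta(es, A, nIter = 8000, burnin = 2000, thin = 10, seed = 63)
  es2 <- effectSizeSet(tab$species, 2 * tab$beta, 2 * tab$se)
  ch2 <- gibbsMeta(es2, A, nIter = 8000, burnin = 2000, thin = 10, seed = 63)
  expect_lt(abs(2 * summarizeMeta(ch1)$estimate - summarizeMeta(ch2)$estimate),
            4e-3)

  perm <- sample(nrow(tab))
  es3 <- effectSizeSet(tab$species[perm], tab$beta[perm], tab$se[perm])
  ch3 <- gibbsMeta(es3, A, nIter = 8000, burnin = 2000, thin = 10, seed = 63)
  expect_lt(abs(summarizeMeta(ch3)$estimate - summarizeMeta(ch1)$estimate),
            3e-3)
})

test_that("meta-regression concentrates on deterministic relations and nulls", {
  sp <- sprintf("sp%02d", 1:12)
  set.seed(64)
  x <- rnorm(12, 0, 0.01)
  es <- effectSizeSet(sp, 2 * x, rep(1e-4, 12), moderator = x)
  ch <- gibbsMeta(es, starCorr(sp), nIter = 4000, burnin = 1000, thin = 5,
                  seed = 65, regression = TRUE)
  b <- summarizeMeta(ch, "b")
  expect_lt(abs(b$estimate - 2), 0.05)

  ## permutation null: slope CI should usually cover zero
  covered <- 0
  for (r in 1:15) {
    y <- rnorm(12, 0, 0.01)
    esn <- effectSizeSet(sp, y, rep(0.005, 12), moderator = sample(x))
    chn <- gibbsMeta(esn, starCorr(sp), nIter = 3000, burnin = 500, thin = 5,
                     seed = 700 + r, regression = TRUE)
    bn <- summarizeMeta(chn, "b")
    if (bn$lower <= 0 && 0 <= bn$upper) covered <- covered + 1
  }
  expect_gte(covered, 12)

  expect_error(gibbsMeta(effectSizeSet(sp, x, rep(1, 12),
                                       moderator = rep(1, 12)),
                         starCorr(sp), regression = TRUE),
               "zero variance")
})

test_that("published wing and colour trends are uncorrelated across species", {
  es <- fixtureEffects("wing", moderatorTrait = "colour")
  out <- metaRegression(es, rep(list(fixtureTree()), 60), itersPerTree = 500,
                        burninTrees = 20, seed = 66)
  ## small slope, credible interval spanning zero
  expect_lt(abs(out$result$estimate), 0.4)
  expect_lt(out$result$lower, 0)
  expect_gt(out$result$upper, 0)
})
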
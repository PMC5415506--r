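test_that("RAC tracks smooth residual fields and vanishes when uninformative", {
  ## smooth planar gradient: the neighbourhood mean approximates the
  ## local residual
  set.seed(31)
  n <- 3000
  lon <- runif(n, 115, 153); lat <- runif(n, -43, -11)
  grad <- 0.3 * (lon - 134) + 0.2 * (lat + 27)
  rac <- computeRac(grad, lat, lon, cell = 1)
  expect_gt(cor(rac, grad), 0.9)

  ## spatially independent residuals: no association
  set.seed(32)
  iid <- rnorm(10000)
  lon2 <- runif(10000, 115, 153); lat2 <- runif(10000, -43, -11)
  rac2 <- computeRac(iid, lat2, lon2, cell = 1)
  expect_lt(abs(cor(rac2, iid)), 0.05)

  ## everyone in one cell
  expect_warning(r0 <- computeRac(rnorm(5), rep(-30.2, 5), rep(140.3, 5)),
                 "one grid cell")
  expect_equal(r0, rep(0, 5))
})

test_that("Moran's I hits its classical benchmarks", {
  ## perfect checkerboard with rook weights
  g <- expand.grid(x = 1:8, y = 1:8)
  val <- (-1)^(g$x + g$y)
  d <- as.matrix(dist(g))
  Wrook <- (abs(d - 1) < 1e-9) * 1
  expect_equal(moransI(val, weights = Wrook)$observed, -1, tolerance = 1e-12)

  ## iid residuals: close to the null expectation -1/(n-1)
  set.seed(33)
  n <- 500
  lon <- runif(n, 0, 10); lat <- runif(n, 0, 10)
  res <- moransI(rnorm(n), lat, lon)
  expect_lt(abs(res$observed - res$expected), 0.05)

  ## smooth gradient along a strip: strong positive autocorrelation
  lonS <- runif(n, 0, 100); latS <- runif(n, 0, 1)
  gradI <- moransI(lonS, latS, lonS)$observed
  expect_gt(gradI, 0.5)
})

test_that("year-mean residual autocorrelation diagnoses AR structure", {
  set.seed(34)
  yrs <- rep(1900:1999, each = 3)
  nullAcf <- replicate(10, residualAcf(rnorm(300), yrs))
  expect_lt(abs(mean(nullAcf)), 0.1)

  ar <- as.numeric(arima.sim(list(ar = 0.8), 100))
  expect_gt(residualAcf(rep(ar, each = 3), yrs), 0.55)

  expect_error(residualAcf(rep(1, 300), yrs), "zero variance")
})

test_that("the decade slope is exact on noiseless data and units convert", {
  d <- makeRecords(80, seed = 35)
  d$wing_length <- 2 + 0.5 * (d$decade / 10)
  d$subspecies <- "only"
  fit <- suppressWarnings(
    fitLmm(d, "wing_length", useRac = FALSE, varStruct = "homoscedastic"))
  dec <- fit$coefficients[fit$coefficients$term == "dec10", ]
  expect_equal(dec$estimate, 0.5, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)

  eff <- extractEffect(fit, "spA")
  expect_equal(eff$beta, dec$estimate / 10)
  expect_equal(eff$beta * 10, dec$estimate)
  expect_equal(eff$t, eff$beta / eff$se, tolerance = 1e-12)
  expect_equal(sign(eff$beta), sign(dec$estimate))
})

test_that("fitLmm recovers a planted slope with the full covariate set", {
  cfg <- studyConfig()
  d <- simulateSpecimens("spA", -0.02, 0, cfg, seed = 36, n = 150)
  fit <- fitLmm(d, "wing_length")
  eff <- extractEffect(fit, "spA")
  expect_lt(abs(eff$beta - (-0.02)), 2 * eff$se)
  expect_equal(eff$df, fit$n - nrow(fit$coefficients))
})

test_that("variance-structure selection prefers the generating structure", {
  set.seed(37)
  picks_homo <- picks_strat <- logical(12)
  for (i in seq_len(12)) {
    d <- makeRecords(120, sd = 1, seed = 400 + i)
    f <- wing_length ~ dec10_z + sex
    dd <- d; dd$dec10 <- dd$decade / 10
    dd$dec10_z <- scale(dd$dec10)[, 1]; dd$sex <- factor(dd$sex)
    picks_homo[i] <- !selectVarianceStructure(f, dd, hasRe = FALSE)$bySex

    dd2 <- dd
    dd2$wing_length <- dd2$wing_length +
      rnorm(nrow(dd2), 0, ifelse(dd2$sex == "male", 3, 0.1))
    picks_strat[i] <- selectVarianceStructure(f, dd2, hasRe = FALSE)$bySex
  }
  expect_gte(mean(picks_homo), 0.75)
  expect_gte(mean(picks_strat), 0.9)
})

test_that("GAMM effective degrees of freedom separate linear from nonlinear", {
  cfg <- studyConfig(spatialSill = 0)
  ## REML smoothing occasionally wiggles on one draw; the typical (median)
  ## EDF over replicate linear datasets sits at 1
  linEdf <- vapply(1:5, function(s) {
    dl <- simulateSpecimens("spA", -0.02, 0, cfg, seed = 30 + s, n = 400)
    fitGamm(dl, "wing_length", useRac = FALSE)$edf
  }, numeric(1))
  expect_lt(abs(median(linEdf) - 1), 0.2)
  expect_false(median(linEdf) > 3)

  d <- simulateSpecimens("spA", -0.02, 0, cfg, seed = 38, n = 400)
  d_nl <- d
  d_nl$wing_length <- d_nl$wing_length + 6 * sin((d_nl$year - 1900) / 108 * 2 * pi)
  g_nl <- fitGamm(d_nl, "wing_length", useRac = FALSE)
  expect_gt(g_nl$edf, 3)
  expect_true(g_nl$nonlinear)

  ## penalty -> infinity forces the smooth to a straight line
  g_pen <- fitGamm(d_nl, "wing_length", useRac = FALSE, sp = 1e10)
  expect_lt(abs(g_pen$edf - 1), 0.01)

  d_few <- d[d$year %in% sort(unique(d$year))[1:10], ]
  expect_error(fitGamm(d_few, "wing_length"), "15 distinct")
})

test_that("in the linear limit the GAMM slope matches the linear model", {
  cfg <- studyConfig(spatialSill = 0)
  d <- simulateSpecimens("spA", -0.03, 0, cfg, seed = 39, n = 250)
  d$subspecies <- "only"
  d$decade <- d$year   # year-resolution predictor shared by both models
  g <- fitGamm(d, "wing_length", useRac = FALSE, sp = 1e12)
  yr <- range(d$year)
  pr <- predict(g$fit, newdata = data.frame(
    year = yr, sex = factor("male", levels = levels(factor(d$sex))),
    altitude_z = 0))
  gamSlope <- unname(diff(pr) / diff(yr))
  fit <- fitLmm(d, "wing_length", useRac = FALSE, varStruct = "homoscedastic")
  lmmSlope <- extractEffect(fit)$beta        # already per-year units
  expect_equal(gamSlope, lmmSlope, tolerance = 1e-6)
})

test_that("two-stage RAC does not worsen residual spatial autocorrelation", {
  worsened <- 0
  for (s in 1:10) {
    cfg <- studyConfig(spatialSill = 1.2, spatialRange = 6)
    d <- simulateSpecimens("spA", -0.01, 0, cfg, seed = 500 + s, n = 150)
    f0 <- fitLmm(d, "wing_length", useRac = FALSE, varStruct = "homoscedastic")
    f1 <- fitLmm(d, "wing_length", useRac = TRUE, varStruct = "homoscedastic")
    i0 <- abs(moransI(f0$residuals, d$latitude, d$longitude)$observed)
    i1 <- abs(moransI(f1$residuals, d$latitude, d$longitude)$observed)
    if (i1 > i0 + 0.02) worsened <- worsened + 1
  }
  expect_lte(worsened, 1)
})

test_that("a singular design is reported with the offending column", {
  d <- makeRecords(60, seed = 40)
  d$altitude <- 300          # constant predictor
  expect_error(fitLmm(d, "wing_length"), "altitude")
})
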
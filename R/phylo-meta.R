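## Bayesian phylogenetic random-effects meta-analysis with known sampling
## variances: conjugate Gibbs sampler with parameter-expanded update for
## the phylogenetic variance, heterogeneity I2, phylogenetic signal, and
## effect-on-effect meta-regression.

#' Construct a set of per-species effect sizes
#'
#' @param species character labels (must match phylogeny tips).
#' @param effect numeric effects (units/year).
#' @param se numeric standard errors; their squares act as fixed
#'   measurement-error variances.
#' @param moderator optional numeric covariate for meta-regression.
#' @return an [EffectSizeSet-class].
#' @export
effectSizeSet <- function(species, effect, se, moderator = NULL) {
  new("EffectSizeSet", species = as.character(species),
      effect = as.numeric(effect), se = as.numeric(se),
      moderator = if (is.null(moderator)) numeric(0) else as.numeric(moderator))
}

#' Read effect sizes from a delimited table
#'
#' Expects columns \code{species}, \code{beta}, \code{se} (the layout of
#' a per-species results table), and optionally \code{moderator}.
#'
#' @param path delimited text file (separator auto-detected).
#' @return an [EffectSizeSet-class].
#' @export
readEffectSizes <- function(path) {
  sep <- .detectSep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("species", "beta", "se")
  if (!all(need %in% names(df)))
    stop("effects table needs columns: ", paste(need, collapse = ", "))
  effectSizeSet(df$species, df$beta, df$se, moderator = df$moderator)
}

#' Brownian-motion phylogenetic correlation matrix
#'
#' Shared-path-length (variance-covariance) matrix of a rooted tree under
#' Brownian motion, scaled to unit diagonal. Row/column order follows
#' \code{species} when given.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param species optional label order; all must be tips of the tree.
#' @return species x species correlation matrix.
#' @export
phyloCorrelation <- function(tree, species = NULL) {
  V <- ape::vcv(tree, corr = FALSE)
  d <- diag(V)
  ## star-tree and zero-length tips: a tip with zero depth has no shared
  ## history, treat as independent with unit self-correlation
  C <- V / sqrt(outer(pmax(d, .Machine$double.eps),
                      pmax(d, .Machine$double.eps)))
  diag(C) <- 1
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(C))
    if (length(miss))
      stop("species missing from tree: ", paste(miss, collapse = ", "))
    C <- C[species, species]
  }
  C
}

#' Typical sampling variance of a set of effect sizes
#'
#' The Nakagawa-Santos "typical" within-study variance used in I2:
#' with weights \eqn{w_i = 1/v_i} and k effects,
#' \eqn{\sigma^2_m = \sum w_i (k-1) / ((\sum w_i)^2 - \sum w_i^2)}.
#'
#' @param v numeric sampling variances (SE squared).
#' @return the typical sampling variance.
#' @export
typicalSamplingVariance <- function(v) {
  if (any(v <= 0)) stop("sampling variances must be positive")
  k <- length(v)
  w <- 1 / v
  sum(w) * (k - 1) / (sum(w)^2 - sum(w^2))
}

## --- Gibbs kernel ---------------------------------------------------------
## Model: y = X beta + alpha*w + u + m
##   w ~ N(0, sigma2_w A), alpha ~ N(0, alphaV)   [sigma2_p = alpha^2 sigma2_w]
##   u_i ~ N(0, sigma2_s),  m_i ~ N(0, v_i) fixed.
## Priors: beta ~ N(0, 1e10 I); sigma2_s ~ inv-chi2(nu = 0.002, V = 1);
##   sigma2_w ~ inv-chi2(nu = 1, V = 1); alpha ~ N(0, 25^2).
.metaPrior <- function() {
  list(betaV = 1e10, nuS = 0.002, VS = 1, nuW = 1, VW = 1, alphaV = 25^2)
}

.initState <- function(y, X, prior) {
  k <- length(y)
  list(beta = qr.solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, y)),
       w = numeric(k), alpha = 0.1, u = numeric(k),
       sigma2_s = max(var(y) / 2, 1e-10), sigma2_w = 1)
}

.rmvnPrec <- function(mean_rhs, P) {
  ## draw from N(P^{-1} rhs, P^{-1}) given precision P
  U <- chol(P)
  mu <- backsolve(U, backsolve(U, mean_rhs, transpose = TRUE))
  mu + backsolve(U, rnorm(length(mean_rhs)))
}

.gibbsKernel <- function(y, X, Ainv, vinv, state, n_iter, prior = .metaPrior(),
                         keepEvery = 0L, usePhylo = TRUE) {
  k <- length(y); p <- ncol(X)
  keep <- keepEvery > 0L
  if (keep) {
    nk <- n_iter %/% keepEvery
    out <- matrix(NA_real_, nk, p + 2L)
    colnames(out) <- c(colnames(X), "sigma2_p", "sigma2_s")
  }
  beta <- state$beta; w <- state$w; alpha <- state$alpha; u <- state$u
  sigma2_s <- state$sigma2_s; sigma2_w <- state$sigma2_w
  XtV <- t(X * vinv)          # p x k, rows X_j * vinv
  XtVX <- XtV %*% X
  Ip <- diag(1 / prior$betaV, p)
  row <- 0L
  for (it in seq_len(n_iter)) {
    a <- alpha * w
    ## beta
    rhs <- XtV %*% (y - a - u)
    beta <- .rmvnPrec(rhs, XtVX + Ip)
    eta <- as.numeric(X %*% beta)
    if (usePhylo) {
      ## w
      P <- Ainv / sigma2_w + diag(alpha^2 * vinv, k)
      w <- .rmvnPrec(alpha * vinv * (y - eta - u), P)
      ## alpha
      precA <- 1 / prior$alphaV + sum(w^2 * vinv)
      muA <- sum(w * vinv * (y - eta - u)) / precA
      alpha <- rnorm(1, muA, sqrt(1 / precA))
    }
    a <- alpha * w
    ## u
    precU <- 1 / sigma2_s + vinv
    muU <- (vinv * (y - eta - a)) / precU
    u <- rnorm(k, muU, sqrt(1 / precU))
    ## sigma2_s (scaled inverse chi-square posterior)
    sigma2_s <- (prior$nuS * prior$VS + sum(u^2)) /
      stats::rchisq(1, prior$nuS + k)
    ## sigma2_w
    if (usePhylo)
      sigma2_w <- (prior$nuW * prior$VW + sum(w * (Ainv %*% w))) /
        stats::rchisq(1, prior$nuW + k)
    if (keep && it %% keepEvery == 0L) {
      row <- row + 1L
      out[row, ] <- c(beta, alpha^2 * sigma2_w, sigma2_s)
    }
  }
  state <- list(beta = beta, w = w, alpha = alpha, u = u,
                sigma2_s = sigma2_s, sigma2_w = sigma2_w)
  list(state = state, samples = if (keep) out[seq_len(row), , drop = FALSE])
}

.metaDesign <- function(es, regression) {
  y <- es@effect
  if (regression) {
    if (!length(es@moderator)) stop("meta-regression needs a moderator")
    if (sd(es@moderator) == 0) stop("moderator has zero variance")
    X <- cbind(mu = 1, b = es@moderator)
  } else {
    X <- cbind(mu = rep(1, length(y)))
  }
  list(y = y, X = X, vinv = 1 / es@se^2)
}

.checkA <- function(A, species) {
  if (!is.null(species)) {
    if (is.null(rownames(A)) || !all(species %in% rownames(A)))
      stop("correlation matrix must be labelled with all species")
    A <- A[species, species]
  }
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-12)
    stop("phylogenetic correlation matrix is not positive definite")
  A
}

#' Single-chain Gibbs sampler for the phylogenetic meta-analysis
#'
#' Markov chain for the model \eqn{y_i = \mu (+ b x_i) + a_i + u_i + m_i}
#' with phylogenetic effects \eqn{a \sim N(0, \sigma^2_p A)}, species
#' effects \eqn{u_i \sim N(0, \sigma^2_s)} and fixed sampling errors
#' \eqn{m_i \sim N(0, v_i = SE_i^2)}. Location parameters use flat
#' normal priors (variance 1e10); \eqn{\sigma^2_s} a weak scaled
#' inverse-chi-square prior (V = 1, nu = 0.002); \eqn{\sigma^2_p} a
#' parameter-expanded prior (working-parameter scale 25). All updates
#' are conjugate; the chain is deterministic given \code{seed}.
#'
#' @param es an [EffectSizeSet-class].
#' @param A species-labelled phylogenetic correlation matrix.
#' @param nIter total iterations (e.g. 110000 for a confirmation run).
#' @param burnin iterations discarded.
#' @param thin keep every \code{thin}-th draw.
#' @param seed integer RNG seed.
#' @param regression fit the moderator slope \code{b}.
#' @param includePhylo set \code{FALSE} to constrain the phylogenetic
#'   variance to zero (plain random-effects meta-analysis).
#' @return a [MetaChain-class].
#' @export
gibbsMeta <- function(es, A, nIter = 110000, burnin = 10000, thin = 100,
                      seed = 1, regression = FALSE, includePhylo = TRUE) {
  A <- .checkA(A, es@species)
  des <- .metaDesign(es, regression)
  Ainv <- chol2inv(chol(A))
  set.seed(seed)
  state <- .initState(des$y, des$X, .metaPrior())
  if (!includePhylo) state$alpha <- 0
  if (burnin > 0)
    state <- .gibbsKernel(des$y, des$X, Ainv, des$vinv, state, burnin,
                          usePhylo = includePhylo)$state
  res <- .gibbsKernel(des$y, des$X, Ainv, des$vinv, state, nIter - burnin,
                      keepEvery = thin, usePhylo = includePhylo)
  new("MetaChain", samples = res$samples,
      sigma2m = typicalSamplingVariance(1 / des$vinv),
      model = if (regression) "regression" else "intercept")
}

#' Chained sampler over a set of candidate phylogenies
#'
#' Incorporates phylogenetic uncertainty: for each tree in turn, the
#' chain runs \code{itersPerTree} iterations starting from the final
#' state reached under the previous tree, and the last draw is retained;
#' the draws from the first \code{burninTrees} trees are discarded. With
#' \code{nTrees} trees this yields a posterior sample of
#' \code{nTrees - burninTrees}.
#'
#' @param es an [EffectSizeSet-class].
#' @param trees list of \code{ape::phylo} trees (or a \code{multiPhylo}),
#'   each containing all species.
#' @param itersPerTree iterations per tree (default 1000).
#' @param burninTrees trees discarded as burn-in (default 300).
#' @param seed integer RNG seed.
#' @param regression fit the moderator slope.
#' @return a [MetaChain-class] with one retained draw per post-burn-in
#'   tree.
#' @export
runTreeSet <- function(es, trees, itersPerTree = 1000, burninTrees = 300,
                       seed = 1, regression = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  nTrees <- length(trees)
  if (nTrees <= burninTrees)
    stop("need more trees (", nTrees, ") than burn-in trees (",
         burninTrees, ")")
  des <- .metaDesign(es, regression)
  set.seed(seed)
  state <- .initState(des$y, des$X, .metaPrior())
  keepRows <- matrix(NA_real_, nTrees - burninTrees, ncol(des$X) + 2L)
  colnames(keepRows) <- c(colnames(des$X), "sigma2_p", "sigma2_s")
  row <- 0L
  for (i in seq_len(nTrees)) {
    A <- .checkA(phyloCorrelation(trees[[i]], es@species), es@species)
    Ainv <- chol2inv(chol(A))
    res <- .gibbsKernel(des$y, des$X, Ainv, des$vinv, state, itersPerTree,
                        keepEvery = itersPerTree)
    state <- res$state
    if (i > burninTrees) {
      row <- row + 1L
      keepRows[row, ] <- res$samples[1L, ]
    }
  }
  new("MetaChain", samples = keepRows,
      sigma2m = typicalSamplingVariance(1 / des$vinv),
      model = if (regression) "regression" else "intercept")
}

#' Posterior heterogeneity I2
#'
#' Per draw, the proportion of total variance not due to sampling error:
#' \eqn{I^2 = (\sigma^2_p + \sigma^2_s) / (\sigma^2_p + \sigma^2_s +
#' \sigma^2_m)}, with the typical sampling variance from
#' [typicalSamplingVariance()].
#'
#' @param chain a [MetaChain-class].
#' @return list: \code{draws}, and \code{mean}, \code{lower},
#'   \code{upper} of the posterior.
#' @export
heterogeneityI2 <- function(chain) {
  s <- chainSamples(chain)
  tot <- s[, "sigma2_p"] + s[, "sigma2_s"]
  draws <- tot / (tot + samplingVariance(chain))
  list(draws = draws, mean = mean(draws),
       lower = unname(quantile(draws, 0.025)),
       upper = unname(quantile(draws, 0.975)))
}

#' Posterior phylogenetic signal (lambda-equivalent)
#'
#' Per draw, the proportion of between-species heterogeneity explained
#' by phylogeny: \eqn{\sigma^2_p / (\sigma^2_p + \sigma^2_s)}.
#'
#' @param chain a [MetaChain-class].
#' @return list as in [heterogeneityI2()].
#' @export
phyloSignal <- function(chain) {
  s <- chainSamples(chain)
  draws <- s[, "sigma2_p"] / pmax(s[, "sigma2_p"] + s[, "sigma2_s"],
                                  .Machine$double.xmin)
  list(draws = draws, mean = mean(draws),
       lower = unname(quantile(draws, 0.025)),
       upper = unname(quantile(draws, 0.975)))
}

#' Summarise a meta-analytic chain
#'
#' Posterior mean, 95% credible interval and pMCMC (two-sided tail
#' probability of crossing zero, floored at 2/sample size) for the focal
#' location parameter, plus I2 and phylogenetic signal summaries.
#'
#' @param chain a [MetaChain-class].
#' @param term \code{"mu"} or \code{"b"}; defaults to \code{"b"} for
#'   regression chains.
#' @return a [MetaResult-class].
#' @export
summarizeMeta <- function(chain,
                          term = if (chain@model == "regression") "b" else "mu") {
  s <- chainSamples(chain)[, term]
  n <- length(s)
  p <- 2 * min(mean(s > 0), mean(s < 0))
  p <- min(1, max(p, 2 / n))
  i2 <- heterogeneityI2(chain)
  sg <- phyloSignal(chain)
  new("MetaResult", term = term, estimate = mean(s),
      lower = unname(quantile(s, 0.025)), upper = unname(quantile(s, 0.975)),
      pMCMC = p,
      i2 = c(mean = i2$mean, lower = i2$lower, upper = i2$upper),
      signal = c(mean = sg$mean, lower = sg$lower, upper = sg$upper),
      sigma2m = samplingVariance(chain))
}

#' Meta-regression of one trait's temporal change on another's
#'
#' Regresses the focal effect sizes (e.g. per-species wing-length
#' slopes) on a species-matched covariate (e.g. colour slopes) with the
#' same phylogenetic random-effects structure; the covariate enters as a
#' fixed regressor (its own SE is not propagated). Sampling variances
#' are the focal trait's squared SEs.
#'
#' @param es an [EffectSizeSet-class] with a moderator.
#' @param trees a tree or list of trees ([runTreeSet()] semantics).
#' @param ... passed to [runTreeSet()].
#' @return list with the \code{chain} ([MetaChain-class]) and
#'   \code{result} ([MetaResult-class] for the slope b).
#' @export
metaRegression <- function(es, trees, ...) {
  chain <- runTreeSet(es, trees, regression = TRUE, ...)
  list(chain = chain, result = summarizeMeta(chain, "b"))
}
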
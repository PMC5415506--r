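# carotrend

Has a century of environmental change left a consistent imprint on the
bodies and colours of Australian songbirds? `carotrend` is an R package for
answering that kind of question from museum-specimen data. It was built
around a study design in which wing length (an index of structural body
size) and yellow carotenoid-based plumage colour are measured on specimens
of 15 Meliphagoidea species collected between 1900 and 2008, per-species
temporal trends are estimated with spatially corrected mixed models, and the
trends are then combined across species in a Bayesian phylogenetic
meta-analysis. Because carotenoid pigments must be ingested, plumage colour
tracks past food availability; whether colour trends co-vary with size
trends speaks to whether changing food supply drives body-size change.

The package is aimed at researchers analysing historical specimen series:
it covers the full chain from raw reflectance spectra to meta-analytic
posterior summaries, plus a synthetic-study generator with known ground
truth for validating every stage.

## The models in brief

**Colour scoring.** Reflectance spectra (300-700 nm, five replicates per
patch) are passed through the receptor-noise limited model of avian
tetrachromatic vision. Quantum catches
Q_i = ∫ R(λ) I(λ) C_i(λ) dλ for the VS, S, M, L cones are von-Kries
normalised; log catches f_i enter the chromatic distance ΔS, whose noise
weights are ω_i = ν √(η_max/η_i). A fixed linear map embeds each stimulus
at xyz coordinates (jnd units) such that Euclidean distance equals ΔS
exactly — verified to 1e-9 in the tests. Per species, a covariance PCA of
the xyz coordinates yields PC1, sign-anchored to carotenoid chroma
(R700 − R450)/R700 so that higher PC1 means more intense carotenoid colour.

**Per-species trends.** For each species and trait, a Gaussian mixed model
regresses the trait on decade of collection with sex and altitude
covariates, a subspecies random intercept, a residual autocovariate (RAC)
absorbing spatial autocorrelation, season + season² terms for colour
(post-molt abrasion), optional per-sex residual variances (adopted when ML
AIC improves by > 2), and Wald t tests with df = n − p. Slopes are reported
in trait units per year. A penalized spline on year (EDF > 3) flags
nonlinear change.

**Across species.** The slopes y_i with fixed sampling variances SE_i² feed
a Bayesian phylogenetic random-effects meta-analysis
y_i = μ (+ b·x_i) + a_i + u_i + m_i, with a ~ N(0, σ²_p A) on the
phylogeny's Brownian correlation matrix, fitted by a conjugate Gibbs
sampler with a parameter-expanded update for σ²_p, chained over a set of
candidate trees. Reported: posterior mean, 95% CI, pMCMC, heterogeneity I²
and phylogenetic signal (λ-equivalent).

## Worked example

The per-species wing-length slopes and standard errors of the 15 study
species ship with the package; the meta-analytic stage can be run on them
directly:

```r
library(carotrend)
es  <- fixtureEffects("wing")          # 15 species: beta (mm/yr), SE
res <- metaOnly(es, nTrees = 130, burninTrees = 30, seed = 1)
res$result
#> Phylogenetic meta-analysis posterior summary
#>   mu = -0.007709  [95% CI -0.02045, 0.006196]  pMCMC = 0.2
#>   I2     = 0.903 [0.805, 0.963]
#>   signal = 0.186 [0.000, 0.630]
```

Read: across species, wing length declines by about 0.008 mm per year on
average, but the credible interval spans zero (pMCMC = 0.2) — no consistent
trend. I² = 0.90 says 90% of the between-species spread in slopes is real
heterogeneity rather than sampling noise; the phylogenetic signal is low,
so related species do not change alike. The same entry point accepts any
delimited file with `species`, `beta`, `se` columns, a `moderator` column
for effect-on-effect meta-regression (`regression = TRUE`), and any
`ape::phylo` tree(s).

A fully synthetic study with known truth runs end to end in one call:

```r
cfg <- studyConfig(nSpecies = 5, nSpecimenRange = c(40, 50))
out <- runPipeline(cfg = cfg, nTrees = 13, burninTrees = 3, gamm = FALSE)
head(out$effects)       # per-species slopes, SEs, Wald tests, both traits
out$meta$wing           # meta-analytic summary of the planted size trend
```

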
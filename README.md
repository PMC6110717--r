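# conflictscope

Tools for prioritising human–carnivore conflict interventions by combining
two views of *where* encounters happen with survey-based measurement of *how
people feel* about the animal involved. The package was built around
human–tiger conflict in a large Sumatran forest–farmland mosaic — encounter
reports (sightings, attacks on livestock and people, tiger removals),
gridded landscape covariates, and village questionnaires on tolerance — but
every stage is generic and the package ships a synthetic-data generator with
known ground truth so the full pipeline runs and is tested without any
external data.

## What it computes

**Geographic profiling** (`fitDPM`, `twoStageSigma`, `profileSurface`,
`hitScores`, `giniCoefficient`). Encounter points are modelled as a
Dirichlet-process mixture of bivariate normal sources: with a
Chinese-restaurant-process prior over partitions (concentration α), source
locations μₖ ~ N(m₀, τ²I) integrated out, and dispersal x | μₖ ~ N(μₖ, σ²I),
a collapsed Gibbs sampler (Rcpp) draws partitions; σ (km) is either fixed or
sampled over a log-spaced grid by its conditional posterior. Because
duplicate coordinates drag σ toward zero, `twoStageSigma` first fits σ on
the unique points, then re-runs with σ fixed at the posterior mean. The
geoprofile surface is the posterior predictive density of the next
encounter, normalised to sum to 1 over the grid; searching cells in
decreasing order yields per-target *hitscores* (fraction of area searched
before the target is reached) and a search *Gini coefficient*
`1 − 2·mean(hitscore)` (1 = perfect search, 0 = random).

**Ensemble risk mapping** (`extractCovariates`, `screenCollinearity`,
`makePseudoAbsences`, `fitEnsemble`, `predictSurface`,
`variableImportance`). Presences (encounters) against 10,000 background
points from the farmland extent; covariates are 3.25-km buffer means,
screened to |r| < 0.7 and VIF < 3. Five binomial learners (GLM, GAM,
random forest, SVM, boosted trees) are screened by mean AUC over ten
70/30 splits; members with AUC > 0.70 are refit and combined with true-skill-
statistic weights. Importance is the mean Pearson correlation between
ensemble predictions before and after permuting each covariate (low r =
important).

**Tolerance modelling** (`prepareResponses`, `scaleDiagnostics`,
`fitMultinomial`, `aicc`, `compareModels`, `evidenceRatio`,
`attachRiskCovariates`). Three-category preference for the local animal
population (reduce/eradicate, stay the same, increase) is modelled by
multinomial logistic regression on psychometric items (affect, attitudes,
norms, beliefs, trust, management scenarios) plus demographics, with
village-level risk covariates (ensemble probability, geoprofile score, or
raw landscape covariates) attached at the centroid. Candidate models are
ranked by AICc; ΔAICc < 2 defines the confidence set, coefficients are
model-averaged, term importance is the sum of Akaike weights, and
`exp(ΔAICc/2)` gives evidence ratios.

**Prioritisation** (`villageScores`, `classifyPriority`,
`conflictAccounting`, `deduplicateEncounters`, `linkEncounters`). Villages
are scored by buffered risk and by mean coded preference (1–3); the
median-split rule classifies villages as high (above-median risk,
below-median tolerance), medium (above-median risk otherwise) or low
(at/below-median risk), with a mean-split variant. Encounters deduplicate
at a 1-month gap, chain at a 6-month window, and are tallied per priority
class.

`runPipeline()` orchestrates simulate → geoprofile → risk → tolerance →
prioritize and returns a structured report.

## Worked example

```r
library(conflictscope)

land  <- genLandscape(seed = 1)                      # 400 x 300 km, 4 km cells
vil   <- genVillages(land, 2300, seed = 2)
truth <- truthParams()                               # 27 km sources, 106/83/12/27 mix
enc   <- genEncounters(land, truth, vil, 228, seed = 3, exactCategories = TRUE)

ts <- twoStageSigma(enc[, c("x", "y")],
                    dpmConfig(samplesPerChain = 4000, burnIn = 1000,
                              nChains = 4, seed = 11))
ts$sigma_hat
#> [1] 28.72568

sight <- enc[enc$category == "sighting", c("x", "y")]
other <- enc[enc$category != "sighting", c("x", "y")]
val <- validateByCategory(sight, other, land@rasters[[1]],
                          dpmConfig(samplesPerChain = 4000, burnIn = 1000,
                                    nChains = 4, seed = 11))
round(c(gini = val$gini, val$found_at), 3)
#>  gini   15%   30%
#> 0.635 0.549 0.803
```

The fitted dispersal sd lands near its generating value of 27 km; a profile
trained on sightings alone finds roughly 80% of the held-out attacks and
removals after searching 30% of the landscape (Gini ≈ 0.64), which is what
makes sighting reports useful for pre-emptive deployment. Model-comparison
arithmetic works directly on criterion values:

```r
tab <- publishedModelTable()        # reference four-model AICc comparison
aiccWeights(setNames(tab$AICc, tab$model))$delta
#> [1] 0.00 6.38 6.82 6.96
round(evidenceRatio(tab$AICc[1], tab$AICc[4]))   # social+geoprofile vs social-only
#> [1] 32
```

Adding the geoprofile score to the social predictors is ~32 times better
supported than the social-only model: people living nearer encounter
clusters are less tolerant, and that risk signal is not captured by the
psychometrics alone.

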
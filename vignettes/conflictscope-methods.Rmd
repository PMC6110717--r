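---
title: "Models and methods behind conflictscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conflictscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`conflictscope` couples two spatial views of encounter risk with a survey
measurement of wildlife tolerance and a simple decision rule for allocating
intervention effort across villages. This vignette describes the models,
their assumptions, the parameters that matter, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Geographic profiling: a Dirichlet-process mixture of sources

Encounter points $x_i \in \mathbb{R}^2$ (planar km) are modelled as draws
from an unknown number of *sources* (territories, hunting grounds):

* partition prior: Chinese restaurant process with concentration $\alpha$;
* source locations: $\mu_k \sim N(m_0, \tau^2 I)$;
* dispersal: $x_i \mid z_i = k \sim N(\mu_k, \sigma^2 I)$.

With $\mu_k$ conjugate, the collapsed Gibbs sampler (implemented in C++)
resamples each $z_i$ from $P(z_i = k) \propto n_k^{-i}\,t_k(x_i)$ and
$P(\text{new}) \propto \alpha\,N(x_i \mid m_0, (\tau^2{+}\sigma^2)I)$, where
$t_k$ is the cluster's posterior predictive. When $\sigma$ is not fixed it
is sampled each sweep over 50 log-spaced values spanning $[0.1,\,2\times$
data extent$]$ km by its conditional posterior given the partition (griddy
Gibbs); conjugacy is unavailable for $\sigma$ and a grid keeps the update
reproducible. Chains (default 10, 50,000 samples, burn-in 10,000) start
from distinct sub-seeds; post-burn-in draws are pooled without convergence
gating, but a split-$\hat R$ on the cluster-count trace is recorded and a
warning raised above 1.1. Retained draws are thinned (default every 10th)
to bound the memory of assignment storage.

**Defaults and units.** $\alpha = 1$ (a weak preference for few clusters);
$m_0 =$ data centroid and $\tau =$ the maximum data extent, i.e. a diffuse,
data-scaled location prior; $\sigma$ in km. None of these is sharply
identified by the data sizes involved, so all are configurable and logged.

**Two-stage $\sigma$.** Repeated identical coordinates (several reports
from one village) make the likelihood favour $\sigma \to 0$. The
`twoStageSigma` procedure therefore fits $\sigma$ on the *unique* points,
takes the posterior mean $\hat\sigma$, and re-runs on all points with
$\sigma$ fixed. Fewer than two unique points is an error: $\sigma$ is
unidentifiable.

**The profile surface.** For each retained draw, each cluster contributes
its source-location posterior $N(m_k, s_k^2 I)$ *convolved with the
dispersal kernel*, giving the posterior predictive density of the next
encounter:
$$
\sum_k \frac{n_k}{n+\alpha} N(\text{cell} \mid m_k, (s_k^2{+}\sigma^2)I)
+ \frac{\alpha}{n+\alpha} N(\text{cell} \mid m_0, (\tau^2{+}\sigma^2)I),
$$
averaged over draws and renormalised to sum to 1 over valid cells. The
dispersal convolution matters: the raw source posterior is nearly a point
mass, its far field underflows to numerically identical zeros, and ranking
ties would make hitscores of outlying targets meaningless. Searching for
*future encounters* — the quantity the hitscore validation measures — needs
the dispersal-scale spread.

**Hitscores and Gini.** A target's hitscore is the fraction of cells
searched, in decreasing surface order, before its cell is reached; ties
take mid-rank weight so flat regions are unbiased. Hitscores are invariant
under any strictly monotone transform of the surface. With $F$ the
empirical CDF of hitscores, the search Gini is
$2\int_0^1 (F(x)-x)\,dx = 1 - 2\,\overline{\text{hitscore}}$, 1 for a
perfect search, 0 for random search.

## 2. Ensemble risk mapping

Encounters are presences; 10,000 pseudo-absences are drawn uniformly from
the farmland extent, defined as cells with forest cover below 0.5 (the
threshold is configurable; the background should cover everywhere an
encounter *could* have been reported). Covariates are buffer means within
3.25 km of each point — a typical village radius, absorbing georeferencing
error — scaled and centred with the scaler frozen at fit time, and screened
by iteratively dropping the highest-VIF column until all VIF < 3 and all
pairwise $|r| < 0.7$.

Five member families (binomial GLM; GAM with spline smooths; random
forest; radial SVM with probability outputs; gradient-boosted trees) are
evaluated by mean AUC over ten stratified 70/30 splits. Members with
cross-validated AUC > 0.70 are refit on all data and weighted by their
full-data true skill statistic (max over thresholds of sensitivity +
specificity − 1), renormalised to sum to 1; TSS is computed in-sample after
refit, the convention of the ensemble tooling this mirrors (whether it
should be cross-validated instead is genuinely open; the choice is logged).
The ensemble probability is the TSS-weighted mean of member probabilities,
hence always inside the member envelope. Member hyperparameters stay at
library defaults with fixed seeds — the pipeline contract, not
hyperparameter search, is the point.

Variable importance permutes one covariate at a time and reports the mean
Pearson correlation between the original and permuted-prediction vectors:
$r \approx 1$ means the covariate is inert; small $r$ means the permutation
destroyed the prediction. A constant prediction vector is reported as 1
(no information to destroy).

## 3. Tolerance: multinomial models with AICc machinery

The response is the preferred change in the local animal population —
reduce/eradicate (reference), stay the same, increase. Don't-know and
missing responses are excluded before modelling. Items sit on 1–5 scales
oriented so higher is pro-conservation (reversal is `x -> 6 - x` for any
item supplied in `reverseItems`); the four management-scenario items are
averaged into a single `Scenario` score after checking they form one
dimension: Cronbach's $\alpha$ from item/total variances, KMO sampling
adequacy from correlation versus partial-correlation magnitudes, and the
loadings/share of the first principal factor of the item correlation
matrix. Age is z-scored; ethnicity is one-hot with the largest group as
baseline; village-level risk covariates (geoprofile value, ensemble
probability, buffered landscape covariates) are evaluated at the village
centroid and z-scored across respondents.

Fits use maximum likelihood (`nnet::multinom`) with SEs from the inverse
observed information; coefficients with implausible magnitude trigger a
quasi-separation warning. The information criterion is
$-2\ell + 2K$ plus the small-sample correction $2K(K{+}1)/(n{-}K{-}1)$,
on by default (the correction is undefined at $n \le K{+}1$ and that is an
error, not a silent fallback). Model comparison: $\Delta$AICc against the
best model, Akaike weights $w_i \propto e^{-\Delta_i/2}$, a
$\Delta < 2$ confidence set, *conditional* (subset) model averaging with
unconditional standard errors
$\sqrt{\sum_i w_i (se_i^2 + (\beta_i - \bar\beta)^2)}$ (full-shrinkage
averaging available by flag), per-term importance as the sum of full-set
weights over models containing the term, and evidence ratios
$e^{\Delta/2}$. The default candidate set is the four named structures
(social only; + landscape covariates; + ensemble probability;
+ geoprofile); an all-subsets generator would explode combinatorially and
is deliberately not the default.

## 4. Prioritisation and encounter chains

Village risk is the 3.25-km buffer mean of the chosen surface at the
centroid; village tolerance is the mean coded preference (1 =
reduce/eradicate, 2 = same, 3 = increase) over analysed respondents. The
default split is the **median** rule — high: risk above median *and*
tolerance below median; medium: risk above median otherwise; low: risk at
or below median — which depends only on ranks, so any monotone transform
of risk yields identical classes, and which therefore always labels half
the villages low. The published framing of such frameworks sometimes says
"above average"; a mean-split variant (`rule = "mean"`) is provided because
the two genuinely differ on skewed risk distributions, and the acceptance
script uses it for the village-share quantities for exactly that reason.
All-identical risk degenerates to all-low with a warning.

Record hygiene follows two windows measured in 30-day months (calendar-free
arithmetic): reports in the same village and category closer than 1 month
merge into the earliest; deduplicated events in one village chain while
successive gaps stay under 6 months, and the escalation rate is the
fraction of chains longer than one event.

## 5. The synthetic study system

The generator emulates the study conditions end to end so every stage has
known ground truth:

* **Landscape**: 400 × 300 km, 4-km cells — eight co-registered rasters.
  Distance-to-feature rasters come from random river walks/road transects
  and a smoothed-noise forest mask via an exact distance transform;
  density/occupancy/connectivity fields are Gaussian-smoothed white noise
  (kernel sd 4 cells) rescaled to their ranges. Only the spatial
  autocorrelation matters for testing; no real hydrology, road topology or
  demography is modelled.
* **Encounters**: 228 records, categories 106/83/12/27 (sightings,
  livestock attacks, attacks on people, removals), drawn from an intensity
  equal to the inverse-logit covariate term times a 4-source Gaussian
  mixture with dispersal sd 27 km and source weight 0.98 (encounters are
  overwhelmingly cluster-driven; the covariate term modulates locally).
  Dates are uniform over a 13-year window — deliberately no temporal
  clustering, so chain-escalation statistics are exercised but not
  calibrated to any field value. Villages (2300) are uniform; each record
  takes the nearest village.
* **Surveys**: ~2386 respondents over 75 villages selected by a stratified
  design — most survey villages drawn, weighted by encounter count, from
  villages with encounter records, the rest uniformly — mirroring surveys
  concentrated where encounters occur. Fourteen 1–5 items load on a shared
  latent plus a scenario factor (loadings chosen so the scenario scale is
  one-dimensional with $\alpha \approx 0.78$); the 3-category response
  follows a multinomial logit on centred items and the z-scored geoprofile
  value with a *negative* GP coefficient (people nearer risk clusters are
  less tolerant), intercepts set so the margins sit near 28/48/19% with
  4.5% don't-know and 1.2% missing injected.

What passing tests show — and what they do not: recovery of cluster count,
source locations, $\sigma$, generating slopes and margins demonstrates the
estimators are correct *under the generating model* (Gaussian dispersal,
logit tolerance, independent respondents). Real data add reporting bias,
non-Gaussian dispersal along terrain, village-level correlation and
measurement drift that the generator intentionally omits. One known
divergence: the synthetic covariate fields make clustered presences more
separable than a real landscape, so ensemble AUCs run higher than the
moderate values typical of field systems.

## 6. Numerical choices and degenerate inputs

* Grids are row-major from a lower-left origin with half-open cells;
  point-in-cell is floor division, so boundary points belong to the cell
  above/right. Raster IO is plain-text ESRI ASCII grid at full double
  precision (bit-exact round trips).
* Profile ranking breaks ties by cell index; hitscores give ties mid-rank
  weight.
* The Gibbs sampler normalises cluster probabilities after subtracting the
  max log weight; empty clusters are deleted by swap-with-last relabelling
  and labels are canonicalised by first appearance before storage.
* Degenerate inputs fail loudly: all-zero intensity, empty background
  masks, single-class AUC/TSS inputs, zero-variance psychometric items,
  < 2 unique points for $\sigma$, $n \le K{+}1$ for the AICc correction.
  Constant covariates are dropped with warnings (undefined correlation).
* Problem sizes in the shipped tests and the acceptance script (e.g.
  4,000 × 4 chains for the sampler, 3,000 pseudo-absences) are scaled-down
  choices that keep runs quick while leaving every estimator in its
  well-behaved regime; the package defaults remain the full-size settings.

## 7. Known limitations

Isotropic Gaussian dispersal only (no anisotropy, barriers, or
spatio-temporal profiling); no spatial block cross-validation for the
ensemble; no ordered-logit variant of the tolerance model; no imputation of
missing items; the prioritisation is a static decision rule, not an
optimisation of patrol effort.
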
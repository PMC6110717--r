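#' @import methods
#' @importFrom stats coef cor dnorm glm.fit lm lm.fit median pnorm predict
#'   qnorm quantile rbinom rnorm runif sd setNames var complete.cases binomial
#'   logLik as.formula kmeans
#' @importFrom utils head read.csv write.csv
#' @useDynLib conflictscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

NODATA_DEFAULT <- -9999

#' Planar gridded surface with lower-left origin
#'
#' A minimal raster container for planar (km) analysis grids. Values are stored
#' as a matrix with `values[i, j]` the cell in row `i` (counted from the
#' *bottom* edge, so row 1 touches the origin) and column `j` (from the left).
#' Cells are half-open squares of side `cellSize`; a point `(x, y)` falls in
#' column `floor((x - x0) / cellSize) + 1` and row `floor((y - y0) / cellSize) + 1`.
#' Cells equal to `nodata` are excluded from all statistics.
#'
#' @slot values numeric matrix of cell values (rows = south to north).
#' @slot origin numeric length-2, `(x, y)` of the lower-left corner in km.
#' @slot cellSize positive numeric, cell side in km.
#' @slot nodata numeric sentinel marking missing cells.
#' @slot crs optional character tag describing the planar reference frame.
#' @export
setClass("RasterGrid",
  representation(
    values = "matrix",
    origin = "numeric",
    cellSize = "numeric",
    nodata = "numeric",
    crs = "character"
  ),
  prototype(
    origin = c(0, 0),
    cellSize = 1,
    nodata = NODATA_DEFAULT,
    crs = "planar-km"
  )
)

setValidity("RasterGrid", function(object) {
  msgs <- character()
  if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be two finite numbers")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@nodata) != 1) msgs <- c(msgs, "nodata must be scalar")
  if (length(msgs)) msgs else TRUE
})

#' Bundle of co-registered landscape covariate rasters
#'
#' Holds the eight covariate surfaces used by the risk models (distance to
#' rivers/roads/forest in km, percent forest cover, human and farmer population
#' density in persons per square km, occupancy and connectivity on \[0, 1\]),
#' all sharing extent, cell size and nodata mask.
#'
#' @slot rasters named list of [RasterGrid-class] objects.
#' @slot extent numeric length-4 `(xmin, ymin, xmax, ymax)` in km.
#' @slot cellSize numeric, km.
#' @slot seed integer seed the bundle was generated from (NA if read from disk).
#' @export
setClass("LandscapeBundle",
  representation(
    rasters = "list",
    extent = "numeric",
    cellSize = "numeric",
    seed = "integer"
  )
)

setValidity("LandscapeBundle", function(object) {
  msgs <- character()
  if (length(object@rasters) == 0) msgs <- c(msgs, "no rasters")
  if (is.null(names(object@rasters)) || any(names(object@rasters) == ""))
    msgs <- c(msgs, "rasters must be named")
  dims <- vapply(object@rasters, function(r) dim(r@values), integer(2))
  if (length(object@rasters) > 1 && any(apply(dims, 1, function(d) length(unique(d)) != 1)))
    msgs <- c(msgs, "rasters must share grid dimensions")
  if (length(object@extent) != 4) msgs <- c(msgs, "extent must be (xmin, ymin, xmax, ymax)")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth parameters for the synthetic study system
#'
#' @slot riskBeta named numeric vector of coefficients on the scaled landscape
#'   covariates entering the true encounter-intensity logit.
#' @slot sourceCentres two-column matrix of source locations (km).
#' @slot sourceSd bivariate-normal dispersal standard deviation around each
#'   source (km).
#' @slot sourceWeight mixing weight of the source term against the
#'   landscape-driven term in the encounter intensity, in \[0, 1\].
#' @slot categoryMix length-4 proportions over
#'   sighting / livestock_attack / human_attack / removal; sums to 1.
#' @slot toleranceBeta two named coefficient vectors (rows `increase`, `same`)
#'   of the true multinomial logit against the reduce/eradicate reference,
#'   including a `gp` column for the z-scored geographic-profile score.
#' @slot dontknowRate,missingRate proportions of don't-know and missing
#'   tolerance responses injected into surveys.
#' @export
setClass("TruthParams",
  representation(
    riskBeta = "numeric",
    sourceCentres = "matrix",
    sourceSd = "numeric",
    sourceWeight = "numeric",
    categoryMix = "numeric",
    toleranceBeta = "matrix",
    dontknowRate = "numeric",
    missingRate = "numeric"
  )
)

setValidity("TruthParams", function(object) {
  msgs <- character()
  if (length(object@categoryMix) != 4 ||
      abs(sum(object@categoryMix) - 1) > 1e-8)
    msgs <- c(msgs, "categoryMix must be 4 proportions summing to 1")
  for (r in c(object@dontknowRate, object@missingRate, object@sourceWeight))
    if (r < 0 || r > 1) msgs <- c(msgs, "rates must lie in [0, 1]")
  if (ncol(object@sourceCentres) != 2)
    msgs <- c(msgs, "sourceCentres must have two columns")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the Dirichlet-process-mixture geoprofile sampler
#'
#' @slot samplesPerChain,burnIn,nChains MCMC run lengths; burn-in draws are
#'   discarded per chain and retained draws pooled across chains.
#' @slot sigma dispersal standard deviation in km, or `NA_real_` to fit it on a
#'   log-spaced conditional grid (griddy Gibbs).
#' @slot dpConcentration Chinese-restaurant-process concentration (alpha).
#' @slot priorCentre,priorSd mean and standard deviation (tau, km) of the
#'   bivariate normal prior on source locations; `NA` means data-scaled
#'   defaults (centroid; max data extent).
#' @slot thin keep every `thin`-th post-burn-in draw to bound memory.
#' @slot seed integer master seed; chains use derived sub-seeds.
#' @export
setClass("DPMConfig",
  representation(
    samplesPerChain = "integer",
    burnIn = "integer",
    nChains = "integer",
    sigma = "numeric",
    dpConcentration = "numeric",
    priorCentre = "numeric",
    priorSd = "numeric",
    thin = "integer",
    seed = "integer"
  ),
  prototype(
    samplesPerChain = 50000L,
    burnIn = 10000L,
    nChains = 10L,
    sigma = NA_real_,
    dpConcentration = 1.0,
    priorCentre = c(NA_real_, NA_real_),
    priorSd = NA_real_,
    thin = 10L,
    seed = 1L
  )
)

setValidity("DPMConfig", function(object) {
  msgs <- character()
  if (object@burnIn >= object@samplesPerChain)
    msgs <- c(msgs, "burnIn must be smaller than samplesPerChain")
  if (!is.na(object@sigma) && object@sigma <= 0)
    msgs <- c(msgs, "fixed sigma must be positive")
  if (object@dpConcentration <= 0)
    msgs <- c(msgs, "dpConcentration must be positive")
  if (object@nChains < 1L) msgs <- c(msgs, "need at least one chain")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Pooled posterior draws from the DPM geoprofile sampler
#'
#' @slot assignments integer matrix, one row per retained (thinned) draw, one
#'   column per point: cluster labels forming a partition of the points.
#' @slot sigmaDraws numeric vector of sigma draws (km) aligned with rows of
#'   `assignments`; constant when sigma was fixed.
#' @slot clusterCountDraws integer cluster count per retained draw.
#' @slot retained nominal retained draw count
#'   `nChains * (samplesPerChain - burnIn)` before thinning.
#' @slot points the fitted two-column coordinate matrix.
#' @slot config the [DPMConfig-class] used (with data-scaled priors resolved).
#' @slot rhat split-R-hat of the cluster-count trace across chains.
#' @export
setClass("DPMPosterior",
  representation(
    assignments = "matrix",
    sigmaDraws = "numeric",
    clusterCountDraws = "integer",
    retained = "integer",
    points = "matrix",
    config = "DPMConfig",
    rhat = "numeric"
  )
)

setValidity("DPMPosterior", function(object) {
  msgs <- character()
  if (nrow(object@assignments) != length(object@clusterCountDraws))
    msgs <- c(msgs, "cluster count trace must align with assignment draws")
  if (nrow(object@assignments) > 0) {
    labs <- object@assignments[1, ]
    if (any(labs < 1L) || any(labs > length(labs)))
      msgs <- c(msgs, "labels must index clusters of the point set")
  }
  if (length(msgs)) msgs else TRUE
})

#' A normalised geographic profile and its search-order ranking
#'
#' @slot surface [RasterGrid-class] of per-cell source probabilities summing to
#'   1 over non-nodata cells.
#' @slot rank [RasterGrid-class] of search-order fractions in (0, 1]: the cell
#'   searched first has rank 1/ncells, the last 1.
#' @export
setClass("GeoProfile",
  representation(surface = "RasterGrid", rank = "RasterGrid")
)

setValidity("GeoProfile", function(object) {
  v <- values(object@surface)
  ok <- v[v != object@surface@nodata]
  if (abs(sum(ok) - 1) > 1e-6) "surface must sum to 1 over valid cells" else TRUE
})

#' Screened, weighted ensemble of binomial encounter-risk models
#'
#' @slot members named list of fitted member models (subset passing the AUC
#'   screen), each a list with fields `fit`, `kind`.
#' @slot cvAuc named numeric of mean cross-validation AUC for every candidate.
#' @slot tss named numeric of full-data true skill statistic per selected member.
#' @slot weights named numeric TSS weights over selected members, summing to 1.
#' @slot scaler list with `center` and `scale` used to z-score covariates.
#' @slot columns character vector of covariate columns the members were fit on.
#' @export
setClass("EnsembleModel",
  representation(
    members = "list",
    cvAuc = "numeric",
    tss = "numeric",
    weights = "numeric",
    scaler = "list",
    columns = "character"
  )
)

setValidity("EnsembleModel", function(object) {
  msgs <- character()
  if (length(object@members) == 0) msgs <- c(msgs, "no selected members")
  if (length(object@weights) != length(object@members))
    msgs <- c(msgs, "one weight per selected member")
  if (any(object@weights < -1e-12)) msgs <- c(msgs, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-8) msgs <- c(msgs, "weights must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' AICc model comparison with averaging, importance and evidence ratios
#'
#' @slot table data.frame with one row per model: `model`, `K`, `logLik`,
#'   `AICc`, `delta`, `weight`, ordered by AICc.
#' @slot averaged data.frame of model-averaged coefficients over the
#'   confidence set (delta < threshold): `equation`, `term`, `estimate`, `se`.
#' @slot importance named numeric: per-term sum of Akaike weights over models
#'   containing the term.
#' @slot confidenceSet character vector of model names with delta < threshold.
#' @slot deltaThreshold numeric, the delta-AICc cut used for the set.
#' @export
setClass("ModelComparison",
  representation(
    table = "data.frame",
    averaged = "data.frame",
    importance = "numeric",
    confidenceSet = "character",
    deltaThreshold = "numeric"
  )
)

setValidity("ModelComparison", function(object) {
  msgs <- character()
  if (nrow(object@table) > 0) {
    if (abs(sum(object@table$weight) - 1) > 1e-8)
      msgs <- c(msgs, "Akaike weights must sum to 1")
    if (abs(min(object@table$delta)) > 1e-8)
      msgs <- c(msgs, "minimum delta-AICc must be 0")
  }
  if (length(msgs)) msgs else TRUE
})
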
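#' Encounter category vocabulary
#'
#' The four encounter types recorded by conflict-response units, in the fixed
#' order used for category mixes: sightings, attacks on livestock, attacks on
#' people, and removals of animals (snaring/poisoning).
#' @export
ENCOUNTER_CATEGORIES <- c("sighting", "livestock_attack", "human_attack", "removal")

#' Questionnaire item columns (all on 1-5 scales)
#' @export
SURVEY_ITEMS <- c("BadGood", "DangHarm", "Kill_tiger", "Protect_tiger",
                  "Descriptive", "Injunctive", "Spirit", "Health", "Env",
                  "TrustB", "ScenA", "ScenB", "ScenC", "ScenD")

COVARIATE_NAMES <- c("dis_riv", "dis_rds", "dis_for", "for_cov",
                     "pop_grd", "farmers", "occupancy", "connect")

#' Ground-truth parameters for the synthetic study system
#'
#' Defaults emulate the study conditions: a 228-encounter record split
#' 106/83/12/27 over the four categories, a handful of encounter sources with
#' 27 km bivariate-normal dispersal, and tolerance margins near 28/48/19 per
#' cent (reduce / same / increase) with 4.5 per cent don't-know and 1.2 per
#' cent missing responses. The geographic-profile score enters the true
#' tolerance logit with a negative sign: respondents nearer risk clusters are
#' less supportive of the population staying level or increasing.
#'
#' @param riskBeta named coefficients on scaled landscape covariates.
#' @param sourceCentres two-column matrix of source locations, km.
#' @param sourceSd dispersal standard deviation around sources, km.
#' @param sourceWeight weight of the source mixture against the flat component
#'   of the encounter intensity.
#' @param categoryMix length-4 proportions over [ENCOUNTER_CATEGORIES].
#' @param toleranceBeta 2-row coefficient matrix (`increase`, `same` vs the
#'   reduce/eradicate reference); columns `(Intercept)`, item names, `gp`.
#' @param dontknowRate,missingRate injection rates for non-analysed responses.
#' @return a [TruthParams-class].
#' @export
truthParams <- function(
    riskBeta = c(dis_riv = -0.6, dis_rds = -0.2, dis_for = -1.0, for_cov = 0.3,
                 pop_grd = 0.5, farmers = 0.2, occupancy = 0.7, connect = 0.7),
    sourceCentres = rbind(c(80, 220), c(300, 90), c(330, 230), c(140, 70)),
    sourceSd = 27,
    sourceWeight = 0.98,
    categoryMix = c(106, 83, 12, 27) / 228,
    toleranceBeta = defaultToleranceBeta(),
    dontknowRate = 0.045,
    missingRate = 0.012) {
  new("TruthParams", riskBeta = riskBeta, sourceCentres = sourceCentres,
      sourceSd = sourceSd, sourceWeight = sourceWeight,
      categoryMix = categoryMix, toleranceBeta = toleranceBeta,
      dontknowRate = dontknowRate, missingRate = missingRate)
}

#' @rdname truthParams
#' @export
defaultToleranceBeta <- function() {
  cols <- c("(Intercept)", SURVEY_ITEMS, "gp")
  b <- matrix(0, 2, length(cols), dimnames = list(c("increase", "same"), cols))
  b["increase", c("(Intercept)", "Protect_tiger", "Kill_tiger", "BadGood",
                  "Spirit", "Descriptive", "ScenA", "TrustB", "gp")] <-
    c(-0.455, 0.45, 0.35, 0.40, 0.35, 0.25, 0.20, 0.10, -0.35)
  b["same", c("(Intercept)", "Protect_tiger", "Kill_tiger", "BadGood",
              "Descriptive", "gp")] <-
    c(0.719, 0.30, 0.18, 0.30, 0.22, -0.18)
  b
}

rescale01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Generate a synthetic landscape of co-registered covariate rasters
#'
#' Distance rasters (`dis_riv`, `dis_rds`, `dis_for`) come from randomly
#' placed line/patch features via an exact distance transform; density fields
#' (`pop_grd`, `farmers`) and the bounded fields (`for_cov`, `occupancy`,
#' `connect`) are Gaussian-smoothed white-noise surfaces rescaled to their
#' ranges, giving realistic spatial autocorrelation without modelling real
#' hydrology or road networks.
#'
#' @param extent `(xmin, ymin, xmax, ymax)` in km.
#' @param cellSize cell side, km.
#' @param seed integer seed; identical seeds give bit-identical bundles.
#' @param smoothSd random-field smoothing kernel sd, in cells.
#' @param maxDensity upper bound of the density fields, persons per square km.
#' @return a [LandscapeBundle-class] with the eight covariate rasters.
#' @export
genLandscape <- function(extent = c(0, 0, 400, 300), cellSize = 4, seed = 1L,
                         smoothSd = 4, maxDensity = 400) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("genLandscape: extent must be a positive rectangle")
  if (cellSize <= 0) stop("genLandscape: cellSize must be positive")
  nc <- floor((extent[3] - extent[1]) / cellSize)
  nr <- floor((extent[4] - extent[2]) / cellSize)
  if (nr < 2 || nc < 2) stop("genLandscape: grid dimensions must be positive")
  origin <- extent[1:2]
  blank <- function() rasterGrid(matrix(0, nr, nc), origin, cellSize)
  geom <- blank()

  set.seed(seed)

  field <- function() gaussianSmooth(matrix(rnorm(nr * nc), nr, nc), smoothSd)

  # rivers: lateral random walks crossing the grid; roads: straight transects
  walkMask <- function(nWalks) {
    mask <- matrix(FALSE, nr, nc)
    for (w in seq_len(nWalks)) {
      r <- sample.int(nr, 1)
      for (j in seq_len(nc)) {
        mask[r, j] <- TRUE
        r <- min(nr, max(1L, r + sample(c(-1L, 0L, 1L), 1)))
      }
    }
    mask
  }
  riverMask <- walkMask(3L)
  roadMask <- matrix(FALSE, nr, nc)
  for (r in sample.int(nr, 2)) roadMask[r, ] <- TRUE
  for (cl in sample.int(nc, 2)) roadMask[, cl] <- TRUE

  forestField <- field()
  forestMask <- forestField > quantile(forestField, 0.55)

  dis_riv <- distanceTransform(geom, riverMask)
  dis_rds <- distanceTransform(geom, roadMask)
  dis_for <- distanceTransform(geom, forestMask)

  for_cov <- rasterGrid(rescale01(gaussianSmooth(forestMask * 1, smoothSd)),
                        origin, cellSize)
  pop_grd <- rasterGrid(maxDensity * rescale01(field())^2, origin, cellSize)
  farmers <- rasterGrid(0.6 * maxDensity * rescale01(field())^2, origin, cellSize)
  occupancy <- rasterGrid(rescale01(field() + forestField), origin, cellSize)
  connect <- rasterGrid(rescale01(field() + 0.8 * forestField -
                                    0.2 * values(dis_riv) / max(values(dis_riv))),
                        origin, cellSize)

  new("LandscapeBundle",
      rasters = list(dis_riv = dis_riv, dis_rds = dis_rds, dis_for = dis_for,
                     for_cov = for_cov, pop_grd = pop_grd, farmers = farmers,
                     occupancy = occupancy, connect = connect),
      extent = as.numeric(extent), cellSize = as.numeric(cellSize),
      seed = as.integer(seed))
}

#' True encounter-intensity surface implied by the ground truth
#'
#' Inverse-logit of the scaled-covariate linear predictor, multiplied by a
#' mixture of bivariate normal source kernels (flat-mixed with weight
#' `1 - sourceWeight`); the surface every encounter generator draws from.
#'
#' @param landscape a [LandscapeBundle-class].
#' @param truth a [TruthParams-class].
#' @return a [RasterGrid-class]; values sum to 1.
#' @export
trueIntensity <- function(landscape, truth) {
  g <- landscape@rasters[[1]]
  d <- dim(values(g))
  eta <- matrix(0, d[1], d[2])
  for (nm in names(truth@riskBeta)) {
    if (truth@riskBeta[[nm]] == 0) next
    v <- values(landscape@rasters[[nm]])
    eta <- eta + truth@riskBeta[[nm]] * (v - mean(v)) / (sd(as.vector(v)) + 1e-12)
  }
  p <- 1 / (1 + exp(-eta))
  if (nrow(truth@sourceCentres) > 0 && truth@sourceWeight > 0) {
    cc <- cellCentres(g)
    mix <- matrix(0, d[1], d[2])
    for (k in seq_len(nrow(truth@sourceCentres))) {
      fx <- dnorm(cc$x, truth@sourceCentres[k, 1], truth@sourceSd)
      fy <- dnorm(cc$y, truth@sourceCentres[k, 2], truth@sourceSd)
      mix <- mix + outer(fy, fx)
    }
    mix <- mix / max(mix)
    p <- p * ((1 - truth@sourceWeight) + truth@sourceWeight * mix)
  }
  if (sum(p) <= 0) stop("trueIntensity: all-zero intensity")
  rasterGrid(p / sum(p), g@origin, g@cellSize, g@nodata, g@crs)
}

#' Generate synthetic village centroids
#'
#' Uniform over the landscape extent; the surveyed subset is the first
#' `nSurveyed` villages.
#'
#' @param landscape a [LandscapeBundle-class].
#' @param nVillages number of villages in the landscape.
#' @param seed integer seed.
#' @return data.frame with `village_id`, `x`, `y` (km).
#' @export
genVillages <- function(landscape, nVillages = 2300, seed = 1L) {
  set.seed(seed)
  e <- landscape@extent
  data.frame(
    village_id = sprintf("V%04d", seq_len(nVillages)),
    x = runif(nVillages, e[1], e[3]),
    y = runif(nVillages, e[2], e[4]),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic encounter records
#'
#' Locations are drawn from [trueIntensity()] (cell sampled by probability,
#' position uniform within the cell); each record receives a category from the
#' truth's category mix, a date uniform over a 13-year window, and the village
#' of the nearest village centroid.
#'
#' @param landscape a [LandscapeBundle-class].
#' @param truth a [TruthParams-class].
#' @param villages village table from [genVillages()].
#' @param nEvents number of encounter records (>= 1).
#' @param seed integer seed.
#' @param dateRange character length-2, ISO dates bounding the record window.
#' @param exactCategories if TRUE, category counts are the largest-remainder
#'   rounding of `nEvents * categoryMix` (shuffled over records) rather than
#'   multinomial draws.
#' @return data.frame of records: `event_id`, `x`, `y`, `date`, `category`,
#'   `village_id`.
#' @export
genEncounters <- function(landscape, truth, villages, nEvents = 228, seed = 1L,
                          dateRange = c("2000-01-01", "2012-12-31"),
                          exactCategories = FALSE) {
  if (nEvents < 1) stop("genEncounters: nEvents must be >= 1")
  intensity <- trueIntensity(landscape, truth)
  v <- values(intensity)
  set.seed(seed)
  cells <- sample.int(length(v), nEvents, replace = TRUE, prob = as.vector(v))
  ri <- (cells - 1L) %% nrow(v) + 1L
  ci <- (cells - 1L) %/% nrow(v) + 1L
  cs <- cellSize(intensity)
  x <- intensity@origin[1] + (ci - 1L) * cs + runif(nEvents) * cs
  y <- intensity@origin[2] + (ri - 1L) * cs + runif(nEvents) * cs

  if (exactCategories) {
    target <- floor(nEvents * truth@categoryMix)
    rem <- nEvents - sum(target)
    if (rem > 0) {
      frac <- nEvents * truth@categoryMix - target
      target[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        target[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    category <- sample(rep(ENCOUNTER_CATEGORIES, times = target))
  } else {
    category <- sample(ENCOUNTER_CATEGORIES, nEvents, replace = TRUE,
                       prob = truth@categoryMix)
  }

  d0 <- as.Date(dateRange[1]); d1 <- as.Date(dateRange[2])
  date <- d0 + floor(runif(nEvents) * (as.numeric(d1 - d0) + 1))

  vid <- villages$village_id[nearestVillage(x, y, villages)]
  data.frame(event_id = sprintf("E%04d", seq_len(nEvents)),
             x = x, y = y, date = date, category = category,
             village_id = vid, stringsAsFactors = FALSE)
}

nearestVillage <- function(x, y, villages) {
  vx <- villages$x; vy <- villages$y
  vapply(seq_along(x), function(i) which.min((vx - x[i])^2 + (vy - y[i])^2), 1L)
}

#' Select survey villages stratified by encounter density
#'
#' Emulates a survey design that stratifies sampling across
#' encounter-density zones: a fraction `denseFrac` of the surveyed villages
#' is drawn (probability proportional to the village's encounter record) from
#' villages with reported encounters, the remainder uniformly from the rest
#' of the landscape.
#'
#' @param villages full village table.
#' @param encounters encounter records (with `village_id`, or `x`/`y` from
#'   which the nearest village is used).
#' @param n number of villages to survey.
#' @param denseFrac fraction of surveyed villages from encounter villages.
#' @param seed integer seed.
#' @return surveyed subset of `villages`.
#' @export
selectSurveyVillages <- function(villages, encounters, n = 75,
                                 denseFrac = 7 / 11, seed = 1L) {
  set.seed(seed)
  vid <- if ("village_id" %in% names(encounters)) encounters$village_id else
    villages$village_id[nearestVillage(encounters$x, encounters$y, villages)]
  counts <- table(vid)
  w <- as.numeric(counts[villages$village_id])
  w[is.na(w)] <- 0
  dense <- which(w > 0)
  sparse <- which(w == 0)
  nDense <- min(length(dense), round(denseFrac * n))
  pickDense <- if (nDense > 0)
    sample(dense, nDense, prob = w[dense]) else integer(0)
  nSparse <- min(length(sparse), n - nDense)
  pickSparse <- if (nSparse > 0) sample(sparse, nSparse) else integer(0)
  villages[sort(c(pickDense, pickSparse)), , drop = FALSE]
}

#' Generate synthetic questionnaire responses
#'
#' Respondents are assigned uniformly to the supplied (surveyed) villages.
#' The fourteen 1-5 psychometric items load on a shared pro-conservation
#' latent plus a scenario-specific factor (so the four management-scenario
#' items form a coherent one-dimensional scale). The 3-category tolerance
#' response is drawn from a multinomial logit with the truth's coefficients
#' applied to the centred items (item minus the neutral midpoint 3) and the
#' z-scored geographic-profile value at the respondent's village; don't-know
#' and missing responses are injected at the configured rates.
#'
#' @param villages surveyed-village table (`village_id`, `x`, `y`).
#' @param gpSurface a [RasterGrid-class] of geoprofile scores (any monotone
#'   scale; values are z-scored across respondents before entering the logit).
#' @param truth a [TruthParams-class].
#' @param nRespondents number of respondents.
#' @param seed integer seed.
#' @return data.frame with `village_id`, `sex`, `age`, `ethnicity`, the items
#'   of [SURVEY_ITEMS], and `tolerance` in
#'   {reduce_eradicate, same, increase, dont_know, missing}.
#' @export
genSurvey <- function(villages, gpSurface, truth, nRespondents = 2386,
                      seed = 1L) {
  if (nrow(villages) == 0) stop("genSurvey: villages must be non-empty")
  set.seed(seed)
  n <- nRespondents
  vidx <- sample.int(nrow(villages), n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.739, 0.261))
  age <- pmax(17, round(rnorm(n, 43.8, 12.7)))
  ethnicity <- sample(c("Minangkabau", "Melayu", "Javanese", "Rejang",
                        "Kerincinese", "Other"), n, replace = TRUE,
                      prob = c(0.454, 0.325, 0.071, 0.065, 0.029, 0.056))

  latent <- rnorm(n)
  scen <- rnorm(n)
  drawItem <- function(load, extra = 0, extraLoad = 0, noise = 0.9) {
    raw <- 3 + load * latent + extraLoad * extra + rnorm(n, sd = noise)
    pmin(5, pmax(1, round(raw)))
  }
  items <- data.frame(
    BadGood = drawItem(0.8), DangHarm = drawItem(0.4),
    Kill_tiger = drawItem(0.7), Protect_tiger = drawItem(0.7),
    Descriptive = drawItem(0.5), Injunctive = drawItem(0.3),
    Spirit = drawItem(0.6), Health = drawItem(0.5), Env = drawItem(0.5),
    TrustB = drawItem(0.3),
    ScenA = drawItem(0.2, scen, 0.43, 0.82), ScenB = drawItem(0.2, scen, 0.83, 0.82),
    ScenC = drawItem(0.2, scen, 1.37, 0.82), ScenD = drawItem(0.2, scen, 1.07, 0.82)
  )

  gpRaw <- if (is.null(gpSurface)) rep(0, n) else
    cellValueAt(gpSurface, villages$x[vidx], villages$y[vidx])
  gpRaw[is.na(gpRaw)] <- mean(gpRaw, na.rm = TRUE)
  gpz <- if (sd(gpRaw) > 0) (gpRaw - mean(gpRaw)) / sd(gpRaw) else gpRaw * 0

  b <- truth@toleranceBeta
  X <- cbind(`(Intercept)` = 1, as.matrix(items) - 3, gp = gpz)
  etaInc <- as.vector(X[, colnames(b), drop = FALSE] %*% b["increase", ])
  etaSame <- as.vector(X[, colnames(b), drop = FALSE] %*% b["same", ])
  den <- 1 + exp(etaInc) + exp(etaSame)
  pInc <- exp(etaInc) / den; pSame <- exp(etaSame) / den
  u <- runif(n)
  tolerance <- ifelse(u < pInc, "increase",
                      ifelse(u < pInc + pSame, "same", "reduce_eradicate"))

  u2 <- runif(n)
  tolerance[u2 < truth@dontknowRate] <- "dont_know"
  tolerance[u2 >= truth@dontknowRate &
              u2 < truth@dontknowRate + truth@missingRate] <- "missing"

  cbind(data.frame(village_id = villages$village_id[vidx], sex = sex,
                   age = age, ethnicity = ethnicity,
                   stringsAsFactors = FALSE),
        items,
        data.frame(tolerance = tolerance, stringsAsFactors = FALSE))
}
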
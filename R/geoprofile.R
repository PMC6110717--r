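#' Configure the DPM geoprofile sampler
#'
#' Defaults follow standard practice for this model family: 50,000 samples
#' per chain, 10 chains, burn-in 10,000, with sigma fitted from the data.
#' The location prior defaults to the data centroid with standard deviation
#' tau equal to the maximum data extent (a diffuse, data-scaled prior); the
#' Dirichlet-process concentration defaults to 1.
#'
#' @param samplesPerChain,burnIn,nChains MCMC run lengths.
#' @param sigma fixed dispersal sd in km, or `"fit"` / `NA` to sample it.
#' @param dpConcentration CRP concentration parameter.
#' @param priorCentre,priorSd location-prior mean (km) and sd tau (km);
#'   `NA` resolves to data-scaled values at fit time.
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param seed integer master seed.
#' @return a [DPMConfig-class].
#' @export
dpmConfig <- function(samplesPerChain = 50000, burnIn = 10000, nChains = 10,
                      sigma = "fit", dpConcentration = 1.0,
                      priorCentre = c(NA, NA), priorSd = NA, thin = 10,
                      seed = 1) {
  sig <- if (identical(sigma, "fit")) NA_real_ else as.numeric(sigma)
  new("DPMConfig", samplesPerChain = as.integer(samplesPerChain),
      burnIn = as.integer(burnIn), nChains = as.integer(nChains),
      sigma = sig, dpConcentration = dpConcentration,
      priorCentre = as.numeric(priorCentre), priorSd = as.numeric(priorSd),
      thin = as.integer(thin), seed = as.integer(seed))
}

#' Nominal retained draw count of a sampler configuration
#'
#' `nChains * (samplesPerChain - burnIn)`, before thinning.
#' @param config a [DPMConfig-class].
#' @export
retainedDraws <- function(config) {
  config@nChains * (config@samplesPerChain - config@burnIn)
}

setMethod("show", "DPMPosterior", function(object) {
  ktab <- table(object@clusterCountDraws)
  cat(sprintf("DPMPosterior: %d points, %d retained draws (%d kept after thinning)\n",
              ncol(object@assignments), object@retained, nrow(object@assignments)))
  cat(sprintf("  cluster-count mode %s; sigma mean %.2f km; split-Rhat(K) %.3f\n",
              names(ktab)[which.max(ktab)], mean(object@sigmaDraws), object@rhat))
})

resolvePrior <- function(points, config) {
  pc <- config@priorCentre
  if (any(is.na(pc))) pc <- colMeans(points)
  tau <- config@priorSd
  if (is.na(tau)) {
    ext <- max(apply(points, 2, function(v) diff(range(v))))
    tau <- max(ext, 1)
  }
  list(centre = pc, tau = tau)
}

splitRhat <- function(chainsMat) {
  # chainsMat: iterations x chains numeric; split each chain in half
  halves <- do.call(cbind, lapply(seq_len(ncol(chainsMat)), function(j) {
    v <- chainsMat[, j]
    h <- floor(length(v) / 2)
    cbind(v[seq_len(h)], v[h + seq_len(h)])
  }))
  m <- ncol(halves); n <- nrow(halves)
  if (n < 2) return(NA_real_)
  means <- colMeans(halves)
  B <- n * var(means)
  W <- mean(apply(halves, 2, var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Dirichlet-process-mixture geoprofile model
#'
#' Collapsed Gibbs sampling of the partition of encounter points into
#' clusters of bivariate-normal sources under a Chinese-restaurant-process
#' prior. Source locations carry a conjugate Normal(priorCentre, tau^2 I)
#' prior and are integrated out; the dispersal sd sigma is either fixed or
#' sampled each sweep over 50 log-spaced values by its conditional posterior.
#' Chains start from distinct sub-seeds and their post-burn-in draws are
#' pooled; a split-R-hat on the cluster-count trace is computed and a warning
#' raised above 1.1.
#'
#' @param points two-column matrix or data.frame of `(x, y)` in km.
#' @param config a [DPMConfig-class].
#' @return a [DPMPosterior-class].
#' @export
fitDPM <- function(points, config = dpmConfig()) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(points) <- "double"
  if (nrow(points) < 1) stop("fitDPM: need at least one point")
  if (any(!is.finite(points))) stop("fitDPM: non-finite coordinates")
  prior <- resolvePrior(points, config)

  fitSigma <- is.na(config@sigma)
  if (fitSigma) {
    ext <- max(apply(points, 2, function(v) diff(range(v))), 1)
    sigmaGrid <- exp(seq(log(0.1), log(2 * ext), length.out = 50))
    sigmaInit <- exp(mean(log(range(sigmaGrid))))
  } else {
    sigmaGrid <- numeric(0)
    sigmaInit <- config@sigma
  }

  perChain <- vector("list", config@nChains)
  subseeds <- config@seed + 1000L * seq_len(config@nChains)
  for (ch in seq_len(config@nChains)) {
    set.seed(subseeds[ch])
    perChain[[ch]] <- dpm_gibbs_chain(points, sigmaInit, fitSigma, sigmaGrid,
                                      config@dpConcentration,
                                      prior$centre[1], prior$centre[2],
                                      prior$tau, config@samplesPerChain,
                                      config@burnIn, config@thin)
  }
  assignments <- do.call(rbind, lapply(perChain, `[[`, "assignments"))
  sigmaDraws <- unlist(lapply(perChain, `[[`, "sigma"))
  kDraws <- unlist(lapply(perChain, `[[`, "k"))
  kMat <- do.call(cbind, lapply(perChain, function(p) as.numeric(p$k)))
  rhat <- splitRhat(kMat)
  if (is.finite(rhat) && rhat > 1.1)
    warning(sprintf("fitDPM: split-Rhat on cluster count = %.2f (> 1.1)", rhat))

  cfg <- config
  cfg@priorCentre <- as.numeric(prior$centre)
  cfg@priorSd <- prior$tau
  new("DPMPosterior", assignments = assignments, sigmaDraws = sigmaDraws,
      clusterCountDraws = as.integer(kDraws),
      retained = as.integer(retainedDraws(config)), points = points,
      config = cfg, rhat = rhat)
}

#' Two-stage sigma fitting on deduplicated points
#'
#' Repeated identical coordinates drag the fitted dispersal sd towards zero,
#' so sigma is first fitted on the unique points only; the posterior mean
#' sigma-hat is then fixed for a second run on the full point set.
#'
#' @inheritParams fitDPM
#' @return list with `sigma_hat` (km) and `posterior` (the stage-2
#'   [DPMPosterior-class] on all points).
#' @export
twoStageSigma <- function(points, config = dpmConfig()) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  uni <- unique(points)
  if (nrow(uni) < 2)
    stop("twoStageSigma: sigma is unidentifiable from < 2 unique points")
  if (nrow(uni) < nrow(points))
    message(sprintf("twoStageSigma: %d duplicate points removed for stage 1",
                    nrow(points) - nrow(uni)))
  cfg1 <- config
  cfg1@sigma <- NA_real_
  stage1 <- fitDPM(uni, cfg1)
  sigmaHat <- mean(stage1@sigmaDraws)
  cfg2 <- config
  cfg2@sigma <- sigmaHat
  cfg2@seed <- config@seed + 1L
  list(sigma_hat = sigmaHat, posterior = fitDPM(points, cfg2),
       stage1 = stage1)
}

#' Posterior-predictive geoprofile surface
#'
#' For every retained draw the partition implies, per cluster, a Gaussian
#' posterior for the source location (conjugate update of the location
#' prior); convolving with the dispersal kernel gives the posterior
#' predictive density of the next encounter, and the surface is its
#' draw-average: sum_k (n_k / (n + alpha)) N(cell | m_k, (s_k^2 + sigma^2) I)
#' plus the new-cluster term
#' (alpha / (n + alpha)) N(cell | priorCentre, (tau^2 + sigma^2) I),
#' renormalised to sum to 1 over valid cells. Spreading by the dispersal sd
#' (rather than ranking by the near-delta source posterior alone) is what
#' makes the profile searchable for future encounters, the quantity the
#' hitscore validation measures. The rank raster gives each cell's
#' search-order fraction (descending probability, ties by cell index).
#'
#' @param posterior a [DPMPosterior-class].
#' @param grid a [RasterGrid-class] defining the output geometry (must cover
#'   all fitted points).
#' @return a [GeoProfile-class].
#' @export
profileSurface <- function(posterior, grid) {
  if (nrow(posterior@assignments) == 0) stop("profileSurface: empty posterior")
  pts <- posterior@points
  pc <- pointToCell(grid, pts[, 1], pts[, 2])
  if (!all(pc$inside)) stop("profileSurface: grid does not cover all points")
  cfg <- posterior@config
  m0 <- cfg@priorCentre; tau <- cfg@priorSd; alpha <- cfg@dpConcentration
  n <- nrow(pts)
  cc <- cellCentres(grid)
  d <- dim(values(grid))
  acc <- matrix(0, d[1], d[2])
  nd <- nrow(posterior@assignments)
  for (it in seq_len(nd)) {
    z <- posterior@assignments[it, ]
    s2 <- posterior@sigmaDraws[it]^2
    for (k in unique(z)) {
      mem <- z == k
      nk <- sum(mem)
      prec <- 1 / tau^2 + nk / s2
      vpost <- 1 / prec
      mx <- (m0[1] / tau^2 + sum(pts[mem, 1]) / s2) * vpost
      my <- (m0[2] / tau^2 + sum(pts[mem, 2]) / s2) * vpost
      vpred <- vpost + s2
      acc <- acc + (nk / (n + alpha)) *
        outer(dnorm(cc$y, my, sqrt(vpred)), dnorm(cc$x, mx, sqrt(vpred)))
    }
    acc <- acc + (alpha / (n + alpha)) *
      outer(dnorm(cc$y, m0[2], sqrt(tau^2 + s2)),
            dnorm(cc$x, m0[1], sqrt(tau^2 + s2)))
  }
  nodataMask <- values(grid) == grid@nodata
  acc[nodataMask] <- 0
  acc <- acc / sum(acc)
  surf <- acc
  surf[nodataMask] <- grid@nodata
  surface <- rasterGrid(surf, grid@origin, grid@cellSize, grid@nodata, grid@crs)

  valid <- which(!nodataMask)
  ord <- valid[order(-acc[valid], valid)]
  rk <- matrix(NA_real_, d[1], d[2])
  rk[ord] <- seq_along(ord) / length(ord)
  rk[nodataMask] <- grid@nodata
  rank <- rasterGrid(rk, grid@origin, grid@cellSize, grid@nodata, grid@crs)
  new("GeoProfile", surface = surface, rank = rank)
}

#' Hitscores of target points under a geoprofile
#'
#' The hitscore of a point is the fraction of the searchable area examined,
#' in decreasing-probability order, before the point's cell is reached:
#' (cells strictly greater + half the other tied cells + the cell itself) /
#' total valid cells. Points on nodata cells or outside the grid are NA.
#'
#' @param profile a [GeoProfile-class].
#' @param x,y target coordinates, km.
#' @return numeric vector of fractions in (0, 1] (NA where flagged).
#' @export
hitScores <- function(profile, x, y) {
  surf <- profile@surface
  v <- values(surf)
  valid <- v != surf@nodata
  vv <- v[valid]
  ncells <- length(vv)
  pv <- cellValueAt(surf, x, y)
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(pv[i])) next
    greater <- sum(vv > pv[i])
    ties <- sum(vv == pv[i]) - 1
    out[i] <- (greater + ties / 2 + 1) / ncells
  }
  out
}

#' Gini coefficient of a set of hitscores
#'
#' With F the empirical CDF of the hitscores, returns
#' `2 * integral_0^1 (F(x) - x) dx`, evaluated exactly from the step
#' function: `1 - 2 * mean(hitscores)`. A value of 1 means every target was
#' found immediately (perfect search); 0 is the random-search baseline.
#'
#' @param hitscores numeric vector of fractions in (0, 1]; NAs are dropped.
#' @return real in \[-1, 1\].
#' @export
giniCoefficient <- function(hitscores) {
  hs <- hitscores[!is.na(hitscores)]
  if (length(hs) == 0) stop("giniCoefficient: no hitscores")
  1 - 2 * mean(hs)
}

#' Train a profile on one encounter category and validate on others
#'
#' Fits the DPM geoprofile on the training points (typically sightings),
#' builds the surface, and evaluates hitscores and the Gini coefficient on
#' the held-out points (typically attacks and removals). Also reports the
#' fraction of test points located within given search fractions of the area.
#'
#' @param trainPoints,testPoints two-column coordinate tables, km.
#' @param grid a [RasterGrid-class] for the profile geometry.
#' @param config a [DPMConfig-class].
#' @param searchFractions area fractions at which to report recovery.
#' @return list with `hitscores`, `gini`, `found_at` (named fractions of test
#'   points found), `profile`, `posterior`.
#' @export
validateByCategory <- function(trainPoints, testPoints, grid,
                               config = dpmConfig(),
                               searchFractions = c(0.15, 0.30)) {
  testPoints <- as.matrix(testPoints)[, 1:2, drop = FALSE]
  if (nrow(testPoints) == 0) stop("validateByCategory: empty test set")
  post <- fitDPM(trainPoints, config)
  prof <- profileSurface(post, grid)
  hs <- hitScores(prof, testPoints[, 1], testPoints[, 2])
  found <- vapply(searchFractions,
                  function(f) mean(hs[!is.na(hs)] <= f), numeric(1))
  list(hitscores = hs, gini = giniCoefficient(hs),
       found_at = setNames(found, sprintf("%g%%", 100 * searchFractions)),
       profile = prof, posterior = post)
}

#' Posterior mean source locations of the largest clusters
#'
#' Utility summarising a [DPMPosterior-class]: for each retained draw the
#' conjugate posterior mean of every cluster's source, weighted by cluster
#' size, accumulated onto the draw's clusters, then aggregated by k-means
#' over draws into `k` representative source locations.
#'
#' @param posterior a [DPMPosterior-class].
#' @param k number of sources to summarise.
#' @return `k x 2` matrix of source coordinates, km.
#' @export
sourceSummary <- function(posterior, k) {
  pts <- posterior@points
  cfg <- posterior@config
  m0 <- cfg@priorCentre; tau <- cfg@priorSd
  centres <- list()
  for (it in seq_len(nrow(posterior@assignments))) {
    z <- posterior@assignments[it, ]
    s2 <- posterior@sigmaDraws[it]^2
    for (cl in unique(z)) {
      mem <- z == cl
      nk <- sum(mem)
      vpost <- 1 / (1 / tau^2 + nk / s2)
      centres[[length(centres) + 1]] <-
        c((m0[1] / tau^2 + sum(pts[mem, 1]) / s2) * vpost,
          (m0[2] / tau^2 + sum(pts[mem, 2]) / s2) * vpost, nk)
    }
  }
  cm <- do.call(rbind, centres)
  km <- stats::kmeans(cm[, 1:2], centers = k, nstart = 5,
                      iter.max = 50)
  km$centers
}
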
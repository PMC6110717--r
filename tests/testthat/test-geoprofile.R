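test_that("sampler configuration carries the standard run lengths", {
  cfg <- dpmConfig()
  expect_equal(cfg@samplesPerChain, 50000L)
  expect_equal(cfg@burnIn, 10000L)
  expect_equal(cfg@nChains, 10L)
  expect_equal(retainedDraws(cfg), 10 * (50000 - 10000))
  expect_error(dpmConfig(samplesPerChain = 100, burnIn = 100), "burnIn")
  expect_error(dpmConfig(sigma = -1), "sigma")
})

test_that("a single point always forms exactly one cluster", {
  post <- fitDPM(cbind(3, 4), quickDpmConfig(sigma = 5, priorSd = 50))
  expect_true(all(post@clusterCountDraws == 1L))
  expect_true(all(post@assignments == 1L))
})

test_that("every retained draw is a valid partition and order does not matter", {
  pts <- twoClusterPoints(25, 25, sep = 60, seed = 2)
  post <- fitDPM(pts, quickDpmConfig(sigma = 5, priorSd = 200))
  for (i in seq_len(nrow(post@assignments))) {
    z <- post@assignments[i, ]
    expect_true(all(sort(unique(z)) == seq_len(max(z))))
    expect_equal(max(z), post@clusterCountDraws[i])
  }
  # exchangeability: permuting input order leaves the cluster-count
  # distribution unchanged within Monte-Carlo error
  perm <- pts[sample(nrow(pts)), ]
  post2 <- fitDPM(perm, quickDpmConfig(sigma = 5, priorSd = 200, seed = 77))
  expect_lt(abs(mean(post@clusterCountDraws) - mean(post2@clusterCountDraws)),
            0.2)
})

test_that("well-separated clusters are recovered in count and location", {
  pts <- twoClusterPoints(50, 50, sep = 100, sd = 5, seed = 1)
  post <- fitDPM(pts, quickDpmConfig(sigma = 5, priorSd = 200))
  ktab <- table(post@clusterCountDraws)
  expect_equal(as.integer(names(ktab)[which.max(ktab)]), 2L)
  src <- sourceSummary(post, 2)
  truth <- rbind(c(0, 0), c(100, 0))
  for (k in 1:2) {
    d <- min(sqrt((src[, 1] - truth[k, 1])^2 + (src[, 2] - truth[k, 2])^2))
    expect_lt(d, 2)
  }
  # independent finite-mixture cross-check on the same data
  km <- kmeans(pts, centers = rbind(c(0, 0), c(100, 0)))
  for (k in 1:2) {
    d <- min(sqrt((src[, 1] - km$centers[, 1])^2 +
                    (src[, 2] - km$centers[, 2])^2))
    expect_lt(d, 0.5)
  }
})

test_that("two-stage sigma deduplicates and recovers the dispersal scale", {
  same <- matrix(rep(c(5, 5), 10), ncol = 2, byrow = TRUE)
  expect_error(twoStageSigma(same, quickDpmConfig()), "unidentifiable")

  set.seed(3)
  pts <- cbind(rnorm(100, 50, 27), rnorm(100, 50, 27))
  doubled <- rbind(pts, pts)
  expect_message(
    ts <- twoStageSigma(doubled, quickDpmConfig(seed = 9)),
    "duplicate")
  expect_equal(nrow(ts$stage1@points), 100)
  expect_equal(nrow(ts$posterior@points), 200)
  expect_gt(ts$sigma_hat, 20)
  expect_lt(ts$sigma_hat, 35)
  # stage 2 runs at fixed sigma
  expect_true(all(ts$posterior@sigmaDraws == ts$sigma_hat))
})

test_that("profile surface normalises, concentrates, and respects symmetry", {
  grid <- rasterGrid(matrix(0, 40, 50), origin = c(-50, -40), cellSize = 4)
  # single point far from the prior centre with tau >> sigma
  cfg1 <- quickDpmConfig(sigma = 3, priorCentre = c(-40, -30), priorSd = 500)
  post1 <- fitDPM(cbind(121, 101), cfg1)
  prof1 <- profileSurface(post1, rasterGrid(matrix(0, 40, 50),
                                            origin = c(0, 0), cellSize = 4))
  v <- values(prof1@surface)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  am <- which(v == max(v), arr.ind = TRUE)
  pc <- pointToCell(prof1@surface, 121, 101)
  expect_equal(unname(am[1, ]), c(pc$row, pc$col))

  # two equal clusters exactly mirrored about x = 0
  set.seed(5)
  a <- cbind(rnorm(40, 60, 5), rnorm(40, 0, 5))
  pts <- rbind(a, cbind(-a[, 1], a[, 2]))
  grid2 <- rasterGrid(matrix(0, 30, 80), origin = c(-160, -60), cellSize = 4)
  post2 <- fitDPM(pts, quickDpmConfig(sigma = 5, priorCentre = c(0, 0),
                                      priorSd = 300))
  prof2 <- profileSurface(post2, grid2)
  v2 <- values(prof2@surface)
  mirrored <- v2[, rev(seq_len(ncol(v2)))]
  expect_lt(max(abs(v2 - mirrored)), 0.1 * max(v2))
  expect_error(profileSurface(post2, rasterGrid(matrix(0, 3, 3))), "cover")
})

test_that("hitscores match enumeration and are monotone-transform invariant", {
  surf <- rasterGrid(matrix(c(0.4, 0.3, 0.2, 0.1), 2, 2), cellSize = 1)
  rank <- rasterGrid(matrix(c(1, 2, 3, 4) / 4, 2, 2), cellSize = 1)
  prof <- new("GeoProfile", surface = surf, rank = rank)
  # cells: [1,1]=0.4 (best), [2,1]=0.3, [1,2]=0.2, [2,2]=0.1
  expect_equal(hitScores(prof, 0.5, 0.5), 1 / 4)   # argmax cell
  expect_equal(hitScores(prof, 0.5, 1.5), 2 / 4)   # the 0.3 cell -> 0.5
  expect_equal(hitScores(prof, 1.5, 1.5), 1.0)     # minimum cell
  # strictly monotone transform of the surface leaves hitscores unchanged
  surfT <- rasterGrid(sqrt(values(surf)) + 2, cellSize = 1)
  profT <- new("GeoProfile",
               surface = rasterGrid(values(surfT) / sum(values(surfT)),
                                    cellSize = 1), rank = rank)
  xs <- c(0.5, 0.5, 1.5, 1.5); ys <- c(0.5, 1.5, 0.5, 1.5)
  expect_equal(hitScores(profT, xs, ys), hitScores(prof, xs, ys))
})

test_that("the Gini coefficient equals the step-function integral", {
  # direct trapezoid integration of 2 * (F(x) - x) on a fine grid
  giniIntegral <- function(hs) {
    F <- ecdf(hs)
    x <- seq(0, 1, length.out = 20001)
    y <- 2 * (F(x) - x)
    sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  }
  hs <- c(0.1, 0.2, 0.5)
  expect_equal(giniCoefficient(hs), giniIntegral(hs), tolerance = 1e-3)
  set.seed(8)
  hs2 <- runif(40)
  expect_equal(giniCoefficient(hs2), giniIntegral(hs2), tolerance = 1e-3)
  expect_equal(giniCoefficient(rep(1e-9, 5)), 1, tolerance = 1e-6)
  expect_equal(giniCoefficient(seq(1e-4, 1, length.out = 10000)), 0,
               tolerance = 1e-3)
  expect_error(giniCoefficient(numeric(0)), "no hitscores")
})

test_that("category-based validation reports hitscores, gini and search fractions", {
  grid <- rasterGrid(matrix(0, 25, 25), cellSize = 4)
  one <- cbind(50, 50)
  val <- validateByCategory(one, one, grid,
                            quickDpmConfig(sigma = 3, priorSd = 300))
  expect_equal(val$hitscores, 1 / (25 * 25))
  expect_gt(val$gini, 0.99)
  expect_equal(unname(val$found_at), c(1, 1))
  expect_error(validateByCategory(one, one[0, , drop = FALSE], grid,
                                  quickDpmConfig()), "empty test set")
})
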
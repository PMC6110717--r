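test_that("covariate extraction averages buffers and keeps the village radius default", {
  land <- smallLandscape()
  pts <- data.frame(x = c(20, 50), y = c(20, 40))
  got <- extractCovariates(pts, land)
  expect_setequal(names(got), names(land@rasters))
  expect_equal(got$dis_riv,
               bufferMean(land@rasters$dis_riv, pts$x, pts$y, 3.25))
  expect_equal(attr(got, "radius"), 3.25)
  expect_equal(formals(extractCovariates)$radius, 3.25)
})

test_that("collinearity screening drops duplicates and matches the VIF oracle", {
  set.seed(2)
  n <- 200
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  # duplicated column: exactly one of the pair survives
  dup <- data.frame(a = a, b = b, a2 = a)
  scr <- screenCollinearity(dup)
  expect_equal(ncol(scr$kept), 2)
  expect_equal(sum(c("a", "a2") %in% names(scr$kept)), 1)
  # orthogonal columns: none dropped
  orth <- data.frame(a = a, b = b, c_ = c_)
  expect_equal(ncol(screenCollinearity(orth)$kept), 3)
  # near-linear dependence: the max-VIF column goes, VIFs match 1/(1 - R^2)
  dep <- data.frame(x1 = a, x2 = b, x3 = a + b + rnorm(n, sd = 0.1))
  vifs <- vifValues(dep)
  for (j in names(dep)) {
    r2 <- summary(lm(dep[[j]] ~ ., data = dep[setdiff(names(dep), j)]))$r.squared
    expect_equal(vifs[[j]], 1 / (1 - r2), tolerance = 1e-8)
  }
  scr2 <- screenCollinearity(dep)
  expect_equal(scr2$report$column[1], names(which.max(vifs)))
  expect_true(all(vifValues(scr2$kept) < 3))
  # constant columns are dropped with a warning
  expect_warning(screenCollinearity(data.frame(a = a, k = rep(1, n))),
                 "constant")
})

test_that("pseudo-absences stay in the mask and are uniform over cells", {
  land <- smallLandscape()
  fc <- values(land@rasters$for_cov)
  pa <- suppressWarnings(makePseudoAbsences(land, 2000, seed = 3))
  pc <- pointToCell(land@rasters$for_cov, pa$x, pa$y)
  expect_true(all(fc[cbind(pc$row, pc$col)] < 0.5))
  expect_equal(formals(makePseudoAbsences)$n, 10000)

  # chi-squared uniformity over a 100-cell mask
  mask <- matrix(FALSE, nrow(fc), ncol(fc)); mask[1:10, 1:10] <- TRUE
  expect_warning(pa2 <- makePseudoAbsences(land, 50000, seed = 4, mask = mask),
                 "reused")
  pc2 <- pointToCell(land@rasters$for_cov, pa2$x, pa2$y)
  counts <- table(factor(paste(pc2$row, pc2$col), levels =
                           paste(rep(1:10, times = 10), rep(1:10, each = 10))))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("AUC and TSS match their enumeration oracles", {
  s <- c(0.9, 0.8, 0.4, 0.2); l <- c(1, 0, 1, 0)
  expect_equal(aucScore(s, l), 0.75)
  expect_equal(tssScore(s, l), 0.5)
  expect_equal(aucScore(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(tssScore(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(tssScore(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0)
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
  expect_error(tssScore(1:3, c(0, 0, 0)), "both classes")
})

test_that("cross-validated AUC separates signal from null", {
  set.seed(6)
  n <- 400
  x <- data.frame(a = rnorm(n))
  sep <- as.integer(x$a > 0)        # perfectly separable
  expect_equal(suppressWarnings(crossvalAUC("glm", x, sep, reps = 3, seed = 1)),
               1.0)
  null <- sample(0:1, 2000, TRUE)   # labels independent of features
  xn <- data.frame(a = rnorm(2000), b = rnorm(2000))
  got <- crossvalAUC("glm", xn, null, reps = 10, seed = 2)
  expect_gt(got, 0.45); expect_lt(got, 0.55)
  expect_equal(formals(crossvalAUC)$reps, 10)
  expect_equal(formals(crossvalAUC)$trainFrac, 0.7)
})

test_that("the ensemble is a TSS-weighted convex combination of members", {
  set.seed(8)
  n <- 500
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c_ = rnorm(n))
  p <- plogis(2 * tab$a - 1.5 * tab$b)
  y <- rbinom(n, 1, p)
  ens <- fitEnsemble(tab, y, members = c("glm", "rf"), reps = 3, seed = 1)
  expect_equal(sum(ens@weights), 1)
  expect_equal(as.numeric(ens@weights),
               as.numeric(ens@tss / sum(ens@tss)))
  # convexity: member predictions bracket the ensemble prediction
  specs <- conflictscope:::memberSpecs()
  Xs <- scale(tab, ens@scaler$center, ens@scaler$scale)
  mem <- sapply(names(ens@members),
                function(nm) specs[[nm]]$pred(ens@members[[nm]]$fit, Xs))
  pe <- predictEnsemble(ens, tab)
  expect_true(all(pe >= apply(mem, 1, min) - 1e-12))
  expect_true(all(pe <= apply(mem, 1, max) + 1e-12))

  # a single passing member: ensemble equals that member
  ens1 <- fitEnsemble(tab, y, members = "glm", reps = 3, seed = 1)
  expect_equal(predictEnsemble(ens1, tab),
               as.numeric(specs$glm$pred(ens1@members$glm$fit,
                                         scale(tab, ens1@scaler$center,
                                               ens1@scaler$scale))))
  # no member passing raises an informative error
  noise <- data.frame(a = rnorm(300))
  expect_error(fitEnsemble(noise, sample(0:1, 300, TRUE), members = "glm",
                           reps = 3, seed = 2), "no member passed")
})

test_that("known TSS pair yields 0.75/0.25 weights and the weighted-mean oracle", {
  w <- c(0.6, 0.2) / sum(c(0.6, 0.2))
  expect_equal(w, c(0.75, 0.25))
  pm <- rbind(c(0.9, 0.1), c(0.2, 0.6), c(0.5, 0.5), c(1, 0), c(0.3, 0.9))
  expect_equal(as.numeric(pm %*% w),
               0.75 * pm[, 1] + 0.25 * pm[, 2])
})

test_that("prediction surfaces are probability-bounded and training-consistent", {
  land <- smallLandscape()
  truth <- truthParams(sourceCentres = rbind(c(30, 40), c(70, 30)),
                       sourceSd = 8, sourceWeight = 0.9)
  v <- genVillages(land, 30, seed = 1)
  enc <- genEncounters(land, truth, v, 150, seed = 2)
  pa <- makePseudoAbsences(land, 400, seed = 3)
  pts <- rbind(enc[, c("x", "y")], pa)
  y <- rep(1:0, c(nrow(enc), nrow(pa)))
  # cell-value covariates so surface lookups equal tabular predictions
  tab <- as.data.frame(lapply(land@rasters, cellValueAt, x = pts$x, y = pts$y))
  ens <- fitEnsemble(tab, y, members = c("glm", "brt"), reps = 3, seed = 4)
  surf <- predictSurface(ens, land)
  vs <- values(surf)
  expect_true(all(vs >= 0 & vs <= 1))
  atPoints <- cellValueAt(surf, pts$x, pts$y)
  expect_equal(atPoints, predictEnsemble(ens, tab), tolerance = 1e-6)
  expect_error(predictSurface(ens, new("LandscapeBundle",
                                       rasters = land@rasters["dis_riv"],
                                       extent = land@extent,
                                       cellSize = land@cellSize,
                                       seed = 1L)),
               "missing covariate")
})

test_that("permutation importance flags informative variables only", {
  set.seed(9)
  n <- 600
  tab <- data.frame(signal = rnorm(n), inert = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * tab$signal))
  ens <- fitEnsemble(tab, y, members = "glm", reps = 3, seed = 1)
  imp <- variableImportance(ens, tab, perms = 10, seed = 2)
  expect_gt(imp[["inert"]], 0.9)   # permutation-inert
  expect_lt(imp[["signal"]], 0.5)  # sole informative variable
})

test_that("ensemble cross-validated AUC approaches the Bayes AUC of the truth", {
  diffs <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 2500
    tab <- data.frame(a = rnorm(n), b = rnorm(n))
    p <- plogis(1.5 * tab$a - tab$b)
    y <- rbinom(n, 1, p)
    bayes <- aucScore(p, y)
    cv <- crossvalAUC("glm", tab, y, reps = 5, seed = s)
    abs(cv - bayes)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})
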
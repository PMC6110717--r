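test_that("response preparation excludes, orients and derives as documented", {
  s <- surveyWithExclusions(2386, 107, 30)
  prep <- prepareResponses(s)
  expect_equal(prep$report$dont_know, 107)
  expect_equal(prep$report$missing, 30)
  expect_equal(prep$report$retained, 2249)
  expect_equal(nrow(prep$data), 2249)
  # no exclusions: row count unchanged
  s2 <- s[s$tolerance %in% c("reduce_eradicate", "same", "increase"), ]
  expect_equal(nrow(prepareResponses(s2)$data), nrow(s2))
  # scenario scale: mean of the four items under the chosen orientation
  row <- prep$data[1, ]
  row[, c("ScenA", "ScenB", "ScenC", "ScenD")] <- c(1, 2, 3, 4)
  expect_equal(prepareResponses(row)$data$Scenario, 2.5)
  # reversal maps x -> 6 - x
  rev <- prepareResponses(row, reverseItems = "ScenA")$data
  expect_equal(rev$ScenA, 5)
})

test_that("scale diagnostics match closed forms", {
  set.seed(4)
  x <- rnorm(500)
  # two perfectly correlated items (KMO undefined there, with a warning)
  perf <- data.frame(a = x, b = x)
  expect_warning(d1 <- scaleDiagnostics(perf), "singular")
  expect_equal(d1$cronbach_alpha, 1)
  # two standardized items with correlation r: alpha = 2r / (1 + r)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(500)
  two <- data.frame(a = as.numeric(scale(x)), b = as.numeric(scale(y)))
  r <- cor(two$a, two$b)
  expect_equal(scaleDiagnostics(two)$cronbach_alpha, 2 * r / (1 + r),
               tolerance = 1e-10)
  expect_error(scaleDiagnostics(data.frame(a = x, b = rep(2, 500))),
               "zero-variance")
  # the generated scenario scale is coherent: per-item KMO above 0.6,
  # alpha and first-factor share near their configured levels
  land <- smallLandscape()
  v <- genVillages(land, 75, seed = 1)
  s <- genSurvey(v, land@rasters$connect, truthParams(), 2386, seed = 5)
  d <- scaleDiagnostics(s[, c("ScenA", "ScenB", "ScenC", "ScenD")])
  expect_true(all(d$kmo_per_item > 0.6))
  expect_equal(d$cronbach_alpha, 0.78, tolerance = 0.08)
  expect_gt(d$first_factor_variance_pct, 50)
  expect_true(all(d$loadings > 0))
})

test_that("multinomial fits reproduce closed-form saturated likelihoods", {
  s <- surveyWithExclusions(600, 0, 0)
  prep <- prepareResponses(s)
  f0 <- fitMultinomial(prep$data, character(0))
  tab <- table(prep$data$tolerance)
  expect_equal(f0@logLik, sum(tab * log(tab / sum(tab))), tolerance = 1e-6)
  expect_equal(f0@K, 2L)
  # fitted probabilities equal sample proportions
  p <- predict(f0@model, newdata = prep$data[1, ], type = "probs")
  expect_equal(as.numeric(p), as.numeric(tab / sum(tab)), tolerance = 1e-5)
  # log-likelihood invariant to reference relabelling
  relab <- prep$data
  relab$tolerance <- factor(as.character(relab$tolerance),
                            levels = c("increase", "same", "reduce_eradicate"))
  f0b <- nnet::multinom(tolerance ~ 1, relab, trace = FALSE)
  expect_equal(as.numeric(logLik(f0b)), f0@logLik, tolerance = 1e-6)
})

test_that("null predictors rarely reach |z| > 3", {
  hits <- vapply(1:10, function(s) {
    surv <- surveyWithExclusions(1200, 0, 0, seed = 100 + s)
    prep <- prepareResponses(surv)
    prep$data$noise <- rnorm(nrow(prep$data))
    fit <- fitMultinomial(prep$data, "noise")
    any(abs(fit@coefficients[, "noise"] / fit@se[, "noise"]) > 3)
  }, logical(1))
  expect_lte(sum(hits), 2)
})

test_that("the information criterion follows its formula exactly", {
  expect_equal(aicc(list(logLik = 0, K = 1, n = 1e9)), 2, tolerance = 1e-6)
  expect_error(aicc(list(logLik = -5, K = 10, n = 11)), "n > K")
  set.seed(1)
  for (i in 1:5) {
    ll <- -runif(1, 100, 3000); K <- sample(2:40, 1); n <- K + sample(5:500, 1)
    expect_equal(aicc(list(logLik = ll, K = K, n = n)),
                 -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1),
                 tolerance = 1e-10)
    expect_equal(aicc(list(logLik = ll, K = K, n = n), correction = FALSE),
                 -2 * ll + 2 * K, tolerance = 1e-10)
  }
})

test_that("model comparison weights, importance and evidence ratios behave", {
  # identical-AICc models, term A in one of them: importance(A) = 0.5
  mkFit <- function(ll, K, terms) {
    co <- matrix(0.1, 2, length(terms) + 1,
                 dimnames = list(c("same", "increase"),
                                 c("(Intercept)", terms)))
    new("MultinomialFit", coefficients = co, se = co * 0 + 0.05,
        logLik = ll, K = as.integer(K), n = 500L,
        terms = terms, model = NULL)
  }
  fits <- list(m1 = mkFit(-100, 4, c("A", "B")), m2 = mkFit(-100, 4, "B"))
  cmp <- compareModels(fits)
  expect_equal(sum(cmp@table$weight), 1)
  expect_equal(min(cmp@table$delta), 0)
  expect_equal(unname(cmp@importance[["A"]]), 0.5)
  expect_equal(unname(cmp@importance[["B"]]), 1)
  expect_setequal(cmp@confidenceSet, c("m1", "m2"))
  # averaged estimate of a shared coefficient with equal weights is the mean
  avg <- cmp@averaged
  bB <- avg[avg$term == "B" & avg$equation == "same", ]
  expect_equal(bB$estimate, 0.1)

  expect_equal(evidenceRatio(100, 100), 1)
  expect_equal(evidenceRatio(0, 6.96), exp(3.48))
  expect_equal(round(evidenceRatio(0, 6.96)), 32)
  expect_equal(round(evidenceRatio(0, 6.38)), 24)

  # weights and deltas invariant to adding a constant to every AICc
  a <- c(m1 = 3760.6, m2 = 3766.9, m3 = 3767.4)
  w1 <- aiccWeights(a); w2 <- aiccWeights(a + 57)
  expect_equal(w1$weight, w2$weight)
  expect_equal(w1$delta, w2$delta)
})

test_that("village risk covariates attach at the centroid and z-score", {
  land <- smallLandscape()
  v <- genVillages(land, 20, seed = 1)
  s <- surveyWithExclusions(300, 0, 0)
  s$village_id <- sample(v$village_id, 300, TRUE)
  prep <- prepareResponses(s)
  mt <- attachRiskCovariates(prep$data, v, geoprofile = land@rasters$connect,
                             riskSurface = land@rasters$occupancy)
  expect_equal(mean(mt$gp), 0, tolerance = 1e-10)
  expect_equal(sd(mt$gp), 1, tolerance = 1e-10)
  # respondents of one village share identical covariates
  for (vid in unique(mt$village_id)[1:5])
    expect_equal(length(unique(mt$gp[mt$village_id == vid])), 1)
  # flat surface is dropped with a warning
  flat <- rasterGrid(matrix(0.4, 40, 50), cellSize = 2)
  expect_warning(mt2 <- attachRiskCovariates(prep$data, v, geoprofile = flat),
                 "constant")
  expect_false("gp" %in% names(mt2))
  expect_error(attachRiskCovariates(transform(prep$data, village_id = "nope"),
                                    v), "unknown village_id")
})
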
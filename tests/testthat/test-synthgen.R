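test_that("generators are deterministic given a seed", {
  l1 <- smallLandscape(11); l2 <- smallLandscape(11)
  expect_identical(lapply(l1@rasters, values), lapply(l2@rasters, values))
  truth <- truthParams()
  v <- genVillages(l1, 50, seed = 2)
  e1 <- genEncounters(l1, truth, v, 100, seed = 3)
  e2 <- genEncounters(l1, truth, v, 100, seed = 3)
  expect_identical(e1, e2)
  s1 <- genSurvey(v, l1@rasters$connect, truth, 200, seed = 4)
  s2 <- genSurvey(v, l1@rasters$connect, truth, 200, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(values(smallLandscape(12)@rasters$pop_grd),
                         values(l1@rasters$pop_grd)))
})

test_that("landscape bundle honours its invariants and covariate roster", {
  land <- smallLandscape()
  expect_setequal(names(land@rasters),
                  c("dis_riv", "dis_rds", "dis_for", "for_cov", "pop_grd",
                    "farmers", "occupancy", "connect"))
  for (nm in c("dis_riv", "dis_rds", "dis_for"))
    expect_true(all(values(land@rasters[[nm]]) >= 0), label = nm)
  for (nm in c("for_cov", "occupancy", "connect")) {
    v <- values(land@rasters[[nm]])
    expect_true(all(v >= 0 & v <= 1), label = nm)
  }
  dims <- vapply(land@rasters, function(r) dim(values(r)), integer(2))
  expect_true(all(dims == dims[, 1]))
  expect_error(genLandscape(extent = c(0, 0, -5, 10)), "extent")
  expect_error(genLandscape(cellSize = 0), "cellSize")
})

test_that("flat truth yields spatially uniform encounters (quadrat GOF)", {
  land <- smallLandscape()
  flat <- truthParams(riskBeta = c(dis_riv = 0), sourceWeight = 0,
                      sourceCentres = matrix(numeric(0), 0, 2))
  v <- genVillages(land, 20, seed = 1)
  enc <- genEncounters(land, flat, v, 2000, seed = 9)
  qx <- cut(enc$x, seq(0, 100, by = 20), include.lowest = TRUE)
  qy <- cut(enc$y, seq(0, 80, by = 20), include.lowest = TRUE)
  gof <- chisq.test(as.vector(table(qx, qy)))
  expect_gt(gof$p.value, 0.01)
})

test_that("encounter categories follow the reference mix", {
  land <- smallLandscape()
  truth <- truthParams()
  v <- genVillages(land, 20, seed = 1)
  enc <- genEncounters(land, truth, v, 228, seed = 2, exactCategories = TRUE)
  expect_equal(table(factor(enc$category, ENCOUNTER_CATEGORIES)),
               table(factor(rep(ENCOUNTER_CATEGORIES,
                                c(106, 83, 12, 27)), ENCOUNTER_CATEGORIES)))
  # sampled mix: expected counts n * mix, checked loosely at n = 2000
  enc2 <- genEncounters(land, truth, v, 2000, seed = 3)
  got <- table(factor(enc2$category, ENCOUNTER_CATEGORIES))
  expected <- 2000 * c(106, 83, 12, 27) / 228
  expect_true(all(abs(got - expected) < 4 * sqrt(expected)))
})

test_that("dominant sources confine encounters to Gaussian neighbourhoods", {
  land <- genLandscape(extent = c(0, 0, 200, 60), cellSize = 2, seed = 4)
  truth <- truthParams(sourceCentres = rbind(c(50, 30), c(150, 30)),
                       sourceSd = 5, sourceWeight = 1)
  v <- genVillages(land, 20, seed = 1)
  enc <- genEncounters(land, truth, v, 1000, seed = 5)
  dmin <- pmin(sqrt((enc$x - 50)^2 + (enc$y - 30)^2),
               sqrt((enc$x - 150)^2 + (enc$y - 30)^2))
  expect_gte(mean(dmin <= 15), 0.95)
})

test_that("empirical encounter density tracks the true intensity surface", {
  land <- smallLandscape()
  truth <- truthParams(sourceCentres = rbind(c(30, 40), c(70, 50)),
                       sourceSd = 10, sourceWeight = 0.9)
  v <- genVillages(land, 20, seed = 1)
  enc <- genEncounters(land, truth, v, 5000, seed = 6)
  intens <- trueIntensity(land, truth)
  pc <- pointToCell(intens, enc$x, enc$y)
  counts <- matrix(0, nrow(values(intens)), ncol(values(intens)))
  for (i in seq_len(nrow(pc)))
    counts[pc$row[i], pc$col[i]] <- counts[pc$row[i], pc$col[i]] + 1
  expect_gt(cor(as.vector(counts), as.vector(values(intens))), 0.5)
})

test_that("survey margins, injection rates and slopes behave as configured", {
  land <- smallLandscape()
  v <- genVillages(land, 75, seed = 1)
  # symmetric logit: zero slopes and intercepts give 1/3 shares
  b0 <- defaultToleranceBeta() * 0
  sym <- truthParams(toleranceBeta = b0, dontknowRate = 0, missingRate = 0)
  s <- genSurvey(v, land@rasters$connect, sym, 30000, seed = 2)
  shares <- prop.table(table(s$tolerance))
  expect_true(all(abs(shares - 1 / 3) < 0.02))
  # default injection rates
  s2 <- genSurvey(v, land@rasters$connect, truthParams(), 30000, seed = 3)
  expect_equal(mean(s2$tolerance == "dont_know"), 0.045, tolerance = 0.15)
  expect_equal(mean(s2$tolerance == "missing"), 0.012, tolerance = 0.3)
})

test_that("survey-village selection is stratified towards encounter villages", {
  land <- smallLandscape()
  v <- genVillages(land, 400, seed = 1)
  enc <- genEncounters(land, truthParams(sourceCentres = rbind(c(30, 40)),
                                         sourceSd = 8, sourceWeight = 1),
                       v, 120, seed = 2)
  sel <- selectSurveyVillages(v, enc, n = 40, seed = 3)
  expect_equal(nrow(sel), 40)
  expect_identical(sel, selectSurveyVillages(v, enc, n = 40, seed = 3))
  encVil <- unique(enc$village_id)
  # roughly 7/11 of surveyed villages come from the encounter stratum
  expect_gte(sum(sel$village_id %in% encVil), round(7 / 11 * 40) - 5)
  expect_gt(mean(!sel$village_id %in% encVil), 0)  # sparse stratum present
})

test_that("refitting the survey model recovers the generating slopes", {
  land <- smallLandscape()
  v <- genVillages(land, 75, seed = 1)
  truth <- truthParams()
  s <- genSurvey(v, land@rasters$connect, truth, 5000, seed = 7)
  prep <- prepareResponses(s)
  mt <- prep$data
  # same covariate construction as the generator: cell value at the village
  # centroid, z-scored across respondents
  vx <- v$x[match(mt$village_id, v$village_id)]
  vy <- v$y[match(mt$village_id, v$village_id)]
  mt$gp <- as.numeric(scale(cellValueAt(land@rasters$connect, vx, vy)))
  terms <- c("Protect_tiger", "Kill_tiger", "BadGood", "Spirit",
             "Descriptive", "ScenA", "TrustB", "gp")
  fit <- fitMultinomial(mt, terms)
  b <- truth@toleranceBeta
  for (eq in c("increase", "same")) for (tm in terms) {
    est <- fit@coefficients[eq, tm]; se <- fit@se[eq, tm]
    expect_lt(abs(est - b[eq, tm]), 3 * se,
              label = sprintf("%s:%s recovered", eq, tm))
  }
  # generated GP effect is negative and detected
  expect_lt(fit@coefficients["increase", "gp"], 0)
})
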
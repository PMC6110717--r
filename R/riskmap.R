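#' Extract buffer-mean covariates at points
#'
#' For each point, the arithmetic mean of every landscape raster over the
#' non-nodata cells whose centres fall within `radius` km (default 3.25 km,
#' the typical village extent, absorbing georeferencing error). Buffers with
#' zero valid cells yield NA and are flagged in the `incomplete` attribute.
#'
#' @param points data.frame or matrix with `x`, `y` columns (km).
#' @param landscape a [LandscapeBundle-class].
#' @param radius buffer radius, km.
#' @return data.frame of unscaled covariate means, one row per point.
#' @export
extractCovariates <- function(points, landscape, radius = 3.25) {
  x <- points[, "x"]; y <- points[, "y"]
  out <- as.data.frame(lapply(landscape@rasters, bufferMean, x = x, y = y,
                              radius = radius))
  attr(out, "incomplete") <- which(!complete.cases(out))
  attr(out, "radius") <- radius
  out
}

#' Variance inflation factors of a covariate table
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing column j on the others.
#'
#' @param table numeric data.frame.
#' @return named numeric vector.
#' @export
vifValues <- function(table) {
  m <- as.matrix(table)
  vapply(seq_len(ncol(m)), function(j) {
    fit <- lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((m[, j] - mean(m[, j]))^2)
    1 / max(1 - r2, 1e-12)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(table))
}

#' Screen covariates for collinearity
#'
#' Constant columns are dropped first (correlation undefined). Then the
#' column with the highest VIF is dropped iteratively until all VIF are below
#' `vifMax` and all pairwise |r| below `rMax`.
#'
#' @param table numeric data.frame of covariates.
#' @param rMax pairwise absolute-correlation ceiling.
#' @param vifMax variance-inflation ceiling.
#' @return list with `kept` (screened data.frame) and `report` (data.frame of
#'   drops with the offending statistic).
#' @export
screenCollinearity <- function(table, rMax = 0.7, vifMax = 3) {
  if (nrow(table) < 2) stop("screenCollinearity: need at least 2 rows")
  report <- data.frame(column = character(), reason = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  consts <- names(table)[vapply(table, function(v) sd(v) == 0, logical(1))]
  for (cn in consts) {
    warning(sprintf("screenCollinearity: dropping constant column '%s'", cn))
    report <- rbind(report, data.frame(column = cn, reason = "constant",
                                       value = NA_real_))
  }
  table <- table[, setdiff(names(table), consts), drop = FALSE]
  repeat {
    if (ncol(table) < 2) break
    vifs <- vifValues(table)
    cors <- cor(table)
    diag(cors) <- 0
    maxR <- max(abs(cors))
    if (all(vifs < vifMax) && maxR < rMax) break
    drop <- names(which.max(vifs))
    report <- rbind(report, data.frame(
      column = drop,
      reason = if (max(vifs) >= vifMax) "vif" else "correlation",
      value = if (max(vifs) >= vifMax) max(vifs) else maxR))
    table <- table[, setdiff(names(table), drop), drop = FALSE]
  }
  list(kept = table, report = report)
}

#' Draw pseudo-absence background points
#'
#' Uniform over the valid cells of the background mask (by default the
#' farmland extent: cells whose forest cover falls below `forestThreshold`),
#' uniform within each cell. Sampling is with replacement over cells, so `n`
#' may exceed the number of distinct cells (a warning notes the reuse).
#'
#' @param landscape a [LandscapeBundle-class].
#' @param n number of background points (default 10,000).
#' @param seed integer seed.
#' @param forestThreshold forest-cover cut defining farmland.
#' @param mask optional logical matrix overriding the farmland rule.
#' @return data.frame with `x`, `y` (km).
#' @export
makePseudoAbsences <- function(landscape, n = 10000, seed = 1L,
                               forestThreshold = 0.5, mask = NULL) {
  fc <- landscape@rasters[["for_cov"]]
  if (is.null(mask)) mask <- values(fc) < forestThreshold & values(fc) != fc@nodata
  cells <- which(mask)
  if (length(cells) == 0) stop("makePseudoAbsences: empty background mask")
  if (n > length(cells))
    warning("makePseudoAbsences: n exceeds distinct background cells; cells reused")
  set.seed(seed)
  pick <- sample(cells, n, replace = TRUE)
  d <- dim(values(fc))
  ri <- (pick - 1L) %% d[1] + 1L
  ci <- (pick - 1L) %/% d[1] + 1L
  cs <- cellSize(fc)
  data.frame(x = fc@origin[1] + (ci - 1L) * cs + runif(n) * cs,
             y = fc@origin[2] + (ri - 1L) * cs + runif(n) * cs)
}

#' Rank-statistic AUC
#'
#' The probability that a randomly chosen presence scores above a randomly
#' chosen absence, ties counting one half (equivalent to the Mann-Whitney
#' statistic and to the area under the ROC curve).
#'
#' @param scores numeric predicted scores.
#' @param labels 0/1 labels.
#' @return real in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("aucScore: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' Maximum over thresholds placed at the observed scores of
#' sensitivity + specificity - 1 (classification rule: score >= threshold).
#'
#' @inheritParams aucScore
#' @return real in \[-1, 1\].
#' @export
tssScore <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("tssScore: both classes must be present")
  thr <- unique(scores)
  best <- -1
  for (t in thr) {
    pos <- scores >= t
    sens <- sum(pos & labels == 1) / n1
    spec <- sum(!pos & labels == 0) / n0
    best <- max(best, sens + spec - 1)
  }
  best
}

memberSpecs <- function() {
  list(
    glm = list(
      fit = function(X, y) glm.fit(cbind(1, X), y, family = binomial()),
      pred = function(fit, X) {
        eta <- cbind(1, X) %*% fit$coefficients
        as.vector(1 / (1 + exp(-eta)))
      }),
    gam = list(
      fit = function(X, y) {
        df <- data.frame(y = y, X)
        terms <- vapply(colnames(X), function(cn) {
          if (length(unique(X[, cn])) > 10) sprintf("s(%s, k = 5)", cn) else cn
        }, "")
        mgcv::gam(as.formula(paste("y ~", paste(terms, collapse = " + "))),
                  family = binomial(), data = df)
      },
      pred = function(fit, X)
        as.vector(predict(fit, newdata = as.data.frame(X), type = "response"))),
    rf = list(
      fit = function(X, y)
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = 250),
      pred = function(fit, X) predict(fit, X, type = "prob")[, "1"]),
    svm = list(
      fit = function(X, y)
        e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE,
                   kernel = "radial"),
      pred = function(fit, X) {
        p <- predict(fit, X, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }),
    brt = list(
      fit = function(X, y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.2, nthread = 1),
          data = xgboost::xgb.DMatrix(as.matrix(X), label = y),
          nrounds = 60, verbose = 0),
      pred = function(fit, X)
        predict(fit, xgboost::xgb.DMatrix(as.matrix(X))))
  )
}

#' Repeated stratified split cross-validation AUC
#'
#' Random 70/30 calibration/evaluation splits, stratified by class,
#' replicated `reps` times; returns the mean held-out AUC. Splits that leave
#' a single class in either part are redrawn (bounded retries).
#'
#' @param member name of a member family (`glm`, `gam`, `rf`, `svm`, `brt`)
#'   or a list with `fit`/`pred` functions.
#' @param table numeric covariate data.frame (already scaled).
#' @param labels 0/1 vector.
#' @param trainFrac calibration fraction.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return mean AUC over replicates.
#' @export
crossvalAUC <- function(member, table, labels, trainFrac = 0.7, reps = 10,
                        seed = 1L) {
  spec <- if (is.character(member)) memberSpecs()[[member]] else member
  X <- as.matrix(table)
  set.seed(seed)
  aucs <- numeric(reps)
  for (r in seq_len(reps)) {
    for (try in 1:20) {
      idx1 <- which(labels == 1); idx0 <- which(labels == 0)
      tr <- c(sample(idx1, max(1, round(trainFrac * length(idx1)))),
              sample(idx0, max(1, round(trainFrac * length(idx0)))))
      te <- setdiff(seq_along(labels), tr)
      if (length(unique(labels[tr])) == 2 && length(unique(labels[te])) == 2)
        break
    }
    fit <- spec$fit(X[tr, , drop = FALSE], labels[tr])
    aucs[r] <- aucScore(spec$pred(fit, X[te, , drop = FALSE]), labels[te])
  }
  mean(aucs)
}

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d/%d members selected (cv AUC > screen)\n",
              length(object@members), length(object@cvAuc)))
  for (nm in names(object@cvAuc))
    cat(sprintf("  %-4s cvAUC %.3f%s\n", nm, object@cvAuc[[nm]],
                if (nm %in% names(object@weights))
                  sprintf("  TSS %.3f  weight %.3f",
                          object@tss[[nm]], object@weights[[nm]]) else
                  "  (not selected)"))
})

#' Fit the screened, TSS-weighted ensemble
#'
#' Every candidate member family is cross-validated ([crossvalAUC()]);
#' members with mean CV AUC above `aucMin` (default 0.70) are refitted on all
#' data and weighted by their full-data true skill statistic, renormalised to
#' sum to 1. The ensemble prediction is the TSS-weighted mean of member
#' probabilities. Covariates are z-scored here and the scaler frozen for
#' prediction.
#'
#' @param table unscaled covariate data.frame (already collinearity-screened).
#' @param labels 0/1 presence/pseudo-absence vector.
#' @param members character vector of member families to consider.
#' @param aucMin CV-AUC screening threshold.
#' @param reps,trainFrac cross-validation settings.
#' @param seed integer seed.
#' @return an [EnsembleModel-class].
#' @export
fitEnsemble <- function(table, labels, members = c("glm", "gam", "rf", "svm", "brt"),
                        aucMin = 0.70, reps = 10, trainFrac = 0.7, seed = 1L) {
  center <- vapply(table, mean, numeric(1))
  scale <- vapply(table, sd, numeric(1))
  scale[scale == 0] <- 1
  Xs <- as.data.frame(scale(table, center = center, scale = scale))
  specs <- memberSpecs()[members]

  cvAuc <- setNames(numeric(length(members)), members)
  for (i in seq_along(members))
    cvAuc[i] <- crossvalAUC(members[i], Xs, labels, trainFrac, reps,
                            seed = seed + i)
  selected <- names(cvAuc)[cvAuc > aucMin]
  if (length(selected) == 0)
    stop(sprintf("fitEnsemble: no member passed AUC > %.2f (cv AUC: %s)",
                 aucMin, paste(sprintf("%s=%.3f", names(cvAuc), cvAuc),
                               collapse = ", ")))
  fits <- list(); tss <- setNames(numeric(length(selected)), selected)
  X <- as.matrix(Xs)
  for (nm in selected) {
    set.seed(seed)
    fit <- specs[[nm]]$fit(X, labels)
    fits[[nm]] <- list(fit = fit, kind = nm)
    tss[nm] <- tssScore(specs[[nm]]$pred(fit, X), labels)
  }
  w <- pmax(tss, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  new("EnsembleModel", members = fits, cvAuc = cvAuc, tss = tss,
      weights = setNames(as.numeric(w), selected),
      scaler = list(center = center, scale = scale),
      columns = names(table))
}

#' Ensemble probability predictions for a covariate table
#'
#' @param ensemble an [EnsembleModel-class].
#' @param table unscaled covariate data.frame with the training columns.
#' @return numeric vector of TSS-weighted mean member probabilities.
#' @export
predictEnsemble <- function(ensemble, table) {
  missing <- setdiff(ensemble@columns, names(table))
  if (length(missing))
    stop(sprintf("predictEnsemble: missing covariate(s): %s",
                 paste(missing, collapse = ", ")))
  X <- as.matrix(scale(table[, ensemble@columns, drop = FALSE],
                       center = ensemble@scaler$center,
                       scale = ensemble@scaler$scale))
  specs <- memberSpecs()
  p <- rep(0, nrow(X))
  for (nm in names(ensemble@members))
    p <- p + ensemble@weights[[nm]] *
      as.numeric(specs[[nm]]$pred(ensemble@members[[nm]]$fit, X))
  p
}

#' Predict the encounter-risk surface over a landscape
#'
#' Per-cell covariates (cell values, not buffer means) are scaled with the
#' frozen training scaler and pushed through the ensemble; nodata propagates.
#'
#' @param ensemble an [EnsembleModel-class].
#' @param landscape a [LandscapeBundle-class] carrying the training covariates.
#' @return a [RasterGrid-class] of probabilities in \[0, 1\].
#' @export
predictSurface <- function(ensemble, landscape) {
  g <- landscape@rasters[[1]]
  missing <- setdiff(ensemble@columns, names(landscape@rasters))
  if (length(missing))
    stop(sprintf("predictSurface: missing covariate(s): %s",
                 paste(missing, collapse = ", ")))
  d <- dim(values(g))
  tab <- as.data.frame(lapply(landscape@rasters[ensemble@columns],
                              function(r) as.vector(values(r))))
  nodata <- values(g) == g@nodata
  p <- predictEnsemble(ensemble, tab)
  m <- matrix(p, d[1], d[2])
  m[nodata] <- g@nodata
  rasterGrid(m, g@origin, g@cellSize, g@nodata, g@crs)
}

#' Permutation variable importance of the ensemble
#'
#' For each covariate, the mean over permutations of the Pearson correlation
#' between the unpermuted ensemble predictions and the predictions after the
#' column is shuffled. Low correlations mean the permutation destroys the
#' prediction, i.e. high importance; inert covariates stay near 1. A constant
#' prediction vector is reported as 1 (carries no information).
#'
#' @param ensemble an [EnsembleModel-class].
#' @param table unscaled covariate data.frame.
#' @param perms permutations per covariate.
#' @param seed integer seed.
#' @return named numeric of mean Pearson r per covariate.
#' @export
variableImportance <- function(ensemble, table, perms = 10, seed = 1L) {
  base <- predictEnsemble(ensemble, table)
  set.seed(seed)
  out <- setNames(numeric(length(ensemble@columns)), ensemble@columns)
  for (cn in ensemble@columns) {
    rs <- numeric(perms)
    for (p in seq_len(perms)) {
      tp <- table
      tp[[cn]] <- sample(tp[[cn]])
      pred <- predictEnsemble(ensemble, tp)
      rs[p] <- if (sd(base) == 0 || sd(pred) == 0) 1 else cor(base, pred)
    }
    out[cn] <- mean(rs)
  }
  out
}
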
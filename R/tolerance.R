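TOLERANCE_LEVELS <- c("reduce_eradicate", "same", "increase")

#' Prepare survey responses for tolerance modelling
#'
#' Drops don't-know and missing tolerance rows (and rows with missing item
#' data), optionally reverses item orientation so that higher scores are
#' pro-conservation, builds the `Scenario` scale as the mean of the four
#' management-scenario items, z-scores age, and encodes the response as a
#' factor with reduce/eradicate as the reference level. Ethnicity is encoded
#' with the largest group as baseline.
#'
#' @param survey data.frame as produced by [genSurvey()] or [readSurvey()].
#' @param reverseItems item columns to reverse (`x -> 6 - x`) so a high score
#'   is pro-conservation; the shipped generator already orients all items
#'   that way, so the default reverses nothing.
#' @return list with `data` (model table) and `report` (exclusion counts).
#' @export
prepareResponses <- function(survey, reverseItems = character(0)) {
  n0 <- nrow(survey)
  dk <- sum(survey$tolerance == "dont_know")
  ms <- sum(survey$tolerance == "missing")
  keep <- survey$tolerance %in% TOLERANCE_LEVELS
  out <- survey[keep, , drop = FALSE]
  itemCols <- intersect(SURVEY_ITEMS, names(out))
  cc <- complete.cases(out[, itemCols, drop = FALSE])
  itemMissing <- sum(!cc)
  out <- out[cc, , drop = FALSE]
  if (nrow(out) == 0) stop("prepareResponses: all rows excluded")
  for (cn in reverseItems) out[[cn]] <- 6 - out[[cn]]
  scen <- intersect(c("ScenA", "ScenB", "ScenC", "ScenD"), names(out))
  if (length(scen)) out$Scenario <- rowMeans(out[, scen, drop = FALSE])
  if ("age" %in% names(out))
    out$age_z <- as.numeric(scale(out$age))
  if ("sex" %in% names(out)) out$sex <- factor(out$sex)
  if ("ethnicity" %in% names(out)) {
    tab <- sort(table(out$ethnicity), decreasing = TRUE)
    out$ethnicity <- factor(out$ethnicity, levels = names(tab))
  }
  out$tolerance <- factor(out$tolerance, levels = TOLERANCE_LEVELS)
  list(data = out,
       report = list(input = n0, dont_know = dk, missing = ms,
                     incomplete_items = itemMissing, retained = nrow(out)))
}

#' Psychometric scale diagnostics
#'
#' Cronbach's alpha from item/total variances, the Kaiser-Meyer-Olkin
#' sampling-adequacy measure (overall and per item) from correlation versus
#' partial-correlation magnitudes, and the loadings and explained variance of
#' the first principal factor of the item correlation matrix.
#'
#' @param items data.frame of numeric item columns (>= 2 items, >= 3 rows).
#' @return list with `cronbach_alpha`, `kmo_overall`, `kmo_per_item`,
#'   `first_factor_variance_pct`, `loadings`.
#' @export
scaleDiagnostics <- function(items) {
  if (ncol(items) < 2 || nrow(items) < 3)
    stop("scaleDiagnostics: need >= 2 items and >= 3 rows")
  zv <- names(items)[vapply(items, function(v) var(v) == 0, logical(1))]
  if (length(zv))
    stop(sprintf("scaleDiagnostics: zero-variance item(s): %s",
                 paste(zv, collapse = ", ")))
  k <- ncol(items)
  m <- as.matrix(items)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))

  R <- cor(m)
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Ri)) {
    warning("scaleDiagnostics: singular item correlation matrix; KMO undefined")
    kmoItem <- rep(NA_real_, k)
    kmo <- NA_real_
  } else {
    # anti-image (partial) correlations
    P <- -Ri / sqrt(outer(diag(Ri), diag(Ri)))
    diag(P) <- 0
    R0 <- R; diag(R0) <- 0
    kmoItem <- colSums(R0^2) / (colSums(R0^2) + colSums(P^2))
    kmo <- sum(R0^2) / (sum(R0^2) + sum(P^2))
  }

  e <- eigen(R, symmetric = TRUE)
  loadings <- sqrt(e$values[1]) * e$vectors[, 1]
  if (sum(loadings) < 0) loadings <- -loadings
  list(cronbach_alpha = alpha,
       kmo_overall = kmo,
       kmo_per_item = setNames(kmoItem, colnames(items)),
       first_factor_variance_pct = 100 * e$values[1] / k,
       loadings = setNames(loadings, colnames(items)))
}

#' Fitted multinomial logistic tolerance model
#'
#' @slot coefficients,se matrices with one row per non-reference outcome
#'   (`same`, `increase`) and one column per model term.
#' @slot logLik maximised log-likelihood.
#' @slot K number of estimated parameters.
#' @slot n rows used.
#' @slot terms right-hand-side terms of the model formula.
#' @slot model the underlying `nnet::multinom` fit.
#' @export
setClass("MultinomialFit",
  representation(coefficients = "matrix", se = "matrix", logLik = "numeric",
                 K = "integer", n = "integer", terms = "character",
                 model = "ANY"))

setMethod("show", "MultinomialFit", function(object) {
  cat(sprintf("MultinomialFit: %d obs, K = %d, logLik = %.3f\n  terms: %s\n",
              object@n, object@K, object@logLik,
              paste(object@terms, collapse = " + ")))
})

#' Fit a 3-category multinomial logistic regression
#'
#' Maximum likelihood via `nnet::multinom` with reference category
#' reduce/eradicate; standard errors from the inverse observed information.
#' Coefficients with implausibly large magnitude or SE trigger a
#' quasi-separation warning.
#'
#' @param data model table from [prepareResponses()] (the `tolerance` factor
#'   must contain all three analysis categories).
#' @param terms character vector of right-hand-side terms.
#' @return a [MultinomialFit-class].
#' @export
fitMultinomial <- function(data, terms) {
  if (nlevels(droplevels(data$tolerance)) != 3)
    stop("fitMultinomial: all three tolerance categories must be present")
  f <- as.formula(paste("tolerance ~",
                        if (length(terms)) paste(terms, collapse = " + ") else "1"))
  fit <- nnet::multinom(f, data = data, trace = FALSE, Hess = TRUE,
                        maxit = 500, MaxNWts = 5000)
  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 2,
                                     dimnames = list(fit$lev[-1], "(Intercept)"))
  H <- fit$Hessian
  se <- tryCatch({
    v <- diag(solve(H))
    matrix(sqrt(pmax(v, 0)), nrow = nrow(co), byrow = TRUE,
           dimnames = dimnames(co))
  }, error = function(e) {
    warning("fitMultinomial: singular information matrix; ridge-stabilised SEs")
    v <- diag(solve(H + diag(1e-6, nrow(H))))
    matrix(sqrt(pmax(v, 0)), nrow = nrow(co), byrow = TRUE,
           dimnames = dimnames(co))
  })
  if (any(abs(co) > 15) || any(se > 100))
    warning("fitMultinomial: possible (quasi-)separation; estimates unstable")
  ll <- as.numeric(logLik(fit))
  new("MultinomialFit", coefficients = co, se = se, logLik = ll,
      K = as.integer(attr(logLik(fit), "df")), n = as.integer(nrow(data)),
      terms = as.character(terms), model = fit)
}

#' Akaike information criterion, optionally small-sample corrected
#'
#' `-2 logLik + 2K`, plus `2K(K+1)/(n-K-1)` when `correction` is on.
#'
#' @param fit a [MultinomialFit-class], or a list/vector with `logLik`, `K`,
#'   `n` entries.
#' @param correction apply the small-sample correction (default on).
#' @return AICc (or plain AIC with `correction = FALSE`).
#' @export
aicc <- function(fit, correction = TRUE) {
  if (is(fit, "MultinomialFit")) {
    ll <- fit@logLik; K <- fit@K; n <- fit@n
  } else {
    ll <- fit[["logLik"]]; K <- fit[["K"]]; n <- fit[["n"]]
  }
  out <- -2 * ll + 2 * K
  if (correction) {
    if (is.null(n) || n <= K + 1)
      stop("aicc: correction requires n > K + 1")
    out <- out + 2 * K * (K + 1) / (n - K - 1)
  }
  out
}

#' Akaike weights and deltas from criterion values
#'
#' @param aiccValues named numeric of AICc values.
#' @return data.frame with `model`, `AICc`, `delta`, `weight`, ordered best
#'   first.
#' @export
aiccWeights <- function(aiccValues) {
  delta <- aiccValues - min(aiccValues)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = names(aiccValues), AICc = as.numeric(aiccValues),
                    delta = as.numeric(delta), weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  out[order(out$AICc), , drop = FALSE]
}

#' Evidence ratio between two models
#'
#' `exp((AICc_B - AICc_A) / 2)`: how many times better model A is supported
#' than model B.
#'
#' @param aiccA,aiccB criterion values of the two models.
#' @export
evidenceRatio <- function(aiccA, aiccB) exp((aiccB - aiccA) / 2)

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison (delta-AICc threshold", object@deltaThreshold, ")\n")
  print(format(object@table, digits = 6), row.names = FALSE)
  cat("confidence set:", paste(object@confidenceSet, collapse = ", "), "\n")
})

#' Compare multinomial models by AICc with averaging and importance
#'
#' Ranks fitted models by AICc, computes delta-AICc and Akaike weights,
#' model-averages coefficients over the confidence set (delta below
#' `deltaThreshold`, default 2) and reports per-term importance (sum of
#' full-set Akaike weights over models containing the term). Averaging is
#' conditional (subset) by default — each coefficient is averaged over the
#' confidence-set models that contain it, with weights renormalised — with
#' unconditional standard errors that fold in between-model spread; `full`
#' averaging shrinks absent coefficients towards zero instead.
#'
#' @param fits named list of [MultinomialFit-class] objects sharing data rows.
#' @param correction passed to [aicc()].
#' @param deltaThreshold delta-AICc cut for the confidence set.
#' @param average `"conditional"` (subset) or `"full"`.
#' @return a [ModelComparison-class].
#' @export
compareModels <- function(fits, correction = TRUE, deltaThreshold = 2,
                          average = c("conditional", "full")) {
  average <- match.arg(average)
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  ns <- vapply(fits, function(f) f@n, integer(1))
  if (length(unique(ns)) != 1)
    warning("compareModels: models fit to differing row counts")
  aiccs <- vapply(fits, aicc, numeric(1), correction = correction)
  tab <- aiccWeights(aiccs)
  tab$logLik <- vapply(fits[tab$model], function(f) f@logLik, numeric(1))
  tab$K <- vapply(fits[tab$model], function(f) f@K, integer(1))
  tab <- tab[, c("model", "K", "logLik", "AICc", "delta", "weight")]

  confSet <- tab$model[tab$delta < deltaThreshold]
  wAll <- setNames(tab$weight, tab$model)

  # collect coefficient entries per (equation, term-column)
  entries <- list()
  for (nm in names(fits)) {
    co <- fits[[nm]]@coefficients; se <- fits[[nm]]@se
    for (eq in rownames(co)) for (cn in colnames(co)) {
      key <- paste(eq, cn, sep = "\r")
      entries[[key]] <- rbind(entries[[key]],
                              data.frame(model = nm, est = co[eq, cn],
                                         se = se[eq, cn]))
    }
  }
  avg <- do.call(rbind, lapply(names(entries), function(key) {
    parts <- strsplit(key, "\r")[[1]]
    e <- entries[[key]]
    inSet <- e[e$model %in% confSet, , drop = FALSE]
    if (nrow(inSet) == 0) return(NULL)
    w <- wAll[inSet$model]
    if (average == "conditional") {
      w <- w / sum(w)
      beta <- sum(w * inSet$est)
      seU <- sqrt(sum(w * (inSet$se^2 + (inSet$est - beta)^2)))
    } else {
      wSet <- wAll[confSet] / sum(wAll[confSet])
      est <- setNames(rep(0, length(confSet)), confSet)
      ses <- setNames(rep(0, length(confSet)), confSet)
      est[inSet$model] <- inSet$est
      ses[inSet$model] <- inSet$se
      beta <- sum(wSet * est)
      seU <- sqrt(sum(wSet * (ses^2 + (est - beta)^2)))
    }
    data.frame(equation = parts[1], term = parts[2], estimate = beta,
               se = seU, stringsAsFactors = FALSE)
  }))

  allTerms <- unique(unlist(lapply(fits, function(f) f@terms)))
  importance <- vapply(allTerms, function(tm) {
    sum(wAll[vapply(names(fits), function(nm) tm %in% fits[[nm]]@terms,
                    logical(1))])
  }, numeric(1))

  new("ModelComparison", table = tab,
      averaged = if (is.null(avg)) data.frame() else avg,
      importance = importance, confidenceSet = confSet,
      deltaThreshold = deltaThreshold)
}

#' Attach village-level risk covariates to a survey model table
#'
#' Adds, per respondent, the z-scored geoprofile score (`gp`), the ensemble
#' encounter-risk probability (`prob_conf`), and/or the 3.25-km buffer means
#' of the landscape covariates, all evaluated at the respondent's village
#' centroid and z-scored across respondents. Respondents of one village share
#' identical values. Villages outside the rasters yield NA (flagged);
#' constant covariates are dropped with a warning.
#'
#' @param data model table from [prepareResponses()].
#' @param villages village table (`village_id`, `x`, `y`).
#' @param riskSurface optional [RasterGrid-class] of ensemble probabilities.
#' @param geoprofile optional [GeoProfile-class] or [RasterGrid-class].
#' @param landscape optional [LandscapeBundle-class].
#' @param radius buffer radius, km.
#' @return the extended model table.
#' @export
attachRiskCovariates <- function(data, villages, riskSurface = NULL,
                                 geoprofile = NULL, landscape = NULL,
                                 radius = 3.25) {
  idx <- match(data$village_id, villages$village_id)
  if (any(is.na(idx)))
    stop("attachRiskCovariates: respondents with unknown village_id")
  vx <- villages$x[idx]; vy <- villages$y[idx]
  addZ <- function(tab, nm, vals) {
    if (any(is.na(vals)))
      warning(sprintf("attachRiskCovariates: %d village(s) outside '%s' raster",
                      length(unique(tab$village_id[is.na(vals)])), nm))
    if (sd(vals, na.rm = TRUE) == 0 || all(is.na(vals))) {
      warning(sprintf("attachRiskCovariates: '%s' constant; dropped", nm))
      return(tab)
    }
    tab[[nm]] <- as.numeric(scale(vals))
    tab
  }
  if (!is.null(geoprofile)) {
    surf <- if (is(geoprofile, "GeoProfile")) geoprofile@surface else geoprofile
    data <- addZ(data, "gp", bufferMean(surf, vx, vy, radius))
  }
  if (!is.null(riskSurface))
    data <- addZ(data, "prob_conf", bufferMean(riskSurface, vx, vy, radius))
  if (!is.null(landscape))
    for (nm in names(landscape@rasters))
      data <- addZ(data, nm, bufferMean(landscape@rasters[[nm]], vx, vy, radius))
  data
}
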
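#' Read and validate an encounter CSV
#'
#' Expected header: `event_id,x,y,date,category,village_id` with ISO-8601
#' dates and categories from [ENCOUNTER_CATEGORIES]. Malformed rows are
#' collected into a validation error citing the offending rows, never
#' silently dropped.
#'
#' @param path CSV file path.
#' @return validated encounter data.frame.
#' @export
readEncounters <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "x", "y", "date", "category", "village_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("readEncounters: missing column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- character()
  badCat <- which(!df$category %in% ENCOUNTER_CATEGORIES)
  if (length(badCat))
    bad <- c(bad, sprintf("row %d: unknown category '%s'", badCat,
                          df$category[badCat]))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  badDate <- which(is.na(dates))
  if (length(badDate))
    bad <- c(bad, sprintf("row %d: unparseable date '%s'", badDate,
                          df$date[badDate]))
  badXY <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(badXY))
    bad <- c(bad, sprintf("row %d: non-finite coordinates", badXY))
  if (length(bad))
    stop(paste(c("readEncounters: validation failed:", bad), collapse = "\n  "))
  df$date <- dates
  df
}

#' @rdname readEncounters
#' @param records encounter data.frame.
#' @export
writeEncounters <- function(records, path) {
  out <- records
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a survey CSV
#'
#' Items must lie in 1..5 (or be empty for missing); the `tolerance` column
#' must use the documented vocabulary.
#'
#' @param path CSV file path.
#' @return validated survey data.frame.
#' @export
readSurvey <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("village_id", "tolerance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("readSurvey: missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- character()
  vocab <- c(TOLERANCE_LEVELS, "dont_know", "missing")
  badTol <- which(!df$tolerance %in% vocab)
  if (length(badTol))
    bad <- c(bad, sprintf("row %d: unknown tolerance '%s'", badTol,
                          df$tolerance[badTol]))
  for (cn in intersect(SURVEY_ITEMS, names(df))) {
    v <- df[[cn]]
    badItem <- which(!is.na(v) & (v < 1 | v > 5 | v != round(v)))
    if (length(badItem))
      bad <- c(bad, sprintf("row %d: item %s out of 1-5 range", badItem, cn))
  }
  if (length(bad))
    stop(paste(c("readSurvey: validation failed:", bad), collapse = "\n  "))
  df
}

#' @rdname readSurvey
#' @param survey survey data.frame.
#' @export
writeSurvey <- function(survey, path) {
  write.csv(survey, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write villages as GeoJSON points or CSV
#'
#' GeoJSON is a `FeatureCollection` of Point features with a `village_id`
#' property; CSV carries `village_id,x,y`.
#'
#' @param path file path (`.geojson`/`.json` or `.csv`).
#' @return data.frame with `village_id`, `x`, `y`.
#' @export
readVillages <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection"))
      stop("readVillages: not a GeoJSON FeatureCollection")
    df <- do.call(rbind, lapply(gj$features, function(f) {
      data.frame(village_id = f$properties$village_id,
                 x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 stringsAsFactors = FALSE)
    }))
  }
  need <- c("village_id", "x", "y")
  if (length(setdiff(need, names(df))))
    stop("readVillages: need village_id, x, y")
  if (any(!is.finite(df$x) | !is.finite(df$y)))
    stop("readVillages: non-finite coordinates")
  df
}

#' @rdname readVillages
#' @param villages village data.frame (`village_id`, `x`, `y`), optionally
#'   with extra columns written as feature properties.
#' @export
writeVillages <- function(villages, path) {
  if (grepl("\\.csv$", path)) {
    write.csv(villages, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  extra <- setdiff(names(villages), c("x", "y"))
  feats <- lapply(seq_len(nrow(villages)), function(i) {
    props <- as.list(villages[i, extra, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(villages$x[i], villages$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a pipeline run configuration as YAML
#'
#' A run configuration is a named list of stage parameters; every stochastic
#' stage carries an explicit seed. Round trips are identical.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @param config named list of stage parameters.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Stage defaults mirror the method's standard settings: 10,000
#' pseudo-absences, 70/30 splits replicated 10 times, AUC > 0.70 member
#' screening, 3.25 km buffers, 50,000 samples x 10 chains with burn-in
#' 10,000 for the geoprofile, delta-AICc < 2 selection, 6-month encounter
#' linkage and 1-month deduplication. The `scale` entries shrink simulation
#' sizes for quick runs without touching those analysis constants.
#'
#' @param seed master integer seed; stage seeds derive from it.
#' @return named list usable by [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(extent = c(0, 0, 400, 300), cell_size = 4,
                    n_events = 228, n_villages = 2300, n_surveyed = 75,
                    n_respondents = 2386, exact_categories = TRUE),
    geoprofile = list(samples = 50000, chains = 10, burnin = 10000,
                      thin = 10, sigma = "fit"),
    risk = list(n_absences = 10000, auc_min = 0.70, cv_reps = 10,
                train_frac = 0.7, buffer_km = 3.25,
                members = c("glm", "gam", "rf", "svm", "brt")),
    tolerance = list(delta_threshold = 2, correction = TRUE),
    prioritize = list(dedup_gap_days = 30, link_window_days = 180)
  )
}

#' Run the full socio-ecological pipeline on synthetic data
#'
#' Executes simulate -> geoprofile -> risk -> tolerance -> prioritize in
#' dependency order and returns a report: member CV AUCs, TSS weights,
#' permutation importance, fitted sigma-hat, hitscore Gini, the four-model
#' AICc comparison (social only; social + landscape covariates; social +
#' ensemble probability; social + geoprofile) with evidence ratios, and the
#' priority accounting. A stage failure marks the stage failed and skips its
#' dependents.
#'
#' @param config named list, see [defaultRunConfig()].
#' @param stages character vector of stages to run.
#' @param outdir optional directory to write artifacts (CSV/ASC/GeoJSON/JSON).
#' @param quiet suppress progress messages.
#' @return named list report.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        stages = c("simulate", "geoprofile", "risk",
                                   "tolerance", "prioritize"),
                        outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(config = config, stages = list())
  env <- new.env()
  seed <- config$seed

  runStage <- function(name, deps, fun) {
    if (!name %in% stages) return()
    for (d in deps) if (!isTRUE(report$stages[[d]]$ok)) {
      report$stages[[name]] <<- list(ok = FALSE, skipped = TRUE,
                                     reason = sprintf("dependency '%s' unavailable", d))
      return()
    }
    say("stage %s ...", name)
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    report$stages[[name]] <<- if (res$ok) list(ok = TRUE) else
      list(ok = FALSE, error = res$error)
    invisible(res$ok)
  }

  runStage("simulate", character(), function() {
    sc <- config$simulate
    env$truth <- truthParams()
    env$landscape <- genLandscape(sc$extent, sc$cell_size, seed = seed)
    env$villages <- genVillages(env$landscape, sc$n_villages, seed = seed + 1L)
    env$encounters <- genEncounters(env$landscape, env$truth, env$villages,
                                    sc$n_events, seed = seed + 2L,
                                    exactCategories = isTRUE(sc$exact_categories))
    env$surveyVillages <- selectSurveyVillages(env$villages, env$encounters,
                                               n = sc$n_surveyed,
                                               seed = seed + 3L)
    report$simulate <<- list(
      n_encounters = nrow(env$encounters),
      category_counts = as.list(table(env$encounters$category)))
    TRUE
  })

  runStage("geoprofile", "simulate", function() {
    gc <- config$geoprofile
    pts <- env$encounters[, c("x", "y")]
    cfg <- dpmConfig(samplesPerChain = gc$samples, burnIn = gc$burnin,
                     nChains = gc$chains, sigma = gc$sigma, thin = gc$thin,
                     seed = seed + 10L)
    ts <- twoStageSigma(pts, cfg)
    env$gpPosterior <- ts$posterior
    grid <- env$landscape@rasters[[1]]
    env$gpProfile <- profileSurface(ts$posterior, grid)
    sightings <- env$encounters[env$encounters$category == "sighting", c("x", "y")]
    others <- env$encounters[env$encounters$category != "sighting", c("x", "y")]
    val <- validateByCategory(sightings, others, grid, cfg)
    report$geoprofile <<- list(
      sigma_hat = ts$sigma_hat,
      cluster_count_mode = as.integer(names(which.max(table(
        ts$posterior@clusterCountDraws)))),
      rhat_k = ts$posterior@rhat,
      gini_sightings = val$gini,
      found_at = as.list(val$found_at))
    env$gpValidation <- val
    TRUE
  })

  runStage("risk", "simulate", function() {
    rc <- config$risk
    pres <- env$encounters[, c("x", "y")]
    abs <- makePseudoAbsences(env$landscape, rc$n_absences, seed = seed + 20L)
    pts <- rbind(pres, abs)
    labels <- c(rep(1L, nrow(pres)), rep(0L, nrow(abs)))
    feats <- extractCovariates(pts, env$landscape, rc$buffer_km)
    ok <- complete.cases(feats)
    scr <- screenCollinearity(feats[ok, , drop = FALSE])
    env$ensemble <- fitEnsemble(scr$kept, labels[ok], members = rc$members,
                                aucMin = rc$auc_min, reps = rc$cv_reps,
                                trainFrac = rc$train_frac, seed = seed + 21L)
    env$riskSurface <- predictSurface(env$ensemble, env$landscape)
    imp <- variableImportance(env$ensemble, scr$kept, seed = seed + 22L)
    w <- env$ensemble@weights
    selAuc <- env$ensemble@cvAuc[names(w)]
    report$risk <<- list(
      cv_auc = as.list(env$ensemble@cvAuc),
      selected = names(w),
      tss_weights = as.list(w),
      weighted_mean_auc = sum(w * selAuc),
      equal_mean_auc = mean(selAuc),
      dropped_covariates = scr$report,
      importance = as.list(imp))
    TRUE
  })

  runStage("tolerance", c("simulate", "geoprofile", "risk"), function() {
    tc <- config$tolerance
    survey <- genSurvey(env$surveyVillages, env$gpProfile@surface, env$truth,
                        config$simulate$n_respondents, seed = seed + 30L)
    env$survey <- survey
    prep <- prepareResponses(survey)
    env$prep <- prep
    mt <- attachRiskCovariates(prep$data, env$surveyVillages,
                               riskSurface = env$riskSurface,
                               geoprofile = env$gpProfile,
                               landscape = env$landscape)
    env$modelTable <- mt
    social <- c("Kill_tiger", "Protect_tiger", "Injunctive", "Descriptive",
                "BadGood", "DangHarm", "Spirit", "Health", "Env", "TrustB",
                "Scenario", "age_z", "sex", "ethnicity")
    landCovs <- intersect(names(env$landscape@rasters), names(mt))
    fits <- list(
      social_gp = fitMultinomial(mt, c(social, "gp")),
      social_prob = fitMultinomial(mt, c(social, "prob_conf")),
      social_landscape = fitMultinomial(mt, c(social, landCovs)),
      social_only = fitMultinomial(mt, social))
    cmp <- compareModels(fits, correction = isTRUE(tc$correction),
                         deltaThreshold = tc$delta_threshold)
    env$comparison <- cmp
    aiccs <- setNames(cmp@table$AICc, cmp@table$model)
    diag <- scaleDiagnostics(prep$data[, c("ScenA", "ScenB", "ScenC", "ScenD")])
    report$tolerance <<- list(
      exclusions = prep$report,
      scale = diag[c("cronbach_alpha", "kmo_overall",
                     "first_factor_variance_pct")],
      comparison = cmp@table,
      confidence_set = cmp@confidenceSet,
      evidence_ratio_gp_vs_social =
        evidenceRatio(aiccs[["social_gp"]], aiccs[["social_only"]]),
      evidence_ratio_gp_vs_prob =
        evidenceRatio(aiccs[["social_gp"]], aiccs[["social_prob"]]),
      gp_coefficients = env$comparison@averaged[
        env$comparison@averaged$term == "gp", , drop = FALSE])
    TRUE
  })

  runStage("prioritize", c("simulate", "risk", "tolerance"), function() {
    pc <- config$prioritize
    dedup <- deduplicateEncounters(env$encounters, pc$dedup_gap_days)
    links <- linkEncounters(dedup, pc$link_window_days)
    scores <- suppressWarnings(
      villageScores(env$surveyVillages, env$prep$data, env$riskSurface))
    pri <- classifyPriority(scores)
    env$priorities <- pri
    acc <- conflictAccounting(pri, env$encounters)
    report$prioritize <<- list(
      escalation_rate = links$escalation_rate,
      class_shares = as.list(prop.table(table(pri$priority))),
      accounting = acc)
    TRUE
  })

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(env$encounters))
      writeEncounters(env$encounters, file.path(outdir, "encounters.csv"))
    if (!is.null(env$surveyVillages))
      writeVillages(env$surveyVillages, file.path(outdir, "villages.geojson"))
    if (!is.null(env$survey))
      writeSurvey(env$survey, file.path(outdir, "survey.csv"))
    if (!is.null(env$riskSurface))
      writeAsciiGrid(env$riskSurface, file.path(outdir, "risk.asc"))
    if (!is.null(env$gpProfile))
      writeAsciiGrid(env$gpProfile@surface, file.path(outdir, "geoprofile.asc"))
    if (!is.null(env$priorities))
      writeVillages(env$priorities, file.path(outdir, "priorities.geojson"))
    rep2 <- report
    rep2$tolerance$comparison <- NULL
    jsonlite::write_json(rep2, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(env$comparison))
      write.csv(env$comparison@table, file.path(outdir, "model_comparison.csv"),
                row.names = FALSE)
  }
  report$state <- env
  report
}
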
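DAYS_PER_MONTH <- 30  # calendar-free gap arithmetic

#' Deduplicate encounter records within villages
#'
#' Within each village and category, records closer than `minGapDays` to an
#' already-retained earlier record are merged into it (the earliest is kept;
#' greedy scan in date order). Incidents at least the gap apart count as
#' separate events.
#'
#' @param records encounter data.frame with `village_id`, `category`, `date`.
#' @param minGapDays minimum gap, days (default one 30-day month).
#' @return the retained records.
#' @export
deduplicateEncounters <- function(records, minGapDays = DAYS_PER_MONTH) {
  if (any(is.na(records$date))) stop("deduplicateEncounters: undated record")
  records <- records[order(records$village_id, records$category, records$date), ]
  keep <- logical(nrow(records))
  grp <- paste(records$village_id, records$category, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    last <- -Inf
    for (i in idx) {
      d <- as.numeric(records$date[i])
      if (d - last >= minGapDays) {
        keep[i] <- TRUE
        last <- d
      }
    }
  }
  records[keep, , drop = FALSE]
}

#' Link encounters into escalation chains
#'
#' Within each village, time-ordered (deduplicated) events are chained while
#' successive gaps are below the linkage window (default six 30-day months).
#' The escalation rate is the fraction of chains containing more than one
#' event.
#'
#' @param records deduplicated encounter data.frame with `event_id`,
#'   `village_id`, `date`.
#' @param windowDays linkage window, days.
#' @return list with `chains` (data.frame `event_id`, `village_id`,
#'   `chain_id`, `escalated`) and `escalation_rate`.
#' @export
linkEncounters <- function(records, windowDays = 6 * DAYS_PER_MONTH) {
  records <- records[order(records$village_id, records$date), ]
  chainId <- integer(nrow(records))
  cid <- 0L
  for (v in unique(records$village_id)) {
    idx <- which(records$village_id == v)
    lastDate <- -Inf
    for (i in idx) {
      d <- as.numeric(records$date[i])
      if (d - lastDate >= windowDays) cid <- cid + 1L
      chainId[i] <- cid
      lastDate <- d
    }
  }
  len <- table(chainId)
  escalated <- as.integer(names(len)[len > 1])
  chains <- data.frame(event_id = records$event_id,
                       village_id = records$village_id,
                       chain_id = chainId,
                       escalated = chainId %in% escalated,
                       stringsAsFactors = FALSE)
  list(chains = chains,
       escalation_rate = mean(len > 1))
}

#' Score villages on risk and tolerance
#'
#' Risk is the buffer mean of the supplied surface (ensemble probability or
#' geoprofile) at the village centroid; tolerance is the mean coded
#' preference of the village's analysed respondents (1 = reduce/eradicate,
#' 2 = same, 3 = increase). Villages with no analysed respondents are
#' excluded with a warning.
#'
#' @param villages village table (`village_id`, `x`, `y`).
#' @param data analysed survey table ([prepareResponses()] output `data`).
#' @param surface a [RasterGrid-class] (or [GeoProfile-class]) of risk.
#' @param radius buffer radius, km.
#' @return data.frame `village_id`, `x`, `y`, `risk_score`, `tolerance_index`,
#'   `n_respondents`.
#' @export
villageScores <- function(villages, data, surface, radius = 3.25) {
  if (is(surface, "GeoProfile")) surface <- surface@surface
  if (!all(data$village_id %in% villages$village_id))
    stop("villageScores: respondents with unknown village_id")
  code <- match(as.character(data$tolerance), TOLERANCE_LEVELS)
  tol <- tapply(code, data$village_id, mean)
  nResp <- tapply(code, data$village_id, length)
  surveyed <- villages[villages$village_id %in% names(tol), , drop = FALSE]
  dropped <- setdiff(villages$village_id, surveyed$village_id)
  if (length(dropped))
    warning(sprintf("villageScores: %d village(s) without analysed respondents excluded",
                    length(dropped)))
  risk <- bufferMean(surface, surveyed$x, surveyed$y, radius)
  data.frame(village_id = surveyed$village_id, x = surveyed$x, y = surveyed$y,
             risk_score = risk,
             tolerance_index = as.numeric(tol[surveyed$village_id]),
             n_respondents = as.integer(nResp[surveyed$village_id]),
             stringsAsFactors = FALSE)
}

#' Median-split priority classification of villages
#'
#' High priority: above-median risk and below-median tolerance. Medium:
#' above-median risk, tolerance at or above its median. Low: risk at or
#' below its median. Medians are taken over the classified villages, so the
#' rule depends only on ranks — any strictly monotone transform of the risk
#' scores yields the same classes. All-identical risk degenerates to all-low
#' (tie rule, warned).
#'
#' @param scores table from [villageScores()].
#' @param rule split statistic: `"median"` (the default, rank-invariant) or
#'   `"mean"` ("above-average risk, below-average tolerance"); the source
#'   framework describes both and they differ on skewed risk distributions.
#' @return the table with a `priority` factor (`high`, `medium`, `low`).
#' @export
classifyPriority <- function(scores, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  if (nrow(scores) < 2) stop("classifyPriority: need >= 2 villages")
  split <- if (rule == "median") median else mean
  rm <- split(scores$risk_score, na.rm = TRUE)
  tm <- split(scores$tolerance_index, na.rm = TRUE)
  if (all(scores$risk_score == scores$risk_score[1]))
    warning("classifyPriority: all risk scores identical; all villages low")
  pri <- ifelse(scores$risk_score > rm,
                ifelse(scores$tolerance_index < tm, "high", "medium"),
                "low")
  scores$priority <- factor(pri, levels = c("high", "medium", "low"))
  scores
}

#' Account encounters by village priority class
#'
#' Per class: counts and shares of attacks (livestock + human) and removals.
#' The headline shares are those of the high-priority villages. Encounters in
#' unclassified villages are tallied in an `unassigned` bucket; shares are
#' reported both over study-village encounters and over all encounters.
#'
#' @param priorities table from [classifyPriority()].
#' @param encounters encounter data.frame with `village_id`, `category`.
#' @return list with `by_class` (data.frame), `high_attack_share_study`,
#'   `high_attack_share_all`, `high_removal_share_study`,
#'   `high_removal_share_all`, `totals`.
#' @export
conflictAccounting <- function(priorities, encounters) {
  cls <- as.character(priorities$priority[match(encounters$village_id,
                                                priorities$village_id)])
  cls[is.na(cls)] <- "unassigned"
  isAttack <- encounters$category %in% c("livestock_attack", "human_attack")
  isRemoval <- encounters$category == "removal"
  lev <- c("high", "medium", "low", "unassigned")
  byClass <- data.frame(
    class = lev,
    encounters = vapply(lev, function(l) sum(cls == l), numeric(1)),
    attacks = vapply(lev, function(l) sum(isAttack & cls == l), numeric(1)),
    removals = vapply(lev, function(l) sum(isRemoval & cls == l), numeric(1)),
    stringsAsFactors = FALSE)
  attStudy <- sum(byClass$attacks[byClass$class != "unassigned"])
  remStudy <- sum(byClass$removals[byClass$class != "unassigned"])
  share <- function(x, d) if (d == 0) 0 else x / d
  hi <- byClass[byClass$class == "high", ]
  list(by_class = byClass,
       high_attack_share_study = share(hi$attacks, attStudy),
       high_attack_share_all = share(hi$attacks, sum(isAttack)),
       high_removal_share_study = share(hi$removals, remStudy),
       high_removal_share_all = share(hi$removals, sum(isRemoval)),
       totals = list(encounters = nrow(encounters), attacks = sum(isAttack),
                     removals = sum(isRemoval)))
}
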
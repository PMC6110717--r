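#' Reference tolerance-model comparison table
#'
#' The published AICc comparison of the four tolerance-model structures for
#' the Kerinci Seblat human-tiger system: social predictors plus geographic
#' profile, social plus ensemble risk probability, social plus the raw
#' landscape covariates, and social predictors only. Shipped as a plain-CSV
#' reference so the delta-AICc / Akaike-weight / evidence-ratio arithmetic
#' can be exercised against known printed values without any download.
#'
#' @return data.frame with `model`, `AICc`, `logLik`, `K`.
#' @export
publishedModelTable <- function() {
  read.csv(system.file("extdata", "published_model_table.csv",
                       package = "conflictscope"), stringsAsFactors = FALSE)
}

#' Reference encounter-category composition
#'
#' The encounter-record composition of the Kerinci Seblat system over
#' 2000-2013: 106 sightings, 83 attacks on livestock, 12 attacks on people
#' and 27 removals of tigers (228 records in all). Used as the default
#' category mix of the synthetic generator and by the packaged encounter
#' fixture.
#'
#' @return named integer vector over [ENCOUNTER_CATEGORIES].
#' @export
referenceEncounterCounts <- function() {
  setNames(c(106L, 83L, 12L, 27L), ENCOUNTER_CATEGORIES)
}

#' Packaged synthetic encounter fixture
#'
#' A deterministic synthetic encounter table (seeded generator output, 228
#' records with the reference category composition) shipped as plain CSV.
#'
#' @return validated encounter data.frame.
#' @export
fixtureEncounters <- function() {
  readEncounters(system.file("extdata", "encounters_synthetic.csv",
                             package = "conflictscope"))
}
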
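# Shared small fixtures, built in code at test time.

smallLandscape <- function(seed = 5L) {
  genLandscape(extent = c(0, 0, 100, 80), cellSize = 2, seed = seed)
}

quickDpmConfig <- function(..., samplesPerChain = 1500, burnIn = 400,
                           nChains = 2, thin = 5, seed = 42) {
  dpmConfig(samplesPerChain = samplesPerChain, burnIn = burnIn,
            nChains = nChains, thin = thin, seed = seed, ...)
}

# two well-separated bivariate-normal clusters
twoClusterPoints <- function(n1 = 50, n2 = 50, sep = 100, sd = 5, seed = 1) {
  set.seed(seed)
  rbind(cbind(rnorm(n1, 0, sd), rnorm(n1, 0, sd)),
        cbind(rnorm(n2, sep, sd), rnorm(n2, 0, sd)))
}

# survey table with exact exclusion composition
surveyWithExclusions <- function(n = 2386, dk = 107, miss = 30, seed = 3) {
  set.seed(seed)
  tol <- c(rep("dont_know", dk), rep("missing", miss),
           sample(c("reduce_eradicate", "same", "increase"), n - dk - miss,
                  replace = TRUE))
  items <- as.data.frame(matrix(sample(1:5, n * length(SURVEY_ITEMS), TRUE),
                                n, dimnames = list(NULL, SURVEY_ITEMS)))
  cbind(data.frame(village_id = sprintf("V%03d", sample(75, n, TRUE)),
                   sex = sample(c("male", "female"), n, TRUE),
                   age = sample(18:80, n, TRUE),
                   ethnicity = sample(c("A", "B", "C"), n, TRUE),
                   stringsAsFactors = FALSE),
        items,
        data.frame(tolerance = sample(tol), stringsAsFactors = FALSE))
}

# brute-force pair-counting AUC oracle
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force threshold-enumeration TSS oracle
tssOracle <- function(scores, labels) {
  best <- -1
  for (t in unique(scores)) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    best <- max(best, sens + spec - 1)
  }
  best
}
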
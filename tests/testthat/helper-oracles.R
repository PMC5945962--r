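# Independent oracles and fixture builders, kept deliberately naive.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Literal staged-likelihood evaluation: per subject, sum over stages of the
# plain product of component densities (no log-space prefix trick). Only
# usable at toy sizes; underflows beyond that, which is the point of the
# log-sum-exp implementation it cross-checks.
naiveSeqLogLik <- function(logPE, logPNotE, order) {
  Z <- nrow(logPE); N <- ncol(logPE)
  pe <- exp(logPE); pne <- exp(logPNotE)
  total <- 0
  for (j in seq_len(N)) {
    sj <- 0
    for (k in 0:Z) {
      term <- 1
      for (pos in seq_len(Z)) {
        i <- order[pos]
        term <- term * if (pos <= k) pe[i, j] else pne[i, j]
      }
      sj <- sj + term / (Z + 1)
    }
    total <- total + log(sj)
  }
  total
}

# random likelihood table (entries are arbitrary finite log-densities)
randomLikTable <- function(Z, N, seed) {
  set.seed(seed)
  new("EventLikelihoodTable",
      logPE = matrix(rnorm(Z * N), Z, N),
      logPNotE = matrix(rnorm(Z * N), Z, N))
}

# likelihood table for subjects at known stages under unit-SD Gaussians
# with the abnormal mean `sep` control-SDs below zero
plantedLikTable <- function(stages, order, Z, sep = 4, seed = 1) {
  set.seed(seed)
  N <- length(stages)
  x <- matrix(0, Z, N)
  for (j in seq_len(N)) {
    abn <- rep(FALSE, Z)
    if (stages[j] > 0) abn[order[seq_len(stages[j])]] <- TRUE
    x[, j] <- rnorm(Z, mean = ifelse(abn, -sep, 0), sd = 1)
  }
  new("EventLikelihoodTable",
      logPE = dnorm(x, -sep, 1, log = TRUE),
      logPNotE = dnorm(x, 0, 1, log = TRUE))
}

# small fully-prepared synthetic cohort for pipeline-level tests
preparedCohort <- function(Z = 6L, n = c(60L, 40L, 60L), seed = 11L,
                           shift = -3, ...) {
  cfg <- cohortConfig(nBiomarkers = Z, nControl = n[1], nPremanifest = n[2],
                      nManifest = n[3], abnormalShift = rep(shift, Z),
                      seed = seed, ...)
  removeOutliers(correctCovariates(generateCohort(cfg)))
}

# constant-covariate settings: isolates the mixture structure
noCovariates <- function(Z) {
  list(age = rep(0, Z), tiv = rep(0, Z), site = matrix(0, 4, Z))
}
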
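test_that("configuration invariants are enforced", {
  expect_error(cohortConfig(nBiomarkers = 4, plantedSequence = c(1, 2, 2, 4)),
               "permutation")
  expect_error(cohortConfig(nBiomarkers = 4, controlSds = c(1, 1, 0, 1)),
               "positive")
  expect_error(generateCohort(
    cohortConfig(nBiomarkers = 4,
                 stageOccupancy = list(HC = rep(0.2, 5), preHD = rep(0.2, 5),
                                       HD = rep(0.3, 5)))),
    "probability")
})

test_that("identical config and seed reproduce the cohort bitwise", {
  cfg <- cohortConfig(nBiomarkers = 5, seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(assay(a, "volumes"), assay(b, "volumes"))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
})

test_that("zero abnormal shift leaves groups indistinguishable", {
  Z <- 5L
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 100, nPremanifest = 0,
                      nManifest = 100, abnormalShift = rep(0, Z),
                      covariateEffects = noCovariates(Z), seed = 5)
  coh <- generateCohort(cfg)
  v <- assay(coh, "volumes")
  hc <- coh$diagnosis == "HC"; hd <- coh$diagnosis == "HD"
  for (i in seq_len(Z)) {
    se <- sqrt(var(v[i, hc]) / sum(hc) + var(v[i, hd]) / sum(hd))
    expect_lt(abs(mean(v[i, hc]) - mean(v[i, hd])), 3 * se)
  }
})

test_that("abnormal values form exactly a prefix of the planted sequence", {
  Z <- 6L
  planted <- c(3L, 1L, 5L, 2L, 6L, 4L)
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 20, nPremanifest = 20,
                      nManifest = 20, plantedSequence = planted,
                      controlMeans = rep(0, Z), controlSds = rep(1e-3, Z),
                      abnormalShift = rep(-1000, Z),   # shift of -1 raw unit
                      abnormalSds = rep(1e-3, Z),
                      covariateEffects = noCovariates(Z), seed = 2)
  coh <- generateCohort(cfg)
  v <- assay(coh, "volumes")
  for (j in seq_len(ncol(coh))) {
    abn <- which(v[, j] < -0.5)
    k <- coh$true_stage[j]
    expect_setequal(abn, if (k > 0) planted[seq_len(k)] else integer(0))
  }
})

test_that("occupancy concentrated at stage Z makes every patient fully abnormal", {
  Z <- 4L
  occ <- c(rep(0, Z), 1)
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 10, nPremanifest = 10,
                      nManifest = 30,
                      stageOccupancy = list(HC = c(1, rep(0, Z)),
                                            preHD = occ, HD = occ),
                      seed = 3)
  coh <- generateCohort(cfg)
  expect_true(all(coh$true_stage[coh$diagnosis == "HD"] == Z))
  expect_true(all(coh$true_stage[coh$diagnosis == "HC"] == 0))
})

test_that("planted effect sizes match a direct Monte-Carlo oracle within 20%", {
  Z <- 4L
  occ <- c(rep(0, Z), 1)                       # patients fully abnormal
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 100, nPremanifest = 0,
                      nManifest = 100, abnormalShift = rep(-3, Z),
                      covariateEffects = noCovariates(Z),
                      stageOccupancy = list(HC = c(1, rep(0, Z)),
                                            preHD = occ, HD = occ),
                      seed = 8)
  coh <- generateCohort(cfg)
  v <- assay(coh, "volumes")
  hc <- coh$diagnosis == "HC"; hd <- coh$diagnosis == "HD"
  cohenD <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  # oracle: direct Monte-Carlo estimate of |d| at n = 100 per group
  set.seed(99)
  dOracle <- mean(replicate(200, abs(cohenD(rnorm(100), rnorm(100, -3)))))
  for (i in seq_len(Z)) {
    d <- abs(cohenD(v[i, hc], v[i, hd]))
    expect_lt(abs(d - dOracle) / dOracle, 0.2)
  }
})

test_that("control marginals are recovered at large n", {
  Z <- 4L
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 500, nPremanifest = 0,
                      nManifest = 0, covariateEffects = noCovariates(Z),
                      stageOccupancy = list(HC = c(1, rep(0, Z)),
                                            preHD = rep(1 / (Z + 1), Z + 1),
                                            HD = rep(1 / (Z + 1), Z + 1)),
                      seed = 21)
  v <- assay(generateCohort(cfg), "volumes")
  for (i in seq_len(Z)) {
    seMean <- cfg@controlSds[i] / sqrt(500)
    expect_lt(abs(mean(v[i, ]) - cfg@controlMeans[i]), 3 * seMean)
    seSd <- cfg@controlSds[i] / sqrt(2 * 499)
    expect_lt(abs(sd(v[i, ]) - cfg@controlSds[i]), 3 * seSd)
  }
})

test_that("longitudinal stages advance as configured and never regress", {
  Z <- 10L
  lowOcc <- c(rep(0.2, 5), rep(0, Z - 4))
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 30, nPremanifest = 50,
                      nManifest = 50,
                      stageOccupancy = list(HC = lowOcc, preHD = lowOcc,
                                            HD = lowOcc),
                      seed = 31)
  coh <- generateCohort(cfg)

  frozen <- generateLongitudinal(coh, nVisits = 3, stagesPerYear = 0)
  for (id in unique(frozen$subject_id)) {
    k <- frozen$true_stage[frozen$subject_id == id]
    expect_true(all(k == k[1]))
  }

  lon <- generateLongitudinal(coh, nVisits = 4, stagesPerYear = 1)
  wide <- split(lon$true_stage[order(lon$subject_id, lon$visit_months)],
                sort(lon$subject_id))
  expect_true(all(vapply(wide, function(k) all(diff(k) >= 0), TRUE)))
  adv <- vapply(wide, function(k) k[4] - k[1], 0)
  # oracle: capped-Poisson advance simulated directly at the same baselines
  set.seed(77)
  base <- vapply(wide, `[`, 0, 1)
  sim <- replicate(400, mean(pmin(Z, base + rpois(length(base), 3)) - base))
  expect_lt(abs(mean(adv) - mean(sim)), 2 * sd(adv) / sqrt(length(adv)))

  expect_error(generateLongitudinal(coh, nVisits = 3, stagesPerYear = -1),
               "non-negative")
})

test_that("subjects at the final stage stay there", {
  Z <- 4L
  occ <- c(rep(0, Z), 1)
  cfg <- cohortConfig(nBiomarkers = Z, nControl = 5, nPremanifest = 5,
                      nManifest = 20,
                      stageOccupancy = list(HC = occ, preHD = occ, HD = occ),
                      seed = 13)
  lon <- generateLongitudinal(generateCohort(cfg), nVisits = 4,
                              stagesPerYear = 2)
  expect_true(all(lon$true_stage == Z))
})

test_that("phenotypes are linear in stage with configurable noise", {
  coh <- generateCohort(cohortConfig(nBiomarkers = 5, nControl = 40,
                                     nPremanifest = 40, nManifest = 40,
                                     seed = 17))
  exact <- generatePhenotypes(coh, slopes = c(TMS = 1), intercepts = c(TMS = 0),
                              noiseSd = c(TMS = 0))
  expect_equal(exact$TMS, as.numeric(exact$true_stage), ignore_attr = TRUE)

  expect_error(generatePhenotypes(coh, slopes = c(bogus = 1),
                                  intercepts = c(TMS = 0),
                                  noiseSd = c(TMS = 1)),
               "phenotype")
})

test_that("a null phenotype slope is rarely declared significant", {
  coh <- generateCohort(cohortConfig(nBiomarkers = 5, nControl = 0,
                                     nPremanifest = 60, nManifest = 60,
                                     seed = 23))
  pvals <- vapply(1:100, function(r) {
    metadata(coh)$config@seed <- 1000L + r
    ph <- generatePhenotypes(coh, slopes = c(TMS = 0),
                             intercepts = c(TMS = 10), noiseSd = c(TMS = 5))
    summary(lm(ph$TMS ~ ph$true_stage))$coefficients[2, 4]
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("a planted motor-score slope is recovered within 20%", {
  cfg <- cohortConfig(nBiomarkers = 5, nControl = 0, nPremanifest = 120,
                      nManifest = 118, seed = 29)
  coh <- generatePhenotypes(generateCohort(cfg),
                            slopes = c(TMS = 0.98), intercepts = c(TMS = 2),
                            noiseSd = c(TMS = 5))
  slope <- coef(lm(coh$TMS ~ coh$true_stage))[2]
  # closed-form OLS sampling SD: noise / (sd(stage) * sqrt(n))
  seSlope <- 5 / (sd(coh$true_stage) * sqrt(ncol(coh)))
  expect_lt(abs(slope - 0.98), max(0.2 * 0.98, 3 * seSlope))
})
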
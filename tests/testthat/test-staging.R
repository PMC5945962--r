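unitFits <- function(bm, sep = 4) {
  new("EventModelFits", fits = data.frame(
    biomarker = bm, normal_mean = 0, normal_sd = 1,
    abnormal_mean = -sep, abnormal_sd = 1, weight = 0.5,
    converged = TRUE, n_iterations = 1L))
}

# cohort whose corrected values are set directly (one column per subject)
cohortFromMatrix <- function(x, diagnosis = rep("HD", ncol(x)),
                             visit = rep(0L, ncol(x)),
                             ids = sprintf("S%03d", seq_len(ncol(x)))) {
  cn <- paste0(ids, "_m", visit)
  colnames(x) <- cn
  if (is.null(rownames(x))) rownames(x) <- sprintf("bm%02d", seq_len(nrow(x)))
  cd <- S4Vectors::DataFrame(
    subject_id = ids, visit_months = visit, diagnosis = diagnosis,
    age = 50, site = factor("site1"), tiv = 1400, row.names = cn)
  coh <- new("HDCohort", SummarizedExperiment(assays = list(volumes = x),
                                              colData = cd))
  assay(coh, "corrected") <- x
  coh
}

test_that("extreme subjects land at the terminal stages", {
  Z <- 5L
  x <- cbind(rep(0, Z), rep(-4, Z))     # all-normal, all-abnormal
  coh <- cohortFromMatrix(x)
  st <- stageSubjects(coh, 1:Z, unitFits(rownames(coh)))
  expect_equal(stageTable(st)$stage, c(0L, Z))
})

test_that("planted stages are recovered within one stage almost always", {
  Z <- 8L
  set.seed(5)
  stages <- sample(0:Z, 300, replace = TRUE)
  ord <- sample(Z)
  x <- matrix(0, Z, length(stages))
  for (j in seq_along(stages)) {
    abn <- rep(FALSE, Z)
    if (stages[j] > 0) abn[ord[seq_len(stages[j])]] <- TRUE
    x[, j] <- rnorm(Z, ifelse(abn, -3, 0), 1)
  }
  coh <- cohortFromMatrix(x)
  st <- stageSubjects(coh, ord, unitFits(rownames(coh), sep = 3))
  expect_gte(mean(abs(stageTable(st)$stage - stages) <= 1), 0.95)
  expect_lte(mean(abs(stageTable(st)$stage - stages)), 1)
})

test_that("stage ties resolve to the smallest stage", {
  Z <- 3L
  x <- matrix(0, Z, 1)
  fits <- new("EventModelFits", fits = data.frame(
    biomarker = sprintf("bm%02d", 1:Z), normal_mean = 0, normal_sd = 1,
    abnormal_mean = 0, abnormal_sd = 1, weight = 0.5,
    converged = TRUE, n_iterations = 1L))     # identical components: all ties
  st <- stageSubjects(cohortFromMatrix(x), 1:Z, fits)
  expect_equal(stageTable(st)$stage, 0L)
})

test_that("pushing the frontier biomarker towards abnormal never lowers the stage", {
  Z <- 4L
  fits <- unitFits(sprintf("bm%02d", 1:Z))
  base <- c(-4, -4, 0, 0)                  # subject at stage 2
  for (v in seq(0, -4, by = -0.5)) {
    x <- matrix(c(base[1:2], v, 0), Z, 1)
    st <- stageSubjects(cohortFromMatrix(x), 1:Z, fits)
    if (v == 0) ref <- stageTable(st)$stage
    expect_gte(stageTable(st)$stage, ref)
    ref <- stageTable(st)$stage
  }
})

test_that("stage distributions are normalised and split into halves", {
  Z <- 4L
  x <- matrix(0, Z, 6)
  coh <- cohortFromMatrix(x, diagnosis = rep("HC", 6))
  st <- stageSubjects(coh, 1:Z, unitFits(rownames(coh)))
  d <- stageDistribution(st)
  expect_equal(unname(d$proportions["HC", ]), c(1, 0, 0, 0, 0))
  expect_equal(d$halves$lower, 1)

  # premanifest-A analogue: early-stage subjects sit in the lower half
  set.seed(6)
  Z <- 10L
  stages <- sample(0:3, 80, replace = TRUE)
  xx <- matrix(0, Z, 80)
  for (j in seq_len(80))
    if (stages[j] > 0) xx[seq_len(stages[j]), j] <- -4
  cohA <- cohortFromMatrix(xx, diagnosis = rep("preHD", 80))
  stA <- stageSubjects(cohA, 1:Z, unitFits(rownames(cohA)))
  dA <- stageDistribution(stA)
  expect_gte(dA$halves$lower[dA$halves$group == "preHD"], 0.7)
  expect_equal(rowSums(dA$proportions), 1, ignore_attr = TRUE)
})

test_that("longitudinal consistency summarises baseline-to-final changes", {
  tab <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 2),
    visit_months = rep(c(0L, 36L), 3),
    diagnosis = "HD",
    stage = c(2L, 2L, 3L, 6L, 5L, 4L))
  ll <- matrix(0, 6, 7); ll[cbind(1:6, tab$stage + 1)] <- 1
  st <- new("StageAssignments", table = tab, logLikByStage = ll,
            sequence = 1:6)
  res <- longitudinalConsistency(st)
  expect_equal(res$fractionNonRegressing, 2 / 3)
  expect_equal(res$meanProgression, 3)
  expect_equal(res$meanRegression, 1)

  # identical stages: nobody regresses, nobody progresses
  tab2 <- tab; tab2$stage <- rep(c(3L, 3L), 3)
  ll2 <- matrix(0, 6, 7); ll2[cbind(1:6, tab2$stage + 1)] <- 1
  res2 <- longitudinalConsistency(
    new("StageAssignments", table = tab2, logLikByStage = ll2, sequence = 1:6))
  expect_equal(res2$fractionNonRegressing, 1)
  expect_equal(res2$meanProgression, 0)
  expect_equal(res2$meanRegression, 0)
})

test_that("conversion prediction sweeps all thresholds and maximises balanced accuracy", {
  mkAssign <- function(stages, Z = 18L) {
    n <- length(stages)
    ll <- matrix(0, n, Z + 1); ll[cbind(seq_len(n), stages + 1)] <- 1
    new("StageAssignments",
        table = data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                           visit_months = 0L, diagnosis = "preHD",
                           stage = stages),
        logLikByStage = ll, sequence = seq_len(Z))
  }
  # perfectly separated stages
  st <- mkAssign(c(rep(2L, 10), rep(12L, 5)))
  conv <- c(rep(FALSE, 10), rep(TRUE, 5))
  res <- predictConversion(st, conv)
  expect_equal(res$balancedAccuracy, 1)
  expect_equal(nrow(res$sweep), 19)
  expect_equal(res$balancedAccuracy, max(res$sweep$balanced_accuracy))
  expect_equal(res$balancedAccuracy,
               (res$sensitivity + res$specificity) / 2)

  # stages unrelated to conversion stay near chance
  set.seed(7)
  stages <- sample(0:18, 500, replace = TRUE)
  conv2 <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  res2 <- predictConversion(mkAssign(stages), conv2)
  # oracle: permutation null of the maximal balanced accuracy
  nullBA <- replicate(100, predictConversion(
    mkAssign(stages), sample(conv2))$balancedAccuracy)
  expect_lte(res2$balancedAccuracy, quantile(nullBA, 0.99) + 0.02)
  expect_lt(res2$balancedAccuracy, 0.6)

  expect_error(predictConversion(st, rep(TRUE, 15)), "non-converter")
})

test_that("phenotype regression recovers exact and null relationships", {
  Z <- 6L
  set.seed(8)
  stages <- sample(0:Z, 120, replace = TRUE)
  x <- matrix(0, Z, 120)
  for (j in seq_len(120))
    if (stages[j] > 0) x[seq_len(stages[j]), j] <- -4
  coh <- cohortFromMatrix(x, diagnosis = rep(c("preHD", "HD"), 60))
  st <- stageSubjects(coh, 1:Z, unitFits(rownames(coh)))
  expect_equal(stageTable(st)$stage, stages)   # noise-free staging is exact

  colData(coh)$TMS <- stages                   # phenotype identical to stage
  reg <- phenotypeRegression(st, coh)
  expect_equal(reg$slope, 1, tolerance = 1e-10)
  expect_lt(reg$p, 1e-20)

  # shuffled phenotype: type-I error is controlled
  hits <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    colData(coh)$TMS <- sample(stages)
    phenotypeRegression(st, coh)$p < 0.05
  }, TRUE)
  expect_gte(mean(!hits), 0.9)
})
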
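#' Stage subjects along a characteristic sequence
#'
#' For each subject-visit, evaluates the staged likelihood for every stage
#' k = 0..Z — abnormal-component densities for the first k events of the
#' sequence, normal-component densities for the rest, uniform stage prior —
#' and assigns the maximising stage. Ties resolve to the smallest k
#' (conservative staging).
#'
#' @param cohort an [HDCohort-class] with a `"corrected"` assay (staging
#'   uses the same covariate-corrected values the model was fitted on).
#' @param sequence integer permutation: the characteristic event ordering.
#' @param fits an [EventModelFits-class].
#' @return a [StageAssignments-class].
#' @export
stageSubjects <- function(cohort, sequence, fits) {
  stopifnot(is(cohort, "HDCohort"))
  table <- eventLikelihoods(cohort, fits)
  Z <- nrow(table@logPE)
  sequence <- checkSequence(sequence, Z)
  ll <- cppStageLogLik(table@logPE, table@logPNotE, sequence)
  colnames(ll) <- as.character(0:Z)
  rownames(ll) <- colnames(cohort)
  stage <- max.col(ll, ties.method = "first") - 1L
  cd <- colData(cohort)
  tab <- data.frame(subject_id = cd$subject_id,
                    visit_months = cd$visit_months,
                    diagnosis = cd$diagnosis,
                    stage = stage, row.names = NULL)
  if ("true_stage" %in% colnames(cd)) tab$true_stage <- cd$true_stage
  new("StageAssignments", table = tab, logLikByStage = ll,
      sequence = sequence)
}

#' Per-group stage occupancy
#'
#' Fraction of subjects at each stage for each cohort label, plus the split
#' between the lower half of the stages (0..floor(Z/2)) and the upper half.
#'
#' @param assignments a [StageAssignments-class] (baseline visits are used).
#' @param groups optional subject -> label vector overriding the stored
#'   diagnosis (e.g. a premanifest A/B subdivision); must cover every
#'   subject.
#' @param lowerHalfMax largest stage counted as "lower half"; default
#'   floor(Z/2).
#' @return list: `proportions` (groups x stages matrix, rows sum to 1) and
#'   `halves` (data.frame of lower/upper fractions per group).
#' @export
stageDistribution <- function(assignments, groups = NULL,
                              lowerHalfMax = NULL) {
  stopifnot(is(assignments, "StageAssignments"))
  tab <- assignments@table
  tab <- tab[tab$visit_months == min(tab$visit_months), ]
  Z <- length(assignments@sequence)
  if (is.null(groups)) {
    groups <- tab$diagnosis
  } else {
    if (is.null(names(groups))) {
      if (length(groups) != nrow(tab))
        stop("`groups` must label every subject")
    } else {
      miss <- setdiff(tab$subject_id, names(groups))
      if (length(miss))
        stop("`groups` missing label(s) for: ",
             paste(head(miss, 5), collapse = ", "))
      groups <- groups[tab$subject_id]
    }
  }
  if (is.null(lowerHalfMax)) lowerHalfMax <- floor(Z / 2)
  gl <- unique(groups)
  prop <- t(vapply(gl, function(g) {
    k <- tab$stage[groups == g]
    tabulate(k + 1L, nbins = Z + 1L) / length(k)
  }, numeric(Z + 1L)))
  dimnames(prop) <- list(gl, as.character(0:Z))
  halves <- data.frame(
    group = gl,
    lower = rowSums(prop[, as.character(0:lowerHalfMax), drop = FALSE]),
    upper = rowSums(prop[, as.character((lowerHalfMax + 1):Z), drop = FALSE]),
    row.names = NULL)
  list(proportions = prop, halves = halves)
}

#' Bootstrap cross-validation of the event sequence
#'
#' Resamples subjects with replacement (stratified by diagnosis, so every
#' resample contains both distribution-fitting groups), refits the mixture
#' models, re-estimates the maximum-likelihood sequence, builds the
#' per-resample positional variance diagram, and returns the element-wise
#' mean. Rows are displayed in the order of a reference sequence estimated
#' once on the full data (or supplied via `referenceSequence`).
#'
#' @param cohort a prepared [HDCohort-class] (corrected assay present).
#' @param nBootstrap number of resamples (default 100).
#' @param seed integer seed.
#' @param nRestarts greedy restarts per resample (default 5).
#' @param referenceSequence optional permutation fixing the display order.
#' @param nMCMC if > 0, the per-resample PVD is built from this many MCMC
#'   samples; default 0 uses the resample's maximum-likelihood sequence (a
#'   permutation matrix).
#' @param nRefine length of the short MCMC refinement chain used to locate
#'   each resample's maximum-likelihood sequence (see [estimateSequence()]).
#' @return a [PositionalVarianceDiagram-class].
#' @export
bootstrapPVD <- function(cohort, nBootstrap = 100L, seed = 1L,
                         nRestarts = 5L, referenceSequence = NULL,
                         nMCMC = 0L, nRefine = 2000L) {
  stopifnot(is(cohort, "HDCohort"))
  if (nBootstrap < 2) stop("`nBootstrap` must be at least 2")
  cd <- colData(cohort)
  baseline <- which(cd$visit_months == min(cd$visit_months))
  base <- cohort[, baseline]
  Z <- nrow(base)
  if (is.null(referenceSequence)) {
    fits <- fitEventModels(base)
    referenceSequence <- estimateSequence(eventLikelihoods(base, fits),
                                          nRestarts = nRestarts,
                                          nSamples = max(nRefine, 1000L),
                                          nBurnIn = max(nRefine %/% 10L, 100L),
                                          seed = seed)$sequence
  }
  referenceSequence <- checkSequence(referenceSequence, Z)
  set.seed(streamSeed(seed, "bootstrap"))
  acc <- matrix(0, Z, Z)
  dx <- colData(base)$diagnosis
  idxByGroup <- split(seq_len(ncol(base)), dx)
  for (b in seq_len(nBootstrap)) {
    repeat {
      take <- unlist(lapply(idxByGroup, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      if (any(dx[take] == "HC") && any(dx[take] == "HD")) break
      message("resample ", b, " lacked a fitting group; redrawn")
    }
    boot <- base[, take]
    # resampled subjects get unique ids so downstream grouping stays valid
    colData(boot)$subject_id <- sprintf("%s.b%d", colData(boot)$subject_id,
                                        seq_along(take))
    fitsB <- fitEventModels(boot)
    tabB <- eventLikelihoods(boot, fitsB)
    est <- estimateSequence(tabB, nRestarts = nRestarts,
                            nSamples = max(nRefine, nMCMC, 100L),
                            nBurnIn = max(nRefine %/% 10L, 100L),
                            seed = streamSeed(seed, "bootstrap") + b)
    pm <- matrix(0, Z, Z)
    if (nMCMC > 0) {
      s <- mcmcSamples(est$trace)
      s <- s[seq(nrow(s) - nMCMC + 1L, nrow(s)), , drop = FALSE]
      for (p in seq_len(Z))
        pm[, p] <- tabulate(s[, p], nbins = Z) / nrow(s)
    } else {
      pm[cbind(est$sequence, seq_len(Z))] <- 1
    }
    acc <- acc + pm
  }
  m <- acc[referenceSequence, , drop = FALSE] / nBootstrap
  rn <- rownames(base)[referenceSequence]
  if (is.null(rn)) rn <- paste0("event", referenceSequence)
  dimnames(m) <- list(rn, paste0("pos", seq_len(Z)))
  new("PositionalVarianceDiagram", matrix = m)
}

#' Longitudinal consistency of staging
#'
#' Compares each subject's final-visit stage to baseline: the fraction of
#' subjects staged at or above their baseline stage at the final follow-up,
#' the mean stage advance among progressors, and the mean decline among
#' regressors, plus per-visit baseline/follow-up stage pairs.
#'
#' @param assignments a [StageAssignments-class] covering multiple visits
#'   (e.g. from staging a longitudinal cohort).
#' @param groups diagnosis labels to include (default the patient groups,
#'   `c("preHD", "HD")`).
#' @return list: `fractionNonRegressing`, `meanProgression`,
#'   `meanRegression`, `n`, and `perVisit` (data.frame with subject_id,
#'   visit_months, baseline_stage, stage).
#' @export
longitudinalConsistency <- function(assignments,
                                    groups = c("preHD", "HD")) {
  stopifnot(is(assignments, "StageAssignments"))
  tab <- assignments@table
  tab <- tab[tab$diagnosis %in% groups, ]
  base <- tab[tab$visit_months == min(tab$visit_months),
              c("subject_id", "stage")]
  names(base)[2] <- "baseline_stage"
  merged <- merge(tab, base, by = "subject_id")
  followed <- merged[merged$visit_months > min(merged$visit_months), ]
  if (nrow(followed) == 0)
    stop("no matched follow-up visits for the requested groups")
  finalVisit <- stats::aggregate(visit_months ~ subject_id, followed, max)
  final <- merge(followed, finalVisit, by = c("subject_id", "visit_months"))
  delta <- final$stage - final$baseline_stage
  list(fractionNonRegressing = mean(delta >= 0),
       meanProgression = if (any(delta > 0)) mean(delta[delta > 0]) else 0,
       meanRegression = if (any(delta < 0)) mean(-delta[delta < 0]) else 0,
       meanChange = mean(delta),
       n = nrow(final),
       perVisit = merged[, c("subject_id", "visit_months",
                             "baseline_stage", "stage")])
}

#' Conversion prediction from baseline stage
#'
#' Sweeps every stage threshold t in 0..Z, predicting conversion for
#' subjects with baseline stage strictly greater than t, and returns the
#' threshold maximising balanced accuracy — the average of sensitivity and
#' specificity (smallest t on ties).
#'
#' @param assignments a [StageAssignments-class] (baseline visits used).
#' @param converted named logical vector (by subject id) or logical vector
#'   aligned with the baseline rows: whether the subject truly converted.
#' @return list: `thresholdStage`, `sensitivity`, `specificity`,
#'   `balancedAccuracy`, and `sweep` (one row per threshold).
#' @export
predictConversion <- function(assignments, converted) {
  stopifnot(is(assignments, "StageAssignments"))
  tab <- assignments@table
  tab <- tab[tab$visit_months == min(tab$visit_months), ]
  if (!is.null(names(converted))) {
    miss <- setdiff(tab$subject_id, names(converted))
    if (length(miss))
      stop("conversion label missing for subject(s): ",
           paste(head(miss, 5), collapse = ", "))
    converted <- converted[tab$subject_id]
  } else if (length(converted) != nrow(tab)) {
    stop("`converted` must label every baseline subject")
  }
  converted <- as.logical(converted)
  if (all(converted) || !any(converted))
    stop("need at least one converter and one non-converter")
  Z <- length(assignments@sequence)
  sweep <- do.call(rbind, lapply(0:Z, function(t) {
    pred <- tab$stage > t
    sens <- mean(pred[converted])
    spec <- mean(!pred[!converted])
    data.frame(threshold = t, sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2)
  }))
  bestRow <- which.max(sweep$balanced_accuracy)   # which.max takes first tie
  list(thresholdStage = sweep$threshold[bestRow],
       sensitivity = sweep$sensitivity[bestRow],
       specificity = sweep$specificity[bestRow],
       balancedAccuracy = sweep$balanced_accuracy[bestRow],
       sweep = sweep)
}

#' Phenotype-on-stage regression
#'
#' Ordinary least squares regression of each phenotype score on the
#' assigned stage across the supplied subjects, with two-sided slope
#' p-values. The intended use is validation: motor and genetic burden
#' scores should increase with stage, cognitive scores decrease.
#'
#' @param assignments a [StageAssignments-class].
#' @param cohort the [HDCohort-class] carrying phenotype colData columns.
#' @param phenotypes character vector of colData columns to regress;
#'   default all of TMS, SDMT, Stroop, CAP that are present.
#' @param groups diagnosis labels to include (default patients,
#'   `c("preHD", "HD")`, matching the combined-cohort analysis).
#' @return data.frame: phenotype, slope, intercept, se, t, p, n.
#' @export
phenotypeRegression <- function(assignments, cohort, phenotypes = NULL,
                                groups = c("preHD", "HD")) {
  stopifnot(is(assignments, "StageAssignments"), is(cohort, "HDCohort"))
  cd <- colData(cohort)
  if (is.null(phenotypes))
    phenotypes <- intersect(c("TMS", "SDMT", "Stroop", "CAP"), colnames(cd))
  if (!length(phenotypes)) stop("no phenotype columns found")
  tab <- assignments@table
  key <- paste(cd$subject_id, cd$visit_months)
  idx <- match(paste(tab$subject_id, tab$visit_months), key)
  keep <- !is.na(idx) & tab$diagnosis %in% groups
  if (sum(keep) < 3) stop("need at least 3 matched observations")
  stage <- tab$stage[keep]
  if (sd(stage) == 0) stop("assigned stages have zero variance")
  rows <- lapply(phenotypes, function(ph) {
    y <- cd[[ph]][idx[keep]]
    ok <- !is.na(y)
    fit <- summary(lm(y[ok] ~ stage[ok]))
    co <- fit$coefficients
    data.frame(phenotype = ph, slope = co[2, 1], intercept = co[1, 1],
               se = co[2, 2], t = co[2, 3], p = co[2, 4], n = sum(ok))
  })
  do.call(rbind, rows)
}
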
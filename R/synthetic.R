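#' Configuration for a synthetic staged-progression cohort
#'
#' Collects every generative assumption behind the synthetic cohorts: a
#' planted event ordering, per-biomarker normal (control) and abnormal
#' component parameters, linear covariate confounding, and per-group stage
#' occupancy. A subject at true stage \eqn{k} draws the biomarkers at the
#' first \eqn{k} positions of the planted sequence from their abnormal
#' component and the rest from the normal component — exactly the monotonic,
#' homogeneous progression the event-based model assumes.
#'
#' @slot nControl,nPremanifest,nManifest group sizes; defaults 119/120/118,
#'   the baseline cohort structure the package's analyses are scaled to.
#' @slot nBiomarkers number of events Z (default 18).
#' @slot plantedSequence integer permutation of 1..Z; position 1 = earliest.
#' @slot biomarkerNames labels, length Z.
#' @slot controlMeans,controlSds raw-scale control component parameters
#'   (volume-like units).
#' @slot abnormalShift signed abnormal-component mean shift per biomarker,
#'   in control-SD units (negative = volume loss; positive shifts model
#'   fluid spaces that grow, e.g. CSF and ventricles).
#' @slot abnormalSds abnormal component SD per biomarker (raw units).
#' @slot covariateEffects list with `age` and `tiv` per-biomarker slopes
#'   (raw units per year / per mL) and `site`, a 4 x Z matrix of additive
#'   site offsets (4 acquisition sites).
#' @slot stageOccupancy list of per-group probability vectors over stages
#'   0..Z. Defaults: controls concentrated at stage 0 with a geometric
#'   tail; premanifest and manifest subjects uniform over 0..Z.
#' @slot seed integer master seed; every generator operation derives its
#'   own sub-stream from it.
#' @export
setClass("CohortConfig",
  representation(nControl = "integer", nPremanifest = "integer",
                 nManifest = "integer", nBiomarkers = "integer",
                 plantedSequence = "integer", biomarkerNames = "character",
                 controlMeans = "numeric", controlSds = "numeric",
                 abnormalShift = "numeric", abnormalSds = "numeric",
                 covariateEffects = "list", stageOccupancy = "list",
                 seed = "integer"))

.validCohortConfig <- function(object) {
  msg <- NULL
  Z <- object@nBiomarkers
  if (any(c(object@nControl, object@nPremanifest, object@nManifest) < 0))
    msg <- c(msg, "group sizes must be non-negative")
  if (Z < 2) msg <- c(msg, "at least 2 biomarkers required")
  if (!isPermutation(object@plantedSequence, Z))
    msg <- c(msg, "plantedSequence must be a permutation of 1..Z")
  perBm <- c(length(object@biomarkerNames), length(object@controlMeans),
             length(object@controlSds), length(object@abnormalShift),
             length(object@abnormalSds))
  if (any(perBm != Z))
    msg <- c(msg, "per-biomarker fields must have length Z")
  if (any(object@controlSds <= 0) || any(object@abnormalSds <= 0))
    msg <- c(msg, "component SDs must be positive")
  ce <- object@covariateEffects
  if (!all(c("age", "tiv", "site") %in% names(ce)))
    msg <- c(msg, "covariateEffects must contain age, tiv and site")
  else if (length(ce$age) != Z || length(ce$tiv) != Z ||
           !is.matrix(ce$site) || ncol(ce$site) != Z)
    msg <- c(msg, "covariateEffects components must span all biomarkers")
  so <- object@stageOccupancy
  if (!all(c("HC", "preHD", "HD") %in% names(so)))
    msg <- c(msg, "stageOccupancy must have HC, preHD and HD entries")
  else {
    for (g in c("HC", "preHD", "HD")) {
      p <- so[[g]]
      if (length(p) != Z + 1 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        msg <- c(msg, paste0("stageOccupancy$", g,
                             " must be a probability vector over stages 0..Z"))
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("CohortConfig", .validCohortConfig)

#' Build a cohort configuration
#'
#' Constructor for [CohortConfig-class] with defaults matching the study
#' structure the package emulates: three diagnostic groups of 119/120/118
#' subjects, Z = 18 regional-volume events, 3-control-SD abnormal shifts
#' (volume loss), four acquisition sites with additive offsets, and modest
#' age/TIV confounding that the preparation step must remove.
#'
#' @param nControl,nPremanifest,nManifest group sizes.
#' @param nBiomarkers number of events Z.
#' @param plantedSequence permutation of `1:nBiomarkers`; default identity.
#' @param biomarkerNames labels (default `bm01`..).
#' @param controlMeans,controlSds control component parameters; defaults
#'   span a range of region sizes (volume-like units) with 10% SDs.
#' @param abnormalShift signed shift in control-SD units (default -3).
#' @param abnormalSds abnormal SDs; default equal to `controlSds`.
#' @param covariateEffects list(age=, tiv=, site=) or NULL for defaults.
#' @param stageOccupancy list of per-group stage distributions or NULL for
#'   defaults (controls: geometric decay from stage 0; patients: uniform).
#' @param seed master seed.
#' @return a validated [CohortConfig-class] object.
#' @export
cohortConfig <- function(nControl = 119L, nPremanifest = 120L,
                         nManifest = 118L, nBiomarkers = 18L,
                         plantedSequence = seq_len(nBiomarkers),
                         biomarkerNames = sprintf("bm%02d", seq_len(nBiomarkers)),
                         controlMeans = seq(150, 10, length.out = nBiomarkers),
                         controlSds = 0.1 * controlMeans,
                         abnormalShift = rep(-3, nBiomarkers),
                         abnormalSds = controlSds,
                         covariateEffects = NULL,
                         stageOccupancy = NULL,
                         seed = 1L) {
  Z <- as.integer(nBiomarkers)
  if (is.null(covariateEffects)) {
    covariateEffects <- list(
      age = -0.02 * controlSds,            # per year of age
      tiv = 0.002 * controlSds,            # per mL of intracranial volume
      site = outer(c(0, 0.3, -0.2, 0.1), controlSds))
  }
  if (is.null(stageOccupancy)) {
    hc <- 0.35 ^ (0:Z); hc <- hc / sum(hc)  # mass at stage 0, geometric tail
    unif <- rep(1 / (Z + 1), Z + 1)
    stageOccupancy <- list(HC = hc, preHD = unif, HD = unif)
  }
  new("CohortConfig",
      nControl = as.integer(nControl), nPremanifest = as.integer(nPremanifest),
      nManifest = as.integer(nManifest), nBiomarkers = Z,
      plantedSequence = as.integer(plantedSequence),
      biomarkerNames = biomarkerNames,
      controlMeans = as.numeric(controlMeans),
      controlSds = as.numeric(controlSds),
      abnormalShift = as.numeric(abnormalShift),
      abnormalSds = as.numeric(abnormalSds),
      covariateEffects = covariateEffects,
      stageOccupancy = stageOccupancy,
      seed = as.integer(seed))
}

# draw one subject-visit's biomarker vector given its true stage
.drawVolumes <- function(config, stage, age, tiv, site) {
  Z <- config@nBiomarkers
  abnormal <- rep(FALSE, Z)
  if (stage > 0) abnormal[config@plantedSequence[seq_len(stage)]] <- TRUE
  mu <- ifelse(abnormal,
               config@controlMeans + config@abnormalShift * config@controlSds,
               config@controlMeans)
  sds <- ifelse(abnormal, config@abnormalSds, config@controlSds)
  ce <- config@covariateEffects
  mu + rnorm(Z, 0, sds) +
    ce$age * (age - 45) + ce$tiv * (tiv - 1390) + ce$site[site, ]
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws a cohort under the staged-progression generative model described in
#' [CohortConfig-class]: each subject receives a true stage from their
#' group's occupancy distribution; biomarkers up to that stage come from the
#' abnormal component and the rest from the control component; linear age,
#' TIV and site effects are added on the raw scale. Group-level age and TIV
#' distributions mirror the study demographics (mean ages 46.3/40.8/48.5
#' years; mean TIV 1392/1408/1362 mL).
#'
#' @param config a [CohortConfig-class].
#' @return an [HDCohort-class]; `metadata()` carries the config and planted
#'   sequence, `colData()$true_stage` the planted stages.
#' @examples
#' cohort <- generateCohort(cohortConfig(nBiomarkers = 6, seed = 7))
#' table(cohort$diagnosis)
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(streamSeed(config@seed, "cohort"))
  Z <- config@nBiomarkers
  groups <- rep(c("HC", "preHD", "HD"),
                c(config@nControl, config@nPremanifest, config@nManifest))
  n <- length(groups)
  ageMean <- c(HC = 46.3, preHD = 40.8, HD = 48.5)
  ageSd   <- c(HC = 10.2, preHD = 8.8, HD = 9.9)
  tivMean <- c(HC = 1392, preHD = 1408, HD = 1362)
  tivSd   <- c(HC = 136, preHD = 151, HD = 130)

  age <- rnorm(n, ageMean[groups], ageSd[groups])
  tiv <- rnorm(n, tivMean[groups], tivSd[groups])
  site <- sample.int(4, n, replace = TRUE)
  stage <- unname(vapply(groups, function(g)
    sample.int(Z + 1, 1, prob = config@stageOccupancy[[g]]) - 1L, 1L))

  vols <- matrix(0, Z, n, dimnames = list(config@biomarkerNames, NULL))
  for (j in seq_len(n))
    vols[, j] <- .drawVolumes(config, stage[j], age[j], tiv[j], site[j])

  ids <- sprintf("S%03d", seq_len(n))
  colnames(vols) <- ids
  cd <- DataFrame(subject_id = ids, visit_months = 0L,
                  diagnosis = groups, age = age,
                  site = factor(paste0("site", site)), tiv = tiv,
                  true_stage = stage, row.names = ids)
  new("HDCohort", SummarizedExperiment(
    assays = list(volumes = vols), colData = cd,
    metadata = list(config = config,
                    plantedSequence = config@plantedSequence)))
}

#' Add longitudinal follow-up visits
#'
#' Extends a baseline cohort with follow-up visits. True stages advance by
#' Poisson increments with expectation `stagesPerYear` per year, capped at
#' Z, so stages are non-decreasing in time. Biomarker values are redrawn at
#' each visit from the component dictated by the visit's stage (fresh
#' measurement noise); age advances with time while site and TIV are fixed.
#' A `converter` flag marks subjects premanifest at baseline whose true
#' stage reaches `conversionStage` by the last visit within 36 months.
#'
#' @param cohort baseline [HDCohort-class] from [generateCohort()].
#' @param nVisits total number of visits including baseline (>= 2).
#' @param stagesPerYear expected stage advance per year (>= 0).
#' @param visitIntervalMonths spacing between visits (default 12).
#' @param conversionStage true stage at which a premanifest subject is
#'   deemed to have converted to manifest disease (default 13, the stage
#'   bracket associated with motor onset).
#' @return an [HDCohort-class] with one column per subject-visit.
#' @export
generateLongitudinal <- function(cohort, nVisits = 4L, stagesPerYear = 1,
                                 visitIntervalMonths = 12,
                                 conversionStage = 13L) {
  stopifnot(is(cohort, "HDCohort"))
  if (nVisits < 2) stop("`nVisits` must be at least 2")
  if (stagesPerYear < 0) stop("`stagesPerYear` must be non-negative")
  config <- metadata(cohort)$config
  if (is.null(config)) stop("cohort carries no generator config")
  set.seed(streamSeed(config@seed, "visits"))
  Z <- config@nBiomarkers
  cd0 <- colData(cohort)
  n <- ncol(cohort)
  dtYears <- visitIntervalMonths / 12

  stages <- matrix(0L, n, nVisits)
  stages[, 1] <- cd0$true_stage
  for (v in 2:nVisits)
    stages[, v] <- pmin(Z, stages[, v - 1] + rpois(n, stagesPerYear * dtYears))

  volsList <- vector("list", nVisits)
  volsList[[1]] <- assay(cohort, "volumes")
  months <- (seq_len(nVisits) - 1L) * visitIntervalMonths
  for (v in 2:nVisits) {
    m <- matrix(0, Z, n, dimnames = dimnames(volsList[[1]]))
    for (j in seq_len(n))
      m[, j] <- .drawVolumes(config, stages[j, v],
                             cd0$age[j] + months[v] / 12,
                             cd0$tiv[j], as.integer(cd0$site[j]))
    volsList[[v]] <- m
  }

  lastWithin36 <- max(which(months <= 36))
  converter <- cd0$diagnosis == "preHD" &
    stages[, lastWithin36] >= conversionStage

  cdList <- lapply(seq_len(nVisits), function(v) {
    cd <- cd0
    cd$visit_months <- months[v]
    cd$age <- cd0$age + months[v] / 12
    cd$true_stage <- stages[, v]
    cd$converter <- converter
    rownames(cd) <- paste0(cd$subject_id, "_m", months[v])
    cd
  })
  vols <- do.call(cbind, volsList)
  colnames(vols) <- unlist(lapply(cdList, rownames))
  md <- metadata(cohort)
  md$stagesPerYear <- stagesPerYear
  new("HDCohort", SummarizedExperiment(
    assays = list(volumes = vols), colData = do.call(rbind, cdList),
    metadata = md))
}

#' Add stage-linked phenotype scores
#'
#' Attaches phenotype columns generated as
#' `intercept + slope * true_stage + N(0, noiseSd)`. Default slopes mirror
#' the direction conventions of the clinical markers: motor impairment
#' (TMS) and genetic burden (CAP) increase with stage, cognitive scores
#' (SDMT, Stroop) decrease.
#'
#' @param cohort an [HDCohort-class] with `true_stage` in its colData.
#' @param slopes,intercepts,noiseSd named numeric vectors; names define the
#'   phenotypes. `noiseSd` must be non-negative (0 gives noise-free scores).
#' @return the cohort with one colData column per phenotype.
#' @export
generatePhenotypes <- function(cohort,
                               slopes = c(TMS = 0.98, SDMT = -1.0,
                                          Stroop = -1.4, CAP = 0.014),
                               intercepts = c(TMS = 2, SDMT = 55,
                                              Stroop = 110, CAP = 0.75),
                               noiseSd = c(TMS = 4, SDMT = 7,
                                           Stroop = 12, CAP = 0.12)) {
  stopifnot(is(cohort, "HDCohort"))
  known <- names(slopes)
  bad <- setdiff(union(names(intercepts), names(noiseSd)), known)
  if (length(bad))
    stop("unknown phenotype name(s): ", paste(bad, collapse = ", "))
  if (!setequal(names(intercepts), known) || !setequal(names(noiseSd), known))
    stop("slopes, intercepts and noiseSd must name the same phenotypes")
  if (any(noiseSd < 0)) stop("`noiseSd` must be non-negative")
  config <- metadata(cohort)$config
  if (is.null(config)) stop("cohort carries no generator config")
  set.seed(streamSeed(config@seed, "phenotypes"))
  k <- colData(cohort)$true_stage
  for (ph in known) {
    colData(cohort)[[ph]] <- intercepts[[ph]] + slopes[[ph]] * k +
      rnorm(length(k), 0, noiseSd[[ph]])
  }
  cohort
}
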
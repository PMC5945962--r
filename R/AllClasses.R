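#' HDCohort: a cohort of subjects with regional volume biomarkers
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the column
#' metadata the event-based model needs. Rows are biomarkers (regional brain
#' volumes), columns are subject-visits. The `"volumes"` assay holds raw
#' (uncorrected) values; [correctCovariates()] adds a `"corrected"` assay of
#' covariate-adjusted residuals. Required colData columns: `subject_id`,
#' `visit_months`, `diagnosis` (one of `"HC"`, `"preHD"`, `"HD"`), `age`,
#' `site`, `tiv`. Synthetic cohorts additionally carry `true_stage` and,
#' optionally, phenotype columns (`TMS`, `SDMT`, `Stroop`, `CAP`) and a
#' logical `converter` flag.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("HDCohort", contains = "SummarizedExperiment")

.validHDCohort <- function(object) {
  msg <- NULL
  required <- c("subject_id", "visit_months", "diagnosis", "age", "site", "tiv")
  missing <- setdiff(required, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing colData column(s): ",
                         paste(missing, collapse = ", ")))
  if (!"volumes" %in% assayNames(object))
    msg <- c(msg, "assay 'volumes' is required")
  if (!length(msg)) {
    dx <- as.character(object$diagnosis)
    bad <- setdiff(unique(dx), c("HC", "preHD", "HD"))
    if (length(bad))
      msg <- c(msg, paste0("unknown diagnosis value(s): ",
                           paste(bad, collapse = ", ")))
    if (anyNA(assay(object, "volumes")))
      msg <- c(msg, "assay 'volumes' contains missing values")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("HDCohort", .validHDCohort)

#' EventModelFits: per-biomarker normal and abnormal component parameters
#'
#' One row per biomarker: the control (normal) Gaussian \eqn{P(x|\neg E)},
#' the fitted abnormal Gaussian \eqn{P(x|E)}, the mixing weight (fraction of
#' patient values attributed to the abnormal component), and EM convergence
#' diagnostics.
#'
#' @slot fits data.frame with columns `biomarker`, `normal_mean`,
#'   `normal_sd`, `abnormal_mean`, `abnormal_sd`, `weight`, `converged`,
#'   `n_iterations`.
#' @export
setClass("EventModelFits", representation(fits = "data.frame"))

.validEventModelFits <- function(object) {
  f <- object@fits
  need <- c("biomarker", "normal_mean", "normal_sd", "abnormal_mean",
            "abnormal_sd", "weight", "converged", "n_iterations")
  missing <- setdiff(need, names(f))
  if (length(missing))
    return(paste0("missing fit column(s): ", paste(missing, collapse = ", ")))
  msg <- NULL
  if (any(f$normal_sd <= 0) || any(f$abnormal_sd <= 0))
    msg <- c(msg, "component standard deviations must be positive")
  if (any(f$weight <= 0 | f$weight >= 1))
    msg <- c(msg, "mixing weights must lie strictly in (0, 1)")
  if (anyDuplicated(f$biomarker))
    msg <- c(msg, "duplicate biomarker names")
  if (is.null(msg)) TRUE else msg
}
setValidity("EventModelFits", .validEventModelFits)

#' EventLikelihoodTable: per subject-biomarker component log-densities
#'
#' Log densities of every observed value under the abnormal
#' (\eqn{P(x|E)}) and normal (\eqn{P(x|\neg E)}) component, stored as
#' biomarkers x subjects matrices. All sequence-likelihood arithmetic runs
#' off this table.
#'
#' @slot logPE biomarkers x subjects matrix of abnormal-component log densities.
#' @slot logPNotE matching matrix of normal-component log densities.
#' @export
setClass("EventLikelihoodTable",
         representation(logPE = "matrix", logPNotE = "matrix"))

.validEventLikelihoodTable <- function(object) {
  msg <- NULL
  if (!identical(dim(object@logPE), dim(object@logPNotE)))
    msg <- c(msg, "logPE and logPNotE dimensions differ")
  if (!all(is.finite(object@logPE)) || !all(is.finite(object@logPNotE)))
    msg <- c(msg, "log-likelihood entries must be finite")
  if (is.null(msg)) TRUE else msg
}
setValidity("EventLikelihoodTable", .validEventLikelihoodTable)

#' MCMCTrace: posterior samples over event orderings
#'
#' @slot samples integer matrix, one post-burn-in sample per row, each row a
#'   permutation of 1..Z (position 1 = earliest event).
#' @slot logLik per-sample sequence log-likelihood.
#' @slot acceptanceRate fraction of proposals accepted over the whole chain.
#' @slot seed integer seed the chain was run with.
#' @slot nBurnIn number of discarded initial iterations.
#' @export
setClass("MCMCTrace",
         representation(samples = "matrix", logLik = "numeric",
                        acceptanceRate = "numeric", seed = "integer",
                        nBurnIn = "integer"))

.validMCMCTrace <- function(object) {
  msg <- NULL
  if (nrow(object@samples) != length(object@logLik))
    msg <- c(msg, "one log-likelihood per sample required")
  if (object@acceptanceRate < 0 || object@acceptanceRate > 1)
    msg <- c(msg, "acceptance rate must lie in [0, 1]")
  Z <- ncol(object@samples)
  if (nrow(object@samples) > 0 &&
      !all(apply(object@samples, 1, function(s) identical(sort(s), seq_len(Z)))))
    msg <- c(msg, "every sample must be a permutation of 1..Z")
  if (is.null(msg)) TRUE else msg
}
setValidity("MCMCTrace", .validMCMCTrace)

#' PositionalVarianceDiagram: positional posterior frequencies
#'
#' Entry (i, p) is the fraction of samples that place biomarker i at
#' sequence position p. Rows are ordered by the maximum-likelihood sequence
#' for display, so a perfectly certain ordering is the identity matrix.
#' Rows and columns each sum to one: every sample contributes exactly one
#' position per biomarker and one biomarker per position.
#'
#' @slot matrix biomarkers x positions matrix of frequencies in [0, 1].
#' @export
setClass("PositionalVarianceDiagram", representation(matrix = "matrix"))

.validPVD <- function(object) {
  m <- object@matrix
  msg <- NULL
  if (nrow(m) != ncol(m))
    msg <- c(msg, "PVD must be square (biomarkers x positions)")
  if (any(m < -1e-12) || any(m > 1 + 1e-12))
    msg <- c(msg, "PVD entries must lie in [0, 1]")
  if (max(abs(rowSums(m) - 1)) > 1e-8 || max(abs(colSums(m) - 1)) > 1e-8)
    msg <- c(msg, "PVD rows and columns must each sum to 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("PositionalVarianceDiagram", .validPVD)

#' StageAssignments: per subject-visit model stages
#'
#' @slot table data.frame with `subject_id`, `visit_months`, `diagnosis`,
#'   `stage` (0..Z).
#' @slot logLikByStage subjects x (Z+1) matrix of stage log-likelihoods,
#'   columns named "0".."Z".
#' @slot sequence the event ordering the stages refer to.
#' @export
setClass("StageAssignments",
         representation(table = "data.frame", logLikByStage = "matrix",
                        sequence = "integer"))

.validStageAssignments <- function(object) {
  msg <- NULL
  Z <- length(object@sequence)
  if (ncol(object@logLikByStage) != Z + 1)
    msg <- c(msg, "logLikByStage must have Z+1 columns (stages 0..Z)")
  if (nrow(object@table) != nrow(object@logLikByStage))
    msg <- c(msg, "one stage log-likelihood row per subject required")
  if (!is.null(msg)) return(msg)
  if (any(object@table$stage < 0 | object@table$stage > Z))
    msg <- c(msg, "stages must lie in 0..Z")
  # smallest-k tie rule: the assigned stage is the first argmax
  first <- max.col(object@logLikByStage, ties.method = "first") - 1L
  if (!all(object@table$stage == first))
    msg <- c(msg, "stage must be the (smallest-k) argmax of logLikByStage")
  if (is.null(msg)) TRUE else msg
}
setValidity("StageAssignments", .validStageAssignments)
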
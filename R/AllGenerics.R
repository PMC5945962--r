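#' @name accessors
#' @title Accessors for ebmHD objects
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an ebmHD S4 object.
#' @return `fitsTable()` the per-biomarker parameter data.frame;
#'   `pvdMatrix()` the positional-frequency matrix; `stageTable()` the
#'   per-subject stage data.frame; `stageLogLik()` the subjects x stages
#'   log-likelihood matrix; `mcmcSamples()` the sample matrix;
#'   `acceptanceRate()` the chain acceptance fraction; `logPE()` /
#'   `logPNotE()` the component log-density matrices.
NULL

#' @rdname accessors
#' @export
setGeneric("fitsTable", function(x) standardGeneric("fitsTable"))
#' @rdname accessors
#' @export
setMethod("fitsTable", "EventModelFits", function(x) x@fits)

#' @rdname accessors
#' @export
setGeneric("pvdMatrix", function(x) standardGeneric("pvdMatrix"))
#' @rdname accessors
#' @export
setMethod("pvdMatrix", "PositionalVarianceDiagram", function(x) x@matrix)

#' @rdname accessors
#' @export
setGeneric("stageTable", function(x) standardGeneric("stageTable"))
#' @rdname accessors
#' @export
setMethod("stageTable", "StageAssignments", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("stageLogLik", function(x) standardGeneric("stageLogLik"))
#' @rdname accessors
#' @export
setMethod("stageLogLik", "StageAssignments", function(x) x@logLikByStage)

#' @rdname accessors
#' @export
setGeneric("mcmcSamples", function(x) standardGeneric("mcmcSamples"))
#' @rdname accessors
#' @export
setMethod("mcmcSamples", "MCMCTrace", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))
#' @rdname accessors
#' @export
setMethod("acceptanceRate", "MCMCTrace", function(x) x@acceptanceRate)

#' @rdname accessors
#' @export
setGeneric("logPE", function(x) standardGeneric("logPE"))
#' @rdname accessors
#' @export
setMethod("logPE", "EventLikelihoodTable", function(x) x@logPE)

#' @rdname accessors
#' @export
setGeneric("logPNotE", function(x) standardGeneric("logPNotE"))
#' @rdname accessors
#' @export
setMethod("logPNotE", "EventLikelihoodTable", function(x) x@logPNotE)

setMethod("show", "EventModelFits", function(object) {
  f <- object@fits
  cat("EventModelFits with", nrow(f), "biomarkers\n")
  cat("  converged:", sum(f$converged), "/", nrow(f), "\n")
  cat("  weight range: [", signif(min(f$weight), 3), ",",
      signif(max(f$weight), 3), "]\n")
})

setMethod("show", "EventLikelihoodTable", function(object) {
  cat("EventLikelihoodTable:", nrow(object@logPE), "biomarkers x",
      ncol(object@logPE), "subjects (log space)\n")
})

setMethod("show", "MCMCTrace", function(object) {
  cat("MCMCTrace:", nrow(object@samples), "post-burn-in samples over",
      ncol(object@samples), "events\n")
  cat("  acceptance rate:", signif(object@acceptanceRate, 3),
      "| burn-in:", object@nBurnIn, "| seed:", object@seed, "\n")
  if (length(object@logLik))
    cat("  max log-likelihood:", format(max(object@logLik)), "\n")
})

setMethod("show", "PositionalVarianceDiagram", function(object) {
  m <- object@matrix
  cat("PositionalVarianceDiagram:", nrow(m), "events\n")
  cat("  diagonal mass (ordering certainty):",
      signif(mean(diag(m)), 3), "\n")
})

setMethod("show", "StageAssignments", function(object) {
  t <- object@table
  cat("StageAssignments:", nrow(t), "subject-visits, stages 0..",
      length(object@sequence), "\n", sep = "")
  print(summary(t$stage))
})
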
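.reservedCols <- c("subject_id", "visit_months", "diagnosis", "age", "site",
                   "tiv", "TMS", "SDMT", "Stroop", "CAP", "converter",
                   "true_stage")

#' Write a cohort to the canonical CSV layout
#'
#' One row per subject-visit: `subject_id`, `visit_months`, `diagnosis`,
#' `age`, `site`, `tiv`, any phenotype/converter columns present, then one
#' column per biomarker. If `truthPath` is given, a ground-truth sidecar is
#' written with the true stages and the planted sequence as a header
#' comment.
#'
#' @param cohort an [HDCohort-class].
#' @param path output CSV path.
#' @param truthPath optional path for the ground-truth sidecar CSV.
#' @return `path`, invisibly.
#' @export
writeCohortCSV <- function(cohort, path, truthPath = NULL) {
  stopifnot(is(cohort, "HDCohort"))
  cd <- as.data.frame(colData(cohort))
  meta <- intersect(.reservedCols, colnames(cd))
  meta <- setdiff(meta, "true_stage")
  df <- cbind(cd[, meta, drop = FALSE],
              as.data.frame(t(assay(cohort, "volumes"))))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(truthPath)) {
    con <- file(truthPath, "w")
    on.exit(close(con))
    ps <- metadata(cohort)$plantedSequence
    if (!is.null(ps))
      writeLines(paste0("# planted_sequence: ",
                        paste(rownames(cohort)[ps], collapse = ",")), con)
    truth <- cd[, intersect(c("subject_id", "visit_months", "true_stage",
                              "converter"), colnames(cd)), drop = FALSE]
    write.csv(truth, con, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort from the canonical CSV layout
#'
#' Validates the required columns, the diagnosis vocabulary, numeric
#' parsability of biomarker columns, and uniqueness of the
#' subject-id/visit key, with errors naming the offending columns.
#'
#' @param path CSV path (layout of [writeCohortCSV()]).
#' @param biomarkerCols optional character vector naming the biomarker
#'   columns; by default every non-reserved column is treated as one.
#' @return an [HDCohort-class].
#' @export
readCohortCSV <- function(path, biomarkerCols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "visit_months", "diagnosis", "age", "site",
                "tiv")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (is.null(biomarkerCols))
    biomarkerCols <- setdiff(colnames(df), .reservedCols)
  if (!length(biomarkerCols)) stop("no biomarker columns found")
  bad <- biomarkerCols[!vapply(df[biomarkerCols], is.numeric, TRUE)]
  if (length(bad))
    stop("non-numeric biomarker column(s): ", paste(bad, collapse = ", "))
  key <- paste(df$subject_id, df$visit_months)
  if (anyDuplicated(key))
    stop("duplicate subject-visit key(s): ",
         paste(head(unique(key[duplicated(key)]), 5), collapse = "; "))
  vols <- t(as.matrix(df[, biomarkerCols, drop = FALSE]))
  ids <- paste0(df$subject_id,
                ifelse(df$visit_months > 0, paste0("_m", df$visit_months), ""))
  colnames(vols) <- ids
  extra <- intersect(c("TMS", "SDMT", "Stroop", "CAP", "converter",
                       "true_stage"), colnames(df))
  cd <- DataFrame(df[, c(required, extra), drop = FALSE], row.names = ids)
  cd$site <- factor(cd$site)
  new("HDCohort", SummarizedExperiment(assays = list(volumes = vols),
                                       colData = cd))
}

#' Run the full event-based model pipeline
#'
#' Chains preparation (covariate correction, biomarker selection, outlier
#' removal), per-biomarker mixture fitting, maximum-likelihood sequence
#' estimation (with optional MCMC positional variance), staging, and
#' whatever validation analyses the cohort's columns support (longitudinal
#' consistency, conversion prediction, phenotype regression). Identical
#' input, configuration and seed reproduce identical outputs.
#'
#' @param cohort an [HDCohort-class] (e.g. from [generateCohort()] or
#'   [readCohortCSV()]).
#' @param pThreshold,tThreshold selection thresholds (defaults 0.001, 8).
#' @param bilateralMap optional left/right pairing for selection.
#' @param nSigma outlier cut-off in within-group SDs (default 5).
#' @param nRestarts greedy restarts for the sequence search (default 10).
#' @param nMCMC post-burn-in MCMC samples for the positional variance
#'   diagram; 0 skips MCMC.
#' @param nBurnIn MCMC burn-in iterations.
#' @param nBootstrap bootstrap resamples for the cross-validated PVD;
#'   0 skips the bootstrap.
#' @param seed integer seed governing every stochastic step.
#' @param outDir optional directory; when given, all artifacts are written
#'   as CSV/JSON-like text files plus a run manifest.
#' @return list with elements `selection`, `cohort` (prepared), `fits`,
#'   `sequence`, `sequenceLogLik`, `stages`, and (when computed) `pvd`,
#'   `bootstrapPvd`, `volumetrics`, `stageDistribution`, `longitudinal`,
#'   `conversion`, `phenotypes`.
#' @export
runEBMPipeline <- function(cohort, pThreshold = 0.001, tThreshold = 8,
                           bilateralMap = NULL, nSigma = 5,
                           nRestarts = 10L, nMCMC = 0L, nBurnIn = 1000L,
                           nBootstrap = 0L, seed = 1L, outDir = NULL) {
  stopifnot(is(cohort, "HDCohort"))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- step("correct_covariates", correctCovariates(cohort))
  selection <- step("select_biomarkers",
                    selectBiomarkers(cohort, pThreshold, tThreshold,
                                     bilateralMap))
  keep <- selection$selected
  if (!any(keep)) stop("pipeline stage 'select_biomarkers' selected nothing")
  cohort <- cohort[selection$biomarker[keep], ]
  cohort <- step("remove_outliers", removeOutliers(cohort, nSigma))
  fits <- step("fit_distributions", fitEventModels(cohort))
  table <- step("event_likelihoods", eventLikelihoods(cohort, fits))
  est <- step("find_sequence",
              estimateSequence(table, nRestarts = nRestarts,
                               nSamples = max(nMCMC, 10000L),
                               nBurnIn = nBurnIn, seed = seed))
  mlSeq <- est$sequence
  res <- list(selection = selection, cohort = cohort, fits = fits,
              sequence = mlSeq,
              sequenceNames = rownames(cohort)[mlSeq],
              sequenceLogLik = est$logLik)
  if (nMCMC > 0) {
    res$trace <- est$trace
    res$pvd <- positionalVariance(est$trace, displayOrder = mlSeq,
                                  biomarkerNames = rownames(cohort))
  }
  if (nBootstrap > 0)
    res$bootstrapPvd <- step("bootstrap",
      bootstrapPVD(cohort, nBootstrap = nBootstrap, seed = seed,
                   referenceSequence = mlSeq))
  res$stages <- step("stage_subjects", stageSubjects(cohort, mlSeq, fits))
  res$volumetrics <- step("volumetric_summary", volumetricSummary(cohort, fits))
  res$stageDistribution <- stageDistribution(res$stages)
  cd <- colData(cohort)
  if (length(unique(cd$visit_months)) > 1)
    res$longitudinal <- step("longitudinal",
                             longitudinalConsistency(res$stages))
  if ("converter" %in% colnames(cd)) {
    base <- cd$visit_months == min(cd$visit_months)
    conv <- setNames(cd$converter[base], cd$subject_id[base])
    pre <- res$stages
    preTab <- pre@table$diagnosis == "preHD"
    predArgs <- new("StageAssignments",
                    table = pre@table[preTab, ],
                    logLikByStage = pre@logLikByStage[preTab, , drop = FALSE],
                    sequence = pre@sequence)
    conv <- conv[predArgs@table$subject_id[
      predArgs@table$visit_months == min(predArgs@table$visit_months)]]
    if (any(conv) && !all(conv))
      res$conversion <- step("conversion",
                             predictConversion(predArgs, conv))
  }
  if (any(c("TMS", "SDMT", "Stroop", "CAP") %in% colnames(cd)))
    res$phenotypes <- step("phenotypes",
                           phenotypeRegression(res$stages, cohort))
  if (!is.null(outDir)) .writeArtifacts(res, outDir, seed)
  res
}

.writeArtifacts <- function(res, outDir, seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$selection, file.path(outDir, "selection_report.csv"),
            row.names = FALSE)
  write.csv(fitsTable(res$fits), file.path(outDir, "event_model_fits.csv"),
            row.names = FALSE)
  write.csv(data.frame(position = seq_along(res$sequence),
                       biomarker = res$sequenceNames),
            file.path(outDir, "ml_sequence.csv"), row.names = FALSE)
  write.csv(stageTable(res$stages), file.path(outDir, "stages.csv"),
            row.names = FALSE)
  write.csv(res$volumetrics, file.path(outDir, "volumetric_summary.csv"),
            row.names = FALSE)
  log <- metadata(res$cohort)$outlierLog
  if (!is.null(log))
    write.csv(log, file.path(outDir, "outlier_log.csv"), row.names = FALSE)
  if (!is.null(res$pvd))
    write.csv(pvdMatrix(res$pvd), file.path(outDir, "pvd_mcmc.csv"))
  if (!is.null(res$bootstrapPvd))
    write.csv(pvdMatrix(res$bootstrapPvd),
              file.path(outDir, "pvd_bootstrap.csv"))
  manifest <- c(
    paste0("seed: ", seed),
    paste0("n_biomarkers: ", length(res$sequence)),
    paste0("n_subject_visits: ", ncol(res$cohort)),
    paste0("sequence_log_likelihood: ",
           format(res$sequenceLogLik, digits = 17)),
    paste0("r_version: ", R.version.string),
    paste0("package_version: ",
           as.character(utils::packageVersion("ebmHD"))))
  writeLines(manifest, file.path(outDir, "run_manifest.txt"))
  invisible(NULL)
}
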
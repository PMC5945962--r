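#' Covariate correction of regional volumes
#'
#' Regresses each biomarker on age, total intracranial volume (TIV) and
#' acquisition site (categorical, reference-level dummy coding) with
#' ordinary least squares, and stores the residuals as a `"corrected"`
#' assay. By default the regression is fitted on healthy controls only
#' (baseline visits) and then applied to every subject-visit: control
#' residuals are anchored at mean zero per biomarker, and disease effects
#' cannot contaminate the covariate coefficients. Set `fitGroup = "all"` to
#' fit on the pooled baseline sample instead.
#'
#' @param cohort an [HDCohort-class] with a `"volumes"` assay.
#' @param fitGroup `"HC"` (default) or `"all"`: which baseline subjects the
#'   covariate model is estimated on.
#' @return the cohort with an added `"corrected"` assay of residuals.
#' @export
correctCovariates <- function(cohort, fitGroup = c("HC", "all")) {
  stopifnot(is(cohort, "HDCohort"))
  fitGroup <- match.arg(fitGroup)
  cd <- colData(cohort)
  if (anyNA(cd$age) || anyNA(cd$tiv) || anyNA(cd$site))
    stop("missing covariate values")

  baseline <- cd$visit_months == min(cd$visit_months)
  inFit <- baseline & (fitGroup == "all" | cd$diagnosis == "HC")
  df <- data.frame(age = cd$age, tiv = cd$tiv, site = factor(cd$site))
  # constant covariates carry no information and are dropped from the
  # design (identical covariates reduce to intercept-only centering)
  keep <- vapply(df[inFit, , drop = FALSE],
                 function(v) length(unique(v)) > 1, TRUE)
  form <- if (any(keep))
    stats::reformulate(names(df)[keep], response = "y") else y ~ 1
  vols <- assay(cohort, "volumes")
  corrected <- vols
  for (i in seq_len(nrow(vols))) {
    fitDf <- cbind(df[inFit, , drop = FALSE], y = vols[i, inFit])
    fit <- lm(form, data = fitDf)
    cf <- coef(fit)
    if (anyNA(cf))
      stop("rank-deficient covariate design; collinear column(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    corrected[i, ] <- vols[i, ] - predict(fit, newdata = df)
  }
  assay(cohort, "corrected") <- corrected
  cohort
}

#' Data-driven biomarker selection
#'
#' Per biomarker, a two-tailed Welch t-test compares covariate-corrected
#' values between healthy controls and manifest subjects (baseline visits).
#' A biomarker is selected when its multiplicity-corrected p-value falls
#' below `pThreshold` and its effect size satisfies |t| > `tThreshold`.
#' Bilateral (left/right) pairs are retained only if both members pass;
#' otherwise both are dropped.
#'
#' @param cohort an [HDCohort-class] with a `"corrected"` assay.
#' @param pThreshold corrected p-value cut-off (default 0.001).
#' @param tThreshold absolute t-statistic cut-off (default 8.0).
#' @param bilateralMap optional two-column data.frame (or list of length-2
#'   character vectors) pairing left/right biomarker labels.
#' @param correction multiple-comparison method passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return a data.frame (one row per biomarker): `t`, `p`, `p_adj`,
#'   `selected`, `reason` (empty when selected).
#' @export
selectBiomarkers <- function(cohort, pThreshold = 0.001, tThreshold = 8.0,
                             bilateralMap = NULL,
                             correction = "bonferroni") {
  stopifnot(is(cohort, "HDCohort"))
  if (!"corrected" %in% assayNames(cohort))
    stop("run correctCovariates() first: no 'corrected' assay")
  cd <- colData(cohort)
  baseline <- cd$visit_months == min(cd$visit_months)
  hc <- baseline & cd$diagnosis == "HC"
  hd <- baseline & cd$diagnosis == "HD"
  if (sum(hc) < 3 || sum(hd) < 3)
    stop("need at least 3 HC and 3 HD subjects")
  x <- assay(cohort, "corrected")
  bm <- rownames(x)

  tt <- lapply(seq_along(bm), function(i)
    t.test(x[i, hd], x[i, hc], var.equal = FALSE))
  tstat <- vapply(tt, function(f) unname(f$statistic), 0)
  p <- vapply(tt, function(f) f$p.value, 0)
  pAdj <- p.adjust(p, method = correction)

  selected <- pAdj < pThreshold & abs(tstat) > tThreshold
  reason <- ifelse(selected, "",
            ifelse(pAdj >= pThreshold & abs(tstat) <= tThreshold,
                   "p and |t| below threshold",
            ifelse(pAdj >= pThreshold, "corrected p above threshold",
                   "|t| below threshold")))

  if (!is.null(bilateralMap)) {
    if (is.data.frame(bilateralMap))
      bilateralMap <- asplit(as.matrix(bilateralMap), 1)
    for (pair in bilateralMap) {
      pair <- as.character(pair)
      if (!all(pair %in% bm))
        stop("bilateral pair label(s) not in biomarkers: ",
             paste(setdiff(pair, bm), collapse = ", "))
      idx <- match(pair, bm)
      if (!all(selected[idx]) && any(selected[idx])) {
        reason[idx][selected[idx]] <- "contralateral side failed"
        selected[idx] <- FALSE
      }
    }
  }
  data.frame(biomarker = bm, t = tstat, p = p, p_adj = pAdj,
             selected = selected, reason = reason,
             row.names = NULL)
}

#' Remove outlying subjects
#'
#' Flags every corrected value more than `nSigma` standard deviations from
#' its within-diagnosis-group biomarker mean and removes the offending
#' subjects entirely (all visits). The removal log — one row per flagged
#' subject x biomarker with its z-score — is stored in
#' `metadata(cohort)$outlierLog`.
#'
#' @param cohort an [HDCohort-class] with a `"corrected"` assay.
#' @param nSigma z-score cut-off (default 5).
#' @return the filtered cohort.
#' @export
removeOutliers <- function(cohort, nSigma = 5) {
  stopifnot(is(cohort, "HDCohort"))
  if (!"corrected" %in% assayNames(cohort))
    stop("run correctCovariates() first: no 'corrected' assay")
  cd <- colData(cohort)
  baseline <- cd$visit_months == min(cd$visit_months)
  x <- assay(cohort, "corrected")
  log <- data.frame(subject_id = character(), biomarker = character(),
                    z = numeric())
  flagged <- character()
  for (g in unique(cd$diagnosis)) {
    cols <- baseline & cd$diagnosis == g
    sub <- x[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdev <- apply(sub, 1, sd)
    if (any(sdev == 0)) stop("zero within-group SD in group ", g)
    z <- (sub - mu) / sdev
    hits <- which(abs(z) > nSigma, arr.ind = TRUE)
    if (nrow(hits)) {
      ids <- cd$subject_id[cols][hits[, "col"]]
      log <- rbind(log, data.frame(subject_id = ids,
                                   biomarker = rownames(sub)[hits[, "row"]],
                                   z = z[hits]))
      flagged <- union(flagged, ids)
    }
  }
  keep <- !(cd$subject_id %in% flagged)
  if (!any(keep)) warning("outlier removal excluded every subject")
  out <- cohort[, keep]
  metadata(out)$outlierLog <- log
  out
}

#' Volumetric summary of group differences and abnormality thresholds
#'
#' For each biomarker, reports the percentage change of the manifest-group
#' corrected (residual) mean relative to the healthy-control raw-volume
#' mean, and the percentage change at the equal-likelihood abnormality
#' threshold (the corrected value at which the normal and abnormal
#' component densities cross). These thresholds are descriptive only; the
#' event-based model itself never uses cut points.
#'
#' @param cohort an [HDCohort-class] with `"volumes"` and `"corrected"`
#'   assays.
#' @param fits an [EventModelFits-class] covering every biomarker.
#' @return data.frame: `biomarker`, `hc_raw_mean`, `hd_residual_mean`,
#'   `pct_change`, `threshold`, `threshold_pct`, `note`.
#' @export
volumetricSummary <- function(cohort, fits) {
  stopifnot(is(cohort, "HDCohort"), is(fits, "EventModelFits"))
  f <- fitsTable(fits)
  bm <- rownames(cohort)
  if (!all(bm %in% f$biomarker))
    stop("fits missing for biomarker(s): ",
         paste(setdiff(bm, f$biomarker), collapse = ", "))
  cd <- colData(cohort)
  baseline <- cd$visit_months == min(cd$visit_months)
  hc <- baseline & cd$diagnosis == "HC"
  hd <- baseline & cd$diagnosis == "HD"
  hcRaw <- rowMeans(assay(cohort, "volumes")[, hc, drop = FALSE])
  hdRes <- rowMeans(assay(cohort, "corrected")[, hd, drop = FALSE])
  out <- data.frame(biomarker = bm, hc_raw_mean = hcRaw,
                    hd_residual_mean = hdRes, pct_change = NA_real_,
                    threshold = NA_real_, threshold_pct = NA_real_,
                    note = "", row.names = NULL)
  for (i in seq_along(bm)) {
    row <- f[f$biomarker == bm[i], ]
    thr <- tryCatch(
      abnormalityThreshold(list(mean = row$normal_mean, sd = row$normal_sd),
                           list(mean = row$abnormal_mean, sd = row$abnormal_sd)),
      error = function(e) NA_real_)
    out$threshold[i] <- thr
    if (hcRaw[i] == 0) {
      out$note[i] <- "HC raw mean is zero; percent change undefined"
    } else {
      out$pct_change[i] <- 100 * hdRes[i] / hcRaw[i]
      if (!is.na(thr)) out$threshold_pct[i] <- 100 * thr / hcRaw[i]
    }
  }
  out
}
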
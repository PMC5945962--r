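#' Fit the control (normal) component of a biomarker
#'
#' Maximum-likelihood Gaussian fit to healthy-control values: the sample
#' mean and the ML standard deviation (divisor n, not n-1). This provides
#' the model for the probability of a value given the event has not
#' occurred.
#'
#' @param values numeric vector of control values (>= 3, non-degenerate).
#' @return list with `mean` and `sd`.
#' @examples
#' fitControlModel(c(-1, 0, 1))  # mean 0, sd sqrt(2/3)
#' @export
fitControlModel <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 control values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("degenerate control distribution (zero variance)")
  list(mean = m, sd = s)
}

#' Fit the patient mixture with a fixed control component
#'
#' Expectation-maximisation fit of a two-component Gaussian mixture to
#' patient values in which the first (normal) component is held fixed at
#' the control fit; only the abnormal component's mean and SD and the
#' mixing weight are estimated. The fitted abnormal component models the
#' probability of a value given the event has occurred.
#'
#' Initialisation: abnormal mean at the patient sample mean, abnormal SD at
#' the patient ML SD, weight 0.5. The abnormal SD is floored at
#' `sdFloor * normal$sd` to prevent density blow-up, and the weight is kept
#' inside `weightBounds` so both likelihood channels stay defined.
#'
#' @param values numeric vector of patient values (>= 5).
#' @param normal list(mean, sd): the fixed control component.
#' @param tol EM stopping tolerance on the log-likelihood change.
#' @param maxIter maximum EM iterations.
#' @param sdFloor abnormal-SD floor as a fraction of the control SD.
#' @param weightBounds allowed range for the abnormal mixing weight.
#' @return list: `normal` (unchanged), `abnormal` (mean, sd), `weight`,
#'   `converged`, `nIterations`, `logLikTrace`.
#' @export
fitPatientMixture <- function(values, normal, tol = 1e-6, maxIter = 500L,
                              sdFloor = 0.05, weightBounds = c(0.01, 0.99)) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 patient values")
  stopifnot(normal$sd > 0)
  muA <- mean(values)
  sdA <- max(sqrt(mean((values - muA)^2)), sdFloor * normal$sd)
  w <- 0.5
  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    dA <- dnorm(values, muA, sdA)
    dN <- dnorm(values, normal$mean, normal$sd)
    mix <- w * dA + (1 - w) * dN
    newLL <- sum(log(mix))
    trace <- c(trace, newLL)
    if (is.finite(ll) && abs(newLL - ll) < tol) { converged <- TRUE; break }
    ll <- newLL
    if (it >= maxIter) break
    r <- (w * dA) / mix                      # responsibility of abnormal comp.
    sr <- sum(r)
    muA <- sum(r * values) / sr
    sdA <- max(sqrt(sum(r * (values - muA)^2) / sr), sdFloor * normal$sd)
    w <- min(max(sr / length(values), weightBounds[1]), weightBounds[2])
  }
  if (!converged)
    warning("EM did not converge within ", maxIter, " iterations")
  list(normal = normal, abnormal = list(mean = muA, sd = sdA), weight = w,
       converged = converged, nIterations = it, logLikTrace = trace)
}

#' Fit event distribution models for every biomarker
#'
#' Convenience wrapper: per biomarker, fits the control Gaussian on
#' baseline healthy controls and the constrained patient mixture on
#' baseline manifest subjects, using the covariate-corrected values.
#' Premanifest subjects take no part in distribution fitting (they enter
#' only the sequence likelihood later).
#'
#' @param cohort an [HDCohort-class] with a `"corrected"` assay.
#' @param ... passed to [fitPatientMixture()].
#' @return an [EventModelFits-class].
#' @export
fitEventModels <- function(cohort, ...) {
  stopifnot(is(cohort, "HDCohort"))
  if (!"corrected" %in% assayNames(cohort))
    stop("run correctCovariates() first: no 'corrected' assay")
  cd <- colData(cohort)
  baseline <- cd$visit_months == min(cd$visit_months)
  hc <- baseline & cd$diagnosis == "HC"
  hd <- baseline & cd$diagnosis == "HD"
  x <- assay(cohort, "corrected")
  rows <- lapply(rownames(x), function(b) {
    ctrl <- fitControlModel(x[b, hc])
    fit <- fitPatientMixture(x[b, hd], ctrl, ...)
    data.frame(biomarker = b, normal_mean = ctrl$mean, normal_sd = ctrl$sd,
               abnormal_mean = fit$abnormal$mean,
               abnormal_sd = fit$abnormal$sd, weight = fit$weight,
               converged = fit$converged, n_iterations = fit$nIterations)
  })
  new("EventModelFits", fits = do.call(rbind, rows))
}

#' Component log-densities for every subject and biomarker
#'
#' Evaluates the fitted normal and abnormal Gaussian densities at every
#' observed (corrected) value, in log space.
#'
#' @param cohort an [HDCohort-class] with a `"corrected"` assay.
#' @param fits an [EventModelFits-class] covering every biomarker.
#' @return an [EventLikelihoodTable-class] (biomarkers x subject-visits).
#' @export
eventLikelihoods <- function(cohort, fits) {
  stopifnot(is(cohort, "HDCohort"), is(fits, "EventModelFits"))
  f <- fitsTable(fits)
  x <- assay(cohort, "corrected")
  idx <- match(rownames(x), f$biomarker)
  if (anyNA(idx))
    stop("fits missing for biomarker(s): ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  lpe <- dnorm(x, f$abnormal_mean[idx], f$abnormal_sd[idx], log = TRUE)
  lpn <- dnorm(x, f$normal_mean[idx], f$normal_sd[idx], log = TRUE)
  dimnames(lpe) <- dimnames(lpn) <- dimnames(x)
  new("EventLikelihoodTable", logPE = lpe, logPNotE = lpn)
}

#' Equal-likelihood abnormality threshold
#'
#' The corrected value at which a biomarker is equally likely to be normal
#' or abnormal, i.e. where the two component densities cross. For equal
#' SDs this is the midpoint of the means; otherwise the crossing solves a
#' quadratic and the root lying between the component means is returned.
#' If no root lies between the means (possible when the weight of evidence
#' is dominated by very different SDs), the root closest to the midpoint of
#' the means is returned instead.
#'
#' @param normal,abnormal lists with `mean` and `sd`; or pass an
#'   [EventModelFits-class] row via `volumetricSummary()`.
#' @return the threshold value (numeric scalar).
#' @examples
#' abnormalityThreshold(list(mean = 0, sd = 1), list(mean = -2, sd = 1))  # -1
#' @export
abnormalityThreshold <- function(normal, abnormal) {
  mN <- normal$mean; sN <- normal$sd
  mA <- abnormal$mean; sA <- abnormal$sd
  if (mN == mA && sN == sA)
    stop("components are identical; threshold undefined")
  if (abs(sN - sA) < 1e-12) {
    if (mN == mA) stop("equal means and SDs; threshold undefined")
    return((mN + mA) / 2)
  }
  # dnorm(x; mN, sN) = dnorm(x; mA, sA)  <=>  a x^2 + b x + c = 0
  a <- 1 / (2 * sA^2) - 1 / (2 * sN^2)
  b <- mN / sN^2 - mA / sA^2
  cc <- mA^2 / (2 * sA^2) - mN^2 / (2 * sN^2) + log(sA / sN)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real density crossing")
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(mN, mA); hi <- max(mN, mA)
  inside <- roots >= lo & roots <= hi
  if (any(inside)) return(roots[inside][1])
  roots[which.min(abs(roots - (mN + mA) / 2))]
}
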
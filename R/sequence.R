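#' Dataset log-likelihood of an event ordering
#'
#' Computes the log of the event-based model's dataset likelihood for a
#' given ordering: each subject's likelihood is the uniform-prior average
#' over all Z+1 stages of the product of abnormal-component densities for
#' events up to the stage and normal-component densities beyond it. The
#' computation runs in log space with a log-sum-exp over stages (the
#' literal per-stage product underflows at realistic cohort sizes) and
#' costs O(N Z) per evaluation.
#'
#' @param table an [EventLikelihoodTable-class].
#' @param order integer permutation of 1..Z; position 1 = earliest event.
#' @return the dataset log-likelihood (scalar).
#' @export
sequenceLogLik <- function(table, order) {
  stopifnot(is(table, "EventLikelihoodTable"))
  order <- checkSequence(order, nrow(table@logPE))
  cppSeqLogLik(table@logPE, table@logPNotE, order)
}

#' Exhaustive maximum-likelihood sequence (test oracle)
#'
#' Enumerates all Z! orderings and returns the maximiser; ties resolve to
#' the lexicographically smallest permutation. Guarded to Z <= 8.
#'
#' @param table an [EventLikelihoodTable-class] with at most 8 biomarkers.
#' @return integer permutation.
#' @export
exhaustiveMLSequence <- function(table) {
  stopifnot(is(table, "EventLikelihoodTable"))
  Z <- nrow(table@logPE)
  if (Z > 8)
    stop("exhaustive enumeration limited to Z <= 8 (", Z,
         "! permutations would be required); use findMLSequence()")
  perms <- allPermutations(Z)
  best <- perms[1, ]
  bestLL <- cppSeqLogLik(table@logPE, table@logPNotE, best)
  # ties (within floating-point noise) keep the earlier, i.e.
  # lexicographically smaller, permutation
  for (r in 2:nrow(perms)) {
    ll <- cppSeqLogLik(table@logPE, table@logPNotE, perms[r, ])
    if (ll > bestLL + 1e-10 * (1 + abs(bestLL))) {
      bestLL <- ll; best <- perms[r, ]
    }
  }
  as.integer(best)
}

# one greedy ascent pass from `order`: first-improvement sweeps over all
# pairwise swaps until a full sweep yields no gain
.greedyAscent <- function(lpe, lpn, order) {
  Z <- length(order)
  ll <- cppSeqLogLik(lpe, lpn, order)
  repeat {
    improved <- FALSE
    for (i in seq_len(Z - 1)) {
      for (j in (i + 1):Z) {
        cand <- order
        cand[c(i, j)] <- cand[c(j, i)]
        candLL <- cppSeqLogLik(lpe, lpn, cand)
        if (candLL > ll) {
          order <- cand; ll <- candLL; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(order = order, logLik = ll)
}

#' Greedy search for the maximum-likelihood sequence
#'
#' Hill-climbs over pairwise swaps from random initial permutations and
#' keeps the best ordering across restarts. Deterministic given `seed`.
#'
#' @param table an [EventLikelihoodTable-class].
#' @param nRestarts number of random restarts (default 10).
#' @param seed integer seed for the restart initialisations.
#' @return integer permutation whose log-likelihood is at least that of
#'   every ordering visited during the search.
#' @export
findMLSequence <- function(table, nRestarts = 10L, seed = 1L) {
  stopifnot(is(table, "EventLikelihoodTable"))
  if (nRestarts < 1) stop("`nRestarts` must be at least 1")
  Z <- nrow(table@logPE)
  set.seed(streamSeed(seed, "restart"))
  best <- NULL
  bestLL <- -Inf
  for (r in seq_len(nRestarts)) {
    init <- sample.int(Z)
    res <- .greedyAscent(table@logPE, table@logPNotE, init)
    if (res$logLik > bestLL) { bestLL <- res$logLik; best <- res$order }
  }
  as.integer(best)
}

#' MCMC sampling of the posterior over event orderings
#'
#' Metropolis-Hastings over permutations with symmetric random
#' pairwise-swap proposals; a proposal is accepted with probability
#' min(1, exp(delta log-likelihood)). Post-burn-in states are returned.
#'
#' @param table an [EventLikelihoodTable-class].
#' @param init initial permutation; `NULL` (default) initialises at the
#'   greedy maximum-likelihood estimate.
#' @param nSamples post-burn-in samples to keep (default 10000).
#' @param nBurnIn discarded initial iterations (default 1000).
#' @param seed integer seed.
#' @return an [MCMCTrace-class].
#' @export
mcmcSequence <- function(table, init = NULL, nSamples = 10000L,
                         nBurnIn = 1000L, seed = 1L) {
  stopifnot(is(table, "EventLikelihoodTable"))
  if (nSamples < 1) stop("`nSamples` must be at least 1")
  Z <- nrow(table@logPE)
  if (is.null(init)) init <- findMLSequence(table, seed = seed)
  cur <- checkSequence(init, Z)
  lpe <- table@logPE; lpn <- table@logPNotE
  curLL <- cppSeqLogLik(lpe, lpn, cur)
  set.seed(streamSeed(seed, "mcmc"))
  total <- nBurnIn + nSamples
  samples <- matrix(0L, nSamples, Z)
  lls <- numeric(nSamples)
  nAccept <- 0L
  for (it in seq_len(total)) {
    ij <- sample.int(Z, 2)
    cand <- cur
    cand[ij] <- cand[rev(ij)]
    candLL <- cppSeqLogLik(lpe, lpn, cand)
    if (candLL >= curLL || runif(1) < exp(candLL - curLL)) {
      cur <- cand; curLL <- candLL; nAccept <- nAccept + 1L
    }
    if (it > nBurnIn) {
      samples[it - nBurnIn, ] <- cur
      lls[it - nBurnIn] <- curLL
    }
  }
  new("MCMCTrace", samples = samples, logLik = lls,
      acceptanceRate = nAccept / total, seed = as.integer(seed),
      nBurnIn = as.integer(nBurnIn))
}

#' Estimate the characteristic sequence
#'
#' The full estimation procedure for the characteristic (maximum
#' likelihood) event ordering: greedy hill-climbing from random restarts
#' provides the initialisation, an MCMC chain then samples the posterior
#' over orderings, and the characteristic sequence is the highest
#' likelihood state visited (greedy optimum or MCMC sample, whichever is
#' better). Pairwise-swap hill climbing alone can stall in local optima of
#' the permutation landscape; the chain routinely escapes them.
#'
#' @param table an [EventLikelihoodTable-class].
#' @param nRestarts greedy restarts for the initialisation (default 10).
#' @param nSamples post-burn-in MCMC samples (default 100000).
#' @param nBurnIn burn-in iterations (default 10000).
#' @param seed integer seed.
#' @return list: `sequence` (the characteristic ordering), `logLik`, and
#'   `trace` (the [MCMCTrace-class], for positional variance diagrams).
#' @export
estimateSequence <- function(table, nRestarts = 10L, nSamples = 100000L,
                             nBurnIn = 10000L, seed = 1L) {
  init <- findMLSequence(table, nRestarts = nRestarts, seed = seed)
  trace <- mcmcSequence(table, init = init, nSamples = nSamples,
                        nBurnIn = nBurnIn, seed = seed)
  initLL <- sequenceLogLik(table, init)
  bestIdx <- which.max(trace@logLik)
  if (trace@logLik[bestIdx] > initLL) {
    list(sequence = as.integer(trace@samples[bestIdx, ]),
         logLik = trace@logLik[bestIdx], trace = trace)
  } else {
    list(sequence = init, logLik = initLL, trace = trace)
  }
}

#' Positional variance diagram from MCMC samples
#'
#' Entry (i, p) is the fraction of samples placing biomarker i at sequence
#' position p. Rows are ordered for display by the maximum-likelihood
#' sample (or an explicit `displayOrder`), so a certain ordering shows as
#' the identity matrix.
#'
#' @param trace an [MCMCTrace-class] with at least one sample.
#' @param displayOrder optional permutation fixing the row order; default
#'   is the trace's highest-likelihood sample.
#' @param biomarkerNames optional labels for the rows.
#' @return a [PositionalVarianceDiagram-class].
#' @export
positionalVariance <- function(trace, displayOrder = NULL,
                               biomarkerNames = NULL) {
  stopifnot(is(trace, "MCMCTrace"))
  s <- trace@samples
  if (nrow(s) == 0) stop("trace contains no samples")
  Z <- ncol(s)
  if (is.null(displayOrder))
    displayOrder <- s[which.max(trace@logLik), ]
  displayOrder <- checkSequence(displayOrder, Z)
  counts <- matrix(0, Z, Z)   # biomarker x position
  for (p in seq_len(Z)) {
    tab <- tabulate(s[, p], nbins = Z)
    counts[, p] <- tab
  }
  m <- counts[displayOrder, , drop = FALSE] / nrow(s)
  rn <- if (!is.null(biomarkerNames)) biomarkerNames[displayOrder]
        else paste0("event", displayOrder)
  dimnames(m) <- list(rn, paste0("pos", seq_len(Z)))
  new("PositionalVarianceDiagram", matrix = m)
}

#' Heatmap of a positional variance diagram
#'
#' @param pvd a [PositionalVarianceDiagram-class].
#' @param main plot title.
#' @export
plotPVD <- function(pvd, main = "Positional variance diagram") {
  stopifnot(is(pvd, "PositionalVarianceDiagram"))
  m <- pvdMatrix(pvd)
  Z <- nrow(m)
  op <- graphics::par(mar = c(4, 8, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(Z), seq_len(Z), t(m[Z:1, , drop = FALSE]),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  axes = FALSE, xlab = "Sequence position", ylab = "",
                  main = main)
  graphics::axis(1, at = seq_len(Z))
  graphics::axis(2, at = seq_len(Z), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  invisible(pvd)
}
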
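#' @include AllClasses.R AllGenerics.R connectome-io.R
NULL

#' Simulate one trial of the networked drift-diffusion model
#'
#' Evidence y_i accumulates per region as dy_i = [beta_i + lambda y_i -
#' sum_j L_ij y_j] dt + D sqrt(dt) xi_i from y = 0, with L the connectome
#' Laplacian. A region's decision is fixed by its first grid point at or
#' beyond +/- theta (+theta correct, -theta incorrect); by default an
#' absorbed region is clamped at the boundary value and keeps driving its
#' neighbours through L (\code{absorb = "free"} lets it diffuse on while
#' only the first hit is recorded).
#'
#' @param L square Laplacian matrix (rows summing to ~0).
#' @param params a [DDMParams-class].
#' @param seed integer RNG seed.
#' @param absorb \code{"clamp"} (default) or \code{"free"}.
#' @return data.frame with per-region \code{decision} (\code{"correct"},
#'   \code{"incorrect"}, \code{"undecided"}) and \code{decisionTime} (s,
#'   NA if undecided).
#' @export
simulateDDMTrial <- function(L, params = ddmParams(), seed = 1,
                             absorb = c("clamp", "free")) {
  absorb <- match.arg(absorb)
  res <- ddmEnsemble(L, params, nTrials = 1L, seed = seed, absorb = absorb)
  sgn <- res$hit_sign[1, ]
  stp <- res$hit_step[1, ]
  data.frame(
    region = res$labels,
    decision = c("incorrect", "undecided", "correct")[sgn + 2],
    decisionTime = ifelse(stp > 0, stp * params@dt, NA_real_)
  )
}

## internal: run the C++ ensemble with validation
ddmEnsemble <- function(L, params, nTrials, seed, absorb = "clamp") {
  L <- as.matrix(L)
  n <- nrow(L)
  if (ncol(L) != n) stop("L must be square")
  if (max(abs(rowSums(L) )) > 1e-6 * max(1, max(abs(L)))) {
    stop("Laplacian rows must sum to (approximately) zero")
  }
  beta <- rep_len(params@beta, n)
  nsteps <- floor(params@T / params@dt)
  set.seed(seed)
  res <- cpp_ddm_trials(L, beta, params@lam, params@D, params@theta,
                        params@dt, nsteps, as.integer(nTrials),
                        absorb == "clamp")
  labels <- rownames(L)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  c(res, list(labels = labels, nsteps = nsteps))
}

#' Decision-accuracy curves over an ensemble of trials
#'
#' Regional accuracy at time t is the fraction of all trials in which the
#' region's first boundary hit was +theta and occurred at or before t
#' (trials undecided by the horizon count as not-yet-correct). The
#' whole-brain curve is the mean over regions.
#'
#' @param L Laplacian matrix (from [graphLaplacian()]) or a
#'   [Connectome-class].
#' @param params a [DDMParams-class] (nTrials, horizon, boundary, ...).
#' @param seed integer RNG seed.
#' @param absorb \code{"clamp"} or \code{"free"} (see
#'   [simulateDDMTrial()]).
#' @return an [AccuracyCurve-class].
#' @export
accuracyCurves <- function(L, params = ddmParams(), seed = 1,
                           absorb = c("clamp", "free")) {
  absorb <- match.arg(absorb)
  if (is(L, "Connectome")) L <- graphLaplacian(L)
  res <- ddmEnsemble(L, params, nTrials = params@nTrials, seed = seed,
                     absorb = absorb)
  n <- ncol(res$hit_sign)
  nsteps <- res$nsteps
  nT <- params@nTrials
  regional <- matrix(0, nsteps, n)
  for (j in seq_len(n)) {
    correctSteps <- res$hit_step[res$hit_sign[, j] == 1L, j]
    counts <- tabulate(correctSteps, nbins = nsteps)
    regional[, j] <- cumsum(counts) / nT
  }
  colnames(regional) <- res$labels
  new("AccuracyCurve", t = seq_len(nsteps) * params@dt,
      regional = regional, wholeBrain = rowMeans(regional),
      nTrials = as.integer(nT), labels = res$labels)
}

#' Difference between two whole-brain accuracy curves
#'
#' diff(t) = wholeBrain_A(t) - wholeBrain_B(t); tMin is the time at which
#' the difference is most negative (first index on ties) — e.g. the window
#' in which connectome A decides less accurately than connectome B.
#'
#' @param curveA,curveB [AccuracyCurve-class] objects on the same time
#'   grid.
#' @return list with \code{t}, \code{diff}, \code{tMin}, \code{minDiff}.
#' @export
accuracyDifference <- function(curveA, curveB) {
  if (length(curveA@t) != length(curveB@t) ||
      max(abs(curveA@t - curveB@t)) > 1e-9) {
    stop("accuracy curves must share a time grid")
  }
  d <- curveA@wholeBrain - curveB@wholeBrain
  k <- which.min(d)  # first index on ties
  list(t = curveA@t, diff = d, tMin = curveA@t[k], minDiff = d[k])
}

#' Smallest self-coupling matching another connectome's accuracy
#'
#' Sweeps the self-coupling lambda (excitation > 0) for connectome A and
#' returns the smallest grid value whose whole-brain accuracy at the
#' reference time reaches that of connectome B at lambda = 0.
#'
#' @param LA,LB Laplacians (or [Connectome-class] objects).
#' @param params a [DDMParams-class] template.
#' @param lamGrid increasing vector of lambda values to try.
#' @param tRef reference time (s).
#' @param seed integer RNG seed.
#' @return list with \code{lambdaStar} (NA if unattained), \code{achieved}
#'   (best accuracy reached), \code{target} (B's accuracy at tRef) and
#'   \code{sweep} (data.frame lambda, accuracy).
#' @export
matchExcitation <- function(LA, LB, params = ddmParams(), lamGrid,
                            tRef, seed = 1) {
  stopifnot(all(diff(lamGrid) > 0))
  if (is(LA, "Connectome")) LA <- graphLaplacian(LA)
  if (is(LB, "Connectome")) LB <- graphLaplacian(LB)
  accAt <- function(curve) {
    k <- max(1L, findInterval(tRef + 1e-12, curve@t))
    curve@wholeBrain[k]
  }
  ## common random numbers: one seed for the target and every grid point,
  ## so A = B attains the target at lambda = 0 exactly
  target <- accAt(accuracyCurves(LB, initialize(params, lam = 0),
                                 seed = seed))
  accs <- numeric(length(lamGrid))
  for (i in seq_along(lamGrid)) {
    accs[i] <- accAt(accuracyCurves(
      LA, initialize(params, lam = lamGrid[i]), seed = seed))
  }
  hit <- which(accs >= target)
  list(lambdaStar = if (length(hit)) lamGrid[hit[1]] else NA_real_,
       achieved = max(accs), target = target,
       sweep = data.frame(lambda = lamGrid, accuracy = accs))
}

#' Accuracy curve of one network
#'
#' Mean regional accuracy over the regions belonging to the named network.
#'
#' @param curve an [AccuracyCurve-class].
#' @param partition per-region network ids covering all regions.
#' @param networkId the network to extract.
#' @return numeric vector of accuracies on \code{curve@t}.
#' @export
networkAccuracy <- function(curve, partition, networkId) {
  if (length(partition) != ncol(curve@regional)) {
    stop("partition must cover all regions")
  }
  idx <- which(partition == networkId)
  if (!length(idx)) stop("unknown network id: ", networkId)
  rowMeans(curve@regional[, idx, drop = FALSE])
}

#' Closed-form terminal accuracy of a single isolated accumulator
#'
#' For a one-dimensional drift-diffusion process with drift beta, noise SD
#' D and symmetric absorbing boundaries +/- theta started at 0, the
#' probability of absorption at +theta is 1 / (1 + exp(-2 beta theta /
#' D^2)). Used as the independent oracle for the simulated ensemble.
#'
#' @param beta drift rate.
#' @param D noise SD.
#' @param theta boundary.
#' @return probability of a correct decision.
#' @export
ddmAbsorptionProbability <- function(beta = 1, D = 1, theta = 1) {
  1 / (1 + exp(-2 * beta * theta / D^2))
}
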
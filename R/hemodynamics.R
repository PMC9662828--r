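#' @include AllClasses.R AllGenerics.R neural-sim.R
NULL

#' Balloon-Windkessel BOLD signal from a neural trace
#'
#' Integrates, per region, the vasodilatory signal z, blood inflow f,
#' volume v and deoxyhemoglobin content q driven by the neural activity,
#' from resting equilibrium (z = 0, f = v = q = 1), with Euler stepping at
#' the neural dt. The BOLD signal is the algebraic readout
#' Y = V0 [k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)], downsampled to the TR
#' by nearest-sample decimation. Channels are independent (no cross-terms).
#'
#' @param trace a [SimulationTrace-class] of neural activity.
#' @param params a [BWParams-class].
#' @param downsample logical; decimate to \code{params@TR} (default TRUE).
#' @return a [SimulationTrace-class] of BOLD (model \code{"bold"}); the
#'   transient cut is carried over from the input trace.
#' @export
simulateBOLD <- function(trace, params = bwParams(), downsample = TRUE) {
  Y <- cpp_bw_sim(trace@states, trace@dt, params@kappa, params@gamma,
                  params@tau, params@alpha, params@rho, params@V0,
                  params@k1, params@k2, params@k3)
  tGrid <- trace@t
  dtOut <- trace@dt
  if (downsample && params@TR > trace@dt) {
    stride <- max(1L, as.integer(round(params@TR / trace@dt)))
    keep <- seq(1, nrow(Y), by = stride)
    Y <- Y[keep, , drop = FALSE]
    tGrid <- tGrid[keep]
    dtOut <- stride * trace@dt
  }
  colnames(Y) <- colnames(trace@states)
  new("SimulationTrace", t = tGrid, states = Y, dt = dtOut,
      transientCut = trace@transientCut, seed = trace@seed,
      model = "bold")
}

#' Functional connectivity of a BOLD trace
#'
#' Pairwise Pearson correlations between regional time series after
#' removing the transient window. Constant channels yield NA rows/columns
#' (with a warning); the diagonal is 1.
#'
#' @param bold a [SimulationTrace-class] (typically from [simulateBOLD()]).
#' @return symmetric n x n correlation matrix.
#' @export
functionalConnectivity <- function(bold) {
  keep <- bold@t >= bold@transientCut
  X <- bold@states[keep, , drop = FALSE]
  if (nrow(X) < 3) stop("fewer than 3 retained time points")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant channel(s): correlations set to NA")
  }
  FC <- suppressWarnings(stats::cor(X))
  diag(FC) <- 1
  FC
}

#' Within-network mean functional connectivity
#'
#' Mean of the off-diagonal FC entries among the regions of each network,
#' plus the whole-brain mean over all off-diagonal entries.
#'
#' @param FC symmetric correlation matrix.
#' @param partition per-region network ids covering all regions.
#' @return list with \code{network} (named numeric vector of within-network
#'   means; NA with a warning for single-region networks) and
#'   \code{wholeBrain} (scalar).
#' @export
withinNetworkFC <- function(FC, partition) {
  FC <- as.matrix(FC)
  n <- nrow(FC)
  if (length(partition) != n) stop("partition must cover all regions")
  nets <- sort(unique(partition))
  vals <- vapply(nets, function(k) {
    idx <- which(partition == k)
    if (length(idx) < 2) {
      warning("network ", k, " has a single region; within-network FC NA")
      return(NA_real_)
    }
    sub <- FC[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(vals) <- as.character(nets)
  list(network = vals,
       wholeBrain = mean(FC[upper.tri(FC)]))
}

#' Within-network FC as a function of recurrent strength
#'
#' For each w on the grid: simulate the Wong-Wang model, feed the activity
#' through the Balloon-Windkessel model, compute FC after transients, and
#' average it within each network. Returns a tidy table.
#'
#' @param C a [Connectome-class].
#' @param wGrid vector of recurrent strengths.
#' @param partition per-region network ids (defaults to the connectome's).
#' @param params a [WWParams-class] template (w is overridden per grid
#'   point).
#' @param bw a [BWParams-class].
#' @param duration,dt simulation length and step (s).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{network} (including
#'   \code{"whole_brain"}), \code{w}, \code{fc}.
#' @export
fcVsW <- function(C, wGrid, partition = networkPartition(C),
                  params = wwParams(), bw = bwParams(), duration = 720,
                  dt = 0.01, seed = 1) {
  if (is.null(partition)) stop("a network partition is required")
  out <- lapply(seq_along(wGrid), function(k) {
    p <- initialize(params, w = wGrid[k])
    tr <- simulateWW(C, p, duration = duration, dt = dt, seed = seed + k - 1)
    FC <- functionalConnectivity(simulateBOLD(tr, bw))
    wn <- withinNetworkFC(FC, partition)
    data.frame(network = c(names(wn$network), "whole_brain"),
               w = wGrid[k],
               fc = c(unname(wn$network), wn$wholeBrain))
  })
  do.call(rbind, out)
}

#' Algebraic steady state of the Balloon-Windkessel model
#'
#' Under constant neural drive S = c: z = 0, f = 1 + c/gamma, v = f^alpha,
#' q = (f/rho)(1 - (1 - rho)^(1/f)) v^(1 - 1/alpha), and the corresponding
#' BOLD readout. Used as an independent oracle for the integrator.
#'
#' @param c constant drive.
#' @param params a [BWParams-class].
#' @return named vector \code{c(f, v, q, Y)}.
#' @export
bwSteadyState <- function(c, params = bwParams()) {
  f <- 1 + c / params@gamma
  v <- f^params@alpha
  q <- (f / params@rho) * (1 - (1 - params@rho)^(1 / f)) *
    v^(1 - 1 / params@alpha)
  Y <- params@V0 * (params@k1 * (1 - q) + params@k2 * (1 - q / v) +
                    params@k3 * (1 - v))
  c(f = f, v = v, q = q, Y = Y)
}
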
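#' @include AllClasses.R AllGenerics.R connectome-io.R
NULL

#' Firing-rate input-output function
#'
#' H(x) = (a x - b) / (1 - exp(-d (a x - b))), the sigmoidal transfer
#' function of the reduced Wong-Wang model; continuous at a x = b where it
#' takes the value 1/d, and asymptotically linear (a x - b) for large input.
#'
#' @param x total input current (nA); vectorized.
#' @param params a [WWParams-class] (defaults used when omitted).
#' @return firing rate in Hz (nonnegative).
#' @examples
#' firingRate(109 / 270)  # the removable singularity: 1 / 0.154
#' @export
firingRate <- function(x, params = wwParams()) {
  vapply(x, cpp_firing_rate, numeric(1),
         a = params@a, b = params@b, d = params@d)
}

## internal: resolve per-region input vector (heterogeneous input replaces I0)
resolveInputs <- function(C, params, iRegional) {
  n <- nRegions(C)
  if (is.null(iRegional)) return(rep(params@I0, n))
  v <- mapValues(iRegional)
  if (length(v) != n) stop("regional input map length must match regions")
  as.numeric(v)
}

## internal: per-pair delays (seconds) rounded to integration steps
delayStepsMatrix <- function(C, delays, dt) {
  n <- nRegions(C)
  if (is.null(delays)) return(matrix(0L, n, n))
  dmat <- delays@delays
  if (!all(dim(dmat) == n)) stop("delay matrix must match region count")
  matrix(as.integer(round(dmat / dt)), n, n)
}

#' Simulate the reduced Wong-Wang model on a connectome
#'
#' Euler-Maruyama integration of the dynamic mean-field equations: per
#' region, dS = [-S/tauS + gammaS (1 - S) H(x)] dt + D sqrt(dt) xi, with
#' total input x_i = w J S_i + G J sum_j A_ij S_j + I0 (the coupling term
#' uses delayed activity S_j(t - delay_ij) when a [DelaySpec-class] is
#' given, and I0 is replaced by a per-region map when supplied). S is
#' clamped to [0, 1] after each step.
#'
#' @param C a [Connectome-class].
#' @param params a [WWParams-class]; \code{params@w} is the recurrent
#'   strength used.
#' @param duration simulated time (s), default 720.
#' @param dt time step (s), default 0.01.
#' @param seed integer RNG seed.
#' @param delays optional [DelaySpec-class] from [computeDelays()].
#' @param iRegional optional [RegionalMap-class] of per-region inputs (nA)
#'   replacing \code{I0}, e.g. from [heterogeneousInputs()].
#' @param S0 initial condition (scalar or per-region), default 0.001.
#' @param transientFrac fraction of the interval treated as transient in
#'   downstream averages (default 0.2).
#' @return a [SimulationTrace-class] of S.
#' @export
simulateWW <- function(C, params = wwParams(), duration = 720, dt = 0.01,
                       seed = 1, delays = NULL, iRegional = NULL,
                       S0 = 0.001, transientFrac = 0.2) {
  stopifnot(dt > 0, duration > dt)
  n <- nRegions(C)
  nsteps <- floor(duration / dt)
  I0 <- resolveInputs(C, params, iRegional)
  dsteps <- delayStepsMatrix(C, delays, dt)
  S0 <- rep_len(S0, n)
  set.seed(seed)
  states <- cpp_ww_sim(weights(C), params@w, params@J, params@G, I0,
                       params@tauS, params@gammaS, params@D, params@a,
                       params@b, params@d, dt, nsteps, S0, dsteps)
  colnames(states) <- regionLabels(C)
  new("SimulationTrace", t = seq(0, by = dt, length.out = nsteps + 1),
      states = states, dt = dt, transientCut = transientFrac * duration,
      seed = as.integer(seed), model = "wong_wang")
}

#' Excitability response functions from a recurrent-strength sweep
#'
#' For each w on the grid, integrates the Wong-Wang model (or the
#' Wilson-Cowan model over its wEE grid) and records each region's
#' time-averaged activity after discarding the transient window. The
#' resulting S-bar versus w curves are the response functions whose shape
#' the dynamic-range statistic summarizes.
#'
#' @param C a [Connectome-class].
#' @param params a [WWParams-class] or [WCParams-class]; selects the model.
#' @param wGrid strictly increasing sweep grid. Defaults: 0..1 step 0.01
#'   for Wong-Wang (recurrent strength w), 0..20 step 0.2 for Wilson-Cowan
#'   (wEE).
#' @param duration,dt simulation length and step (s); Wong-Wang defaults
#'   720 and 0.01, Wilson-Cowan 15 and 0.001.
#' @param seed integer RNG seed.
#' @param iRegional optional per-region input map (Wong-Wang only).
#' @param transientFrac fraction discarded as transient (default 0.2).
#' @param S0 initial condition.
#' @return a [ResponseFunction-class].
#' @export
responseFunction <- function(C, params = wwParams(), wGrid = NULL,
                             duration = NULL, dt = NULL, seed = 1,
                             iRegional = NULL, transientFrac = 0.2,
                             S0 = NULL) {
  if (is(params, "WWParams")) {
    if (is.null(wGrid)) wGrid <- seq(0, 1, by = 0.01)
    if (is.null(duration)) duration <- 720
    if (is.null(dt)) dt <- 0.01
    if (is.null(S0)) S0 <- 0.001
    stopifnot(all(diff(wGrid) > 0))
    nsteps <- floor(duration / dt)
    ntrans <- floor(transientFrac * nsteps)
    I0 <- resolveInputs(C, params, iRegional)
    set.seed(seed)
    sbar <- cpp_ww_sweep(weights(C), wGrid, params@J, params@G, I0,
                         params@tauS, params@gammaS, params@D, params@a,
                         params@b, params@d, dt, nsteps, ntrans,
                         rep_len(S0, nRegions(C)))
    model <- "wong_wang"
  } else if (is(params, "WCParams")) {
    if (is.null(wGrid)) wGrid <- seq(0, 20, by = 0.2)
    if (is.null(duration)) duration <- 15
    if (is.null(dt)) dt <- 0.001
    if (is.null(S0)) S0 <- 0.1
    stopifnot(all(diff(wGrid) > 0))
    nsteps <- floor(duration / dt)
    ntrans <- floor(transientFrac * nsteps)
    set.seed(seed)
    sbar <- cpp_wc_sweep(weights(C), wGrid, params@wEI, params@wIE,
                         params@wII, params@G, params@GE, params@PE,
                         params@tauE, params@tauI, params@DE, params@DI,
                         params@aE, params@aI, params@muE, params@muI,
                         dt, nsteps, ntrans, S0, S0)
    model <- "wilson_cowan"
  } else {
    stop("params must be WWParams or WCParams")
  }
  sbar <- pmin(pmax(sbar, 0), 1)
  dim(sbar) <- c(nRegions(C), length(wGrid))
  new("ResponseFunction", wGrid = as.numeric(wGrid), sBar = sbar,
      model = model, regionLabels = regionLabels(C))
}

#' Strength-ranked heterogeneous excitatory inputs
#'
#' Assigns each region an input I_i = Imax - (Imax - Imin)
#' (rank(s_i) - 1)/(N - 1), where s_i is the region's total connection
#' strength (ascending ranks, ties averaged): the weakest-strength region
#' receives Imax and the strongest Imin, mimicking a decreasing excitatory
#' drive along the cortical hierarchy.
#'
#' @param C a [Connectome-class].
#' @param iMax,iMin input bounds in nA (defaults 0.33 and 0.28).
#' @return a [RegionalMap-class] of inputs (nA).
#' @export
heterogeneousInputs <- function(C, iMax = 0.33, iMin = 0.28) {
  stopifnot(iMax >= iMin)
  s <- nodeStrengths(C)
  n <- length(s)
  r <- rank(s, ties.method = "average")
  inputs <- if (n == 1) rep(iMax, 1) else iMax - (iMax - iMin) * (r - 1) / (n - 1)
  RegionalMap(inputs, labels = regionLabels(C), name = "excitatory_input",
              units = "nA")
}

#' Simulate the Wilson-Cowan model on a connectome
#'
#' Euler-Maruyama integration of coupled excitatory/inhibitory populations
#' with sigmoidal activation; the noise term sits inside the 1/tau bracket,
#' so its increment is (D/tau) sqrt(dt) xi. States are clamped to [0, 1].
#'
#' @param C a [Connectome-class].
#' @param params a [WCParams-class].
#' @param duration simulated time (s), default 15.
#' @param dt time step (s), default 0.001.
#' @param seed integer RNG seed.
#' @param SE0,SI0 initial conditions (default 0.1).
#' @param transientFrac transient fraction for downstream averages.
#' @return a [SimulationTrace-class]; \code{states} holds the excitatory
#'   trace, \code{extra$SI} the inhibitory one.
#' @export
simulateWC <- function(C, params = wcParams(), duration = 15, dt = 0.001,
                       seed = 1, SE0 = 0.1, SI0 = 0.1,
                       transientFrac = 0.2) {
  stopifnot(dt > 0, duration > dt)
  nsteps <- floor(duration / dt)
  set.seed(seed)
  res <- cpp_wc_sim(weights(C), params@wEE, params@wEI, params@wIE,
                    params@wII, params@G, params@GE, params@PE,
                    params@tauE, params@tauI, params@DE, params@DI,
                    params@aE, params@aI, params@muE, params@muI,
                    dt, nsteps, SE0, SI0)
  colnames(res$SE) <- regionLabels(C)
  new("SimulationTrace", t = seq(0, by = dt, length.out = nsteps + 1),
      states = res$SE, dt = dt, transientCut = transientFrac * duration,
      seed = as.integer(seed), model = "wilson_cowan",
      extra = list(SI = res$SI))
}

#' Inter-regional conduction delays from centroids
#'
#' Delays are pairwise Euclidean centroid distances (mm) divided by a
#' constant propagation speed v (m/s): delay_ij = D_ij / v.
#'
#' @param centroids n x 3 matrix of region centroids in mm (or a
#'   [Connectome-class] carrying centroids).
#' @param speed propagation speed in m/s (default 10).
#' @return a [DelaySpec-class] with distances (mm) and delays (s).
#' @examples
#' computeDelays(rbind(c(0, 0, 0), c(10, 0, 0)))  # 10 mm at 10 m/s = 1 ms
#' @export
computeDelays <- function(centroids, speed = 10) {
  if (is(centroids, "Connectome")) {
    cc <- centroids(centroids)
    if (is.null(cc)) stop("connectome carries no centroids")
    centroids <- cc
  }
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stop("need at least two centroids")
  if (speed <= 0) stop("speed must be positive")
  d <- as.matrix(stats::dist(centroids))  # mm
  delays <- (d / 1000) / speed            # mm -> m, then /(m/s) = s
  new("DelaySpec", distances = unname(d), speed = speed,
      delays = unname(delays))
}

#' Deterministic steady state of an isolated Wong-Wang region
#'
#' Root of -S/tauS + gammaS (1 - S) H(w J S + I0) = 0 on [0, 1], found by
#' bisection; an independent check for the noiseless uncoupled simulation.
#'
#' @param params a [WWParams-class]; \code{params@w} is used.
#' @param I0 input current (defaults to \code{params@I0}).
#' @return the steady-state S in [0, 1] nearest the low branch.
#' @export
wwFixedPoint <- function(params = wwParams(), I0 = params@I0) {
  f <- function(S) {
    x <- params@w * params@J * S + I0
    -S / params@tauS + params@gammaS * (1 - S) * firingRate(x, params)
  }
  ## the low branch is the first sign change scanning up from 0
  grid <- seq(0, 1, by = 1e-3)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)[1]
  if (is.na(flip)) stop("no steady state found on [0, 1]")
  stats::uniroot(f, c(grid[flip], grid[flip + 1]), tol = 1e-12)$root
}

#' Deterministic fixed point of an isolated Wilson-Cowan region
#'
#' Solves the two-dimensional steady state of the excitatory/inhibitory
#' pair (no coupling, no noise) by damped fixed-point iteration followed by
#' Newton polishing; an independent check for the noiseless simulation.
#'
#' @param params a [WCParams-class].
#' @return named vector \code{c(SE, SI)}.
#' @export
wcFixedPoint <- function(params = wcParams()) {
  sig <- function(x, a, mu) 1 / (1 + exp(-a * (x - mu)))
  F <- function(s) {
    xE <- params@wEE * s[1] - params@wEI * s[2] + params@GE * params@PE
    xI <- params@wIE * s[1] - params@wII * s[2]
    c(-s[1] + (1 - s[1]) * sig(xE, params@aE, params@muE),
      -s[2] + (1 - s[2]) * sig(xI, params@aI, params@muI))
  }
  s <- c(0.1, 0.1)
  for (k in 1:5000) {
    step <- F(s)
    s2 <- pmin(pmax(s + 0.2 * step, 0), 1)
    if (max(abs(s2 - s)) < 1e-14) { s <- s2; break }
    s <- s2
  }
  ## Newton polish with numerical Jacobian
  for (k in 1:50) {
    f0 <- F(s)
    if (max(abs(f0)) < 1e-13) break
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      sp <- s; sp[j] <- sp[j] + h
      J[, j] <- (F(sp) - f0) / h
    }
    s <- s - solve(J, f0)
  }
  stats::setNames(pmin(pmax(s, 0), 1), c("SE", "SI"))
}
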
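#' @useDynLib conndyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Connectome: a weighted region-by-region structural network
#'
#' Central container of the package. Holds a nonnegative weighted adjacency
#' matrix with zero diagonal, region labels, hemisphere labels, an optional
#' network partition (e.g. seven canonical resting-state networks) and
#' optional region centroid coordinates in millimetres.
#'
#' @slot weights n x n nonnegative numeric matrix, zero diagonal; symmetric
#'   unless \code{directed} is \code{TRUE}.
#' @slot regionLabels character vector of region names (length n).
#' @slot hemisphere character vector, per-region hemisphere in \code{"L"},
#'   \code{"R"} (or \code{NA} when unknown).
#' @slot partition integer vector of network/module ids (or length 0).
#' @slot centroids numeric n x 3 matrix of region centroids in mm
#'   (or 0 x 3 when absent).
#' @slot directed logical flag; when \code{FALSE} the matrix must be symmetric.
#'
#' @seealso [Connectome()], [syntheticConnectome()], [readConnectome()]
#' @exportClass Connectome
setClass("Connectome",
  representation(
    weights = "matrix",
    regionLabels = "character",
    hemisphere = "character",
    partition = "integer",
    centroids = "matrix",
    directed = "logical"
  ),
  prototype(
    weights = matrix(numeric(0), 0, 0),
    regionLabels = character(0),
    hemisphere = character(0),
    partition = integer(0),
    centroids = matrix(numeric(0), 0, 3),
    directed = FALSE
  )
)

setValidity("Connectome", function(object) {
  w <- object@weights
  msg <- character(0)
  if (nrow(w) != ncol(w)) {
    msg <- c(msg, "weights must be a square matrix")
  }
  n <- nrow(w)
  if (anyNA(w)) {
    bad <- which(is.na(w), arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("NA/NaN weight at row %d, column %d",
                          bad[1], bad[2]))
  } else {
    if (any(w < 0)) msg <- c(msg, "all weights must be nonnegative")
    if (n > 0 && any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
    if (length(object@directed) != 1) {
      msg <- c(msg, "directed must be a single logical")
    } else if (!object@directed && n > 0 &&
               max(abs(w - t(w))) > 1e-10 * max(1, max(abs(w)))) {
      msg <- c(msg, "undirected connectome must have a symmetric matrix")
    }
  }
  if (length(object@regionLabels) != n) {
    msg <- c(msg, "regionLabels length must equal number of regions")
  }
  if (length(object@hemisphere) != n) {
    msg <- c(msg, "hemisphere length must equal number of regions")
  }
  if (length(object@partition) && length(object@partition) != n) {
    msg <- c(msg, "partition must be empty or one id per region")
  }
  if (nrow(object@centroids) && (nrow(object@centroids) != n ||
                                 ncol(object@centroids) != 3)) {
    msg <- c(msg, "centroids must be empty or an n x 3 matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Connectome
#'
#' @param weights square nonnegative numeric matrix with zero diagonal.
#' @param regionLabels region names; defaults to \code{R1..Rn}.
#' @param hemisphere per-region \code{"L"}/\code{"R"} labels; defaults to
#'   \code{NA}.
#' @param partition optional per-region network ids (coerced to integer).
#' @param centroids optional n x 3 matrix of centroids (mm).
#' @param directed logical; set \code{TRUE} to accept an asymmetric matrix.
#' @return A [Connectome-class] object.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' Connectome(w)
#' @export
Connectome <- function(weights, regionLabels = NULL, hemisphere = NULL,
                       partition = NULL, centroids = NULL, directed = FALSE) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (is.null(regionLabels)) {
    regionLabels <- if (!is.null(rownames(weights))) rownames(weights)
                    else paste0("R", seq_len(n))
  }
  if (is.null(hemisphere)) hemisphere <- rep(NA_character_, n)
  if (is.null(partition)) partition <- integer(0)
  if (is.null(centroids)) centroids <- matrix(numeric(0), 0, 3)
  dimnames(weights) <- list(regionLabels, regionLabels)
  new("Connectome",
      weights = weights,
      regionLabels = as.character(regionLabels),
      hemisphere = as.character(hemisphere),
      partition = as.integer(partition),
      centroids = as.matrix(centroids),
      directed = isTRUE(directed))
}

#' EdgeClassification: shared and species-specific connections
#'
#' Result of comparing two connectomes on the same parcellation: edges present
#' in both (with paired weights), edges specific to each, and the fraction of
#' each specific set whose endpoints lie in the same hemisphere.
#'
#' @slot shared data.frame with columns \code{from}, \code{to}, \code{w1},
#'   \code{w2} for edges present in both connectomes.
#' @slot specific1,specific2 data.frames (\code{from}, \code{to}, \code{w})
#'   for edges present only in the first / second connectome.
#' @slot intraFrac1,intraFrac2 fraction of specific edges that are
#'   intrahemispheric (\code{NA} when hemisphere labels are absent).
#' @exportClass EdgeClassification
setClass("EdgeClassification",
  representation(
    shared = "data.frame",
    specific1 = "data.frame",
    specific2 = "data.frame",
    intraFrac1 = "numeric",
    intraFrac2 = "numeric"
  )
)

#' RegionalMap: one scalar value per brain region
#'
#' @slot values numeric vector, one entry per region.
#' @slot labels character region names.
#' @slot name metric identifier (e.g. "dynamic_range").
#' @slot units free-text units.
#' @exportClass RegionalMap
setClass("RegionalMap",
  representation(
    values = "numeric",
    labels = "character",
    name = "character",
    units = "character"
  ),
  prototype(name = "map", units = "")
)

setValidity("RegionalMap", function(object) {
  if (length(object@values) != length(object@labels)) {
    "values and labels must have equal length"
  } else TRUE
})

#' Construct a RegionalMap
#'
#' @param values per-region numeric values.
#' @param labels region names; default \code{R1..Rn}.
#' @param name metric identifier.
#' @param units free text.
#' @return A [RegionalMap-class].
#' @export
RegionalMap <- function(values, labels = NULL, name = "map", units = "") {
  if (is.null(labels)) {
    labels <- if (!is.null(names(values))) names(values)
              else paste0("R", seq_along(values))
  }
  new("RegionalMap", values = as.numeric(values),
      labels = as.character(labels), name = name, units = units)
}

#' SimulationTrace: a time-by-region state matrix
#'
#' Container for trajectories produced by any of the dynamical models
#' (synaptic gating S, Wilson-Cowan excitatory rate, BOLD signal Y, ...).
#'
#' @slot t numeric time grid in seconds (uniform).
#' @slot states numeric time x region matrix; for the Wilson-Cowan model the
#'   excitatory population (the inhibitory trace travels in \code{extra}).
#' @slot dt time step in seconds.
#' @slot transientCut seconds of initial transient to discard in averages.
#' @slot seed integer seed used for the simulation (NA if deterministic).
#' @slot model model identifier string.
#' @slot extra list of auxiliary traces (e.g. \code{SI}).
#' @exportClass SimulationTrace
setClass("SimulationTrace",
  representation(
    t = "numeric",
    states = "matrix",
    dt = "numeric",
    transientCut = "numeric",
    seed = "integer",
    model = "character",
    extra = "list"
  ),
  prototype(transientCut = 0, seed = NA_integer_, model = "generic",
            extra = list())
)

setValidity("SimulationTrace", function(object) {
  msg <- character(0)
  if (length(object@t) != nrow(object@states)) {
    msg <- c(msg, "time grid length must match rows of states")
  }
  if (length(object@t) > 1) {
    dts <- diff(object@t)
    if (max(abs(dts - dts[1])) > 1e-8 * max(dts[1], 1e-12)) {
      msg <- c(msg, "time grid must be uniform")
    }
  }
  if (!all(is.finite(object@states))) {
    msg <- c(msg, "states must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' ResponseFunction: time-averaged activity across an excitability sweep
#'
#' Per-region mean activity (synaptic gating for the Wong-Wang model,
#' excitatory rate for the Wilson-Cowan model) as a function of the global
#' recurrent strength being swept.
#'
#' @slot wGrid strictly increasing vector of recurrent strengths.
#' @slot sBar region x w matrix of time-averaged activity in [0, 1].
#' @slot model \code{"wong_wang"} or \code{"wilson_cowan"}.
#' @slot regionLabels character region names.
#' @exportClass ResponseFunction
setClass("ResponseFunction",
  representation(
    wGrid = "numeric",
    sBar = "matrix",
    model = "character",
    regionLabels = "character"
  )
)

setValidity("ResponseFunction", function(object) {
  msg <- character(0)
  if (any(diff(object@wGrid) <= 0)) {
    msg <- c(msg, "wGrid must be strictly increasing")
  }
  if (ncol(object@sBar) != length(object@wGrid)) {
    msg <- c(msg, "sBar must have one column per grid point")
  }
  if (nrow(object@sBar) != length(object@regionLabels)) {
    msg <- c(msg, "sBar must have one row per region label")
  }
  if (length(object@sBar) &&
      (min(object@sBar) < -1e-9 || max(object@sBar) > 1 + 1e-9)) {
    msg <- c(msg, "sBar entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' DynamicRangeProfile: regional dynamic ranges and their distribution
#'
#' @slot dr per-region dynamic range, 10*log10(w90/w10) (NA where undefined).
#' @slot w10,w90 recurrent strengths at 10%/90% of the response span.
#' @slot sigma standard deviation of the dynamic-range distribution over
#'   regions with a defined value.
#' @slot zscores z-transformed dynamic ranges (NA where undefined).
#' @slot labels region names.
#' @slot nDefined number of regions with a defined dynamic range.
#' @exportClass DynamicRangeProfile
setClass("DynamicRangeProfile",
  representation(
    dr = "numeric",
    w10 = "numeric",
    w90 = "numeric",
    sigma = "numeric",
    zscores = "numeric",
    labels = "character",
    nDefined = "integer"
  )
)

#' AccuracyCurve: probability of a correct decision as a function of time
#'
#' Produced by the networked drift-diffusion model: for each region, the
#' fraction of trials in which the region's first boundary hit was the
#' correct boundary at or before time t.
#'
#' @slot t time grid (seconds).
#' @slot regional time x region matrix of accuracies in [0, 1], nondecreasing
#'   in time.
#' @slot wholeBrain mean regional accuracy at each time.
#' @slot nTrials ensemble size.
#' @slot labels region names.
#' @exportClass AccuracyCurve
setClass("AccuracyCurve",
  representation(
    t = "numeric",
    regional = "matrix",
    wholeBrain = "numeric",
    nTrials = "integer",
    labels = "character"
  )
)

setValidity("AccuracyCurve", function(object) {
  msg <- character(0)
  if (nrow(object@regional) != length(object@t)) {
    msg <- c(msg, "regional must have one row per time point")
  }
  if (length(object@wholeBrain) != length(object@t)) {
    msg <- c(msg, "wholeBrain must have one value per time point")
  }
  if (length(object@regional) &&
      (min(object@regional) < 0 || max(object@regional) > 1)) {
    msg <- c(msg, "accuracies must lie in [0, 1]")
  }
  if (ncol(object@regional) > 0 &&
      any(apply(object@regional, 2, function(x) any(diff(x) < -1e-12)))) {
    msg <- c(msg, "regional accuracy curves must be nondecreasing")
  }
  if (length(msg)) msg else TRUE
})

## ---- parameter classes -----------------------------------------------------

#' Parameters of the reduced Wong-Wang (dynamic mean-field) model
#'
#' Defaults are the standard dynamic mean-field values: synaptic time constant
#' tauS = 0.1 s, saturation rate gammaS = 0.641, noise SD D = 0.003, firing
#' rate function constants a = 270 (V nC)^-1, b = 109 Hz, d = 0.154 s,
#' synaptic coupling J = 0.2609 nA, global scaling G = 0.2, background
#' input I0 = 0.33 nA. See the
#' documentation of [firingRate()] and [simulateWW()] for the role of each.
#' The global scaling constant G is held fixed across species so that
#' dynamics are directly comparable.
#'
#' @slot tauS synaptic time constant (s), 0.1.
#' @slot gammaS saturation rate (dimensionless), 0.641.
#' @slot D noise standard deviation, 0.003.
#' @slot a input-output gain, 270 (V nC)^-1.
#' @slot b input-output threshold, 109 Hz.
#' @slot d input-output curvature, 0.154 s.
#' @slot J synaptic coupling, 0.2609 nA.
#' @slot G global scaling constant, 0.2.
#' @slot I0 excitatory subcortical input, 0.33 nA.
#' @slot w global recurrent strength (the quantity swept), default 0.45.
#' @exportClass WWParams
setClass("WWParams",
  representation(tauS = "numeric", gammaS = "numeric", D = "numeric",
                 a = "numeric", b = "numeric", d = "numeric", J = "numeric",
                 G = "numeric", I0 = "numeric", w = "numeric"),
  prototype(tauS = 0.1, gammaS = 0.641, D = 0.003, a = 270, b = 109,
            d = 0.154, J = 0.2609, G = 0.2, I0 = 0.33, w = 0.45)
)

setValidity("WWParams", function(object) {
  vals <- c(object@tauS, object@gammaS, object@a, object@b, object@d,
            object@J, object@I0)
  if (any(vals <= 0) || object@D < 0 || object@G < 0 || object@w < 0) {
    "model constants must be positive (D, G, w nonnegative)"
  } else TRUE
})

#' @rdname WWParams-class
#' @param ... named slot overrides, e.g. \code{wwParams(w = 0.6, G = 0)}.
#' @return A \code{WWParams} object.
#' @export
wwParams <- function(...) new("WWParams", ...)

#' Parameters of the Wilson-Cowan excitatory-inhibitory model
#'
#' Defaults: tauE = 2.5e-3 s, tauI = 3.75e-3 s, sigmoid gains aE = aI = 1.5,
#' thresholds muE = muI = 3, couplings wEE = 16 (the swept quantity),
#' wEI = 12, wIE = 15, wII = 3, global scaling G = 2, excitatory drive
#' PE = 1 scaled by GE = 0.5, noise SDs DE = DI = 5e-5.
#'
#' @slot tauE,tauI population time constants (s).
#' @slot DE,DI noise standard deviations.
#' @slot aE,aI sigmoid gains.
#' @slot muE,muI sigmoid thresholds.
#' @slot wEE,wEI,wIE,wII population coupling strengths.
#' @slot G global scaling constant.
#' @slot PE excitatory drive.
#' @slot GE drive scaling.
#' @exportClass WCParams
setClass("WCParams",
  representation(tauE = "numeric", tauI = "numeric", DE = "numeric",
                 DI = "numeric", aE = "numeric", aI = "numeric",
                 muE = "numeric", muI = "numeric", wEE = "numeric",
                 wEI = "numeric", wIE = "numeric", wII = "numeric",
                 G = "numeric", PE = "numeric", GE = "numeric"),
  prototype(tauE = 2.5e-3, tauI = 3.75e-3, DE = 5e-5, DI = 5e-5,
            aE = 1.5, aI = 1.5, muE = 3, muI = 3, wEE = 16, wEI = 12,
            wIE = 15, wII = 3, G = 2, PE = 1, GE = 0.5)
)

setValidity("WCParams", function(object) {
  if (object@tauE <= 0 || object@tauI <= 0 || object@DE < 0 ||
      object@DI < 0) "time constants must be positive, noise nonnegative"
  else TRUE
})

#' @rdname WCParams-class
#' @param ... named slot overrides.
#' @return A \code{WCParams} object.
#' @export
wcParams <- function(...) new("WCParams", ...)

#' Parameters of the Balloon-Windkessel haemodynamic model
#'
#' Defaults: signal decay kappa = 0.65 s^-1, elimination rate gamma =
#' 0.41 s^-1, transit time tau = 0.98 s, Grubb's exponent alpha = 0.32,
#' resting oxygen extraction rho = 0.34, resting blood volume V0 = 0.02,
#' BOLD constants k1 = 4.10, k2 = 0.58, k3 = 0.53, output resolution
#' TR = 0.72 s.
#'
#' @slot kappa vasodilatory signal decay rate (1/s).
#' @slot gamma flow elimination rate (1/s).
#' @slot tau haemodynamic transit time (s).
#' @slot alpha Grubb's exponent, in (0, 1).
#' @slot rho resting oxygen extraction fraction, in (0, 1).
#' @slot V0 resting blood volume fraction.
#' @slot k1,k2,k3 BOLD signal constants.
#' @slot TR output sampling interval (s).
#' @exportClass BWParams
setClass("BWParams",
  representation(kappa = "numeric", gamma = "numeric", tau = "numeric",
                 alpha = "numeric", rho = "numeric", V0 = "numeric",
                 k1 = "numeric", k2 = "numeric", k3 = "numeric",
                 TR = "numeric"),
  prototype(kappa = 0.65, gamma = 0.41, tau = 0.98, alpha = 0.32,
            rho = 0.34, V0 = 0.02, k1 = 4.10, k2 = 0.58, k3 = 0.53,
            TR = 0.72)
)

setValidity("BWParams", function(object) {
  msg <- character(0)
  if (any(c(object@kappa, object@gamma, object@tau, object@V0, object@k1,
            object@k2, object@k3, object@TR) <= 0)) {
    msg <- c(msg, "all parameters must be positive")
  }
  if (object@alpha <= 0 || object@alpha >= 1) {
    msg <- c(msg, "alpha must lie in (0, 1)")
  }
  if (object@rho <= 0 || object@rho >= 1) {
    msg <- c(msg, "rho must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname BWParams-class
#' @param ... named slot overrides.
#' @return A \code{BWParams} object.
#' @export
bwParams <- function(...) new("BWParams", ...)

#' Parameters of the networked drift-diffusion decision model
#'
#' Defaults: unit drift rate beta = 1 for every region, self-coupling
#' lambda = 0, noise SD D = 1, decision boundary theta = 1 (the +theta
#' boundary is the correct decision), time step dt = 0.01 s, horizon
#' T = 5 s, ensemble of nTrials = 1000 trials.
#'
#' @slot beta drift rate (scalar, recycled per region, or vector).
#' @slot lam self-coupling lambda (excitation > 0, inhibition < 0).
#' @slot D noise standard deviation.
#' @slot theta absorbing boundary (+theta correct, -theta incorrect).
#' @slot dt integration step (s).
#' @slot T simulation horizon (s).
#' @slot nTrials ensemble size.
#' @exportClass DDMParams
setClass("DDMParams",
  representation(beta = "numeric", lam = "numeric", D = "numeric",
                 theta = "numeric", dt = "numeric", T = "numeric",
                 nTrials = "integer"),
  prototype(beta = 1, lam = 0, D = 1, theta = 1, dt = 0.01, T = 5,
            nTrials = 1000L)
)

setValidity("DDMParams", function(object) {
  msg <- character(0)
  if (object@theta <= 0) msg <- c(msg, "theta must be positive")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@T <= 0) msg <- c(msg, "T must be positive")
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be >= 1")
  if (object@D < 0) msg <- c(msg, "D must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @rdname DDMParams-class
#' @param ... named slot overrides; \code{nTrials} is coerced to integer.
#' @return A \code{DDMParams} object.
#' @export
ddmParams <- function(...) {
  args <- list(...)
  if (!is.null(args$nTrials)) args$nTrials <- as.integer(args$nTrials)
  do.call(new, c(list("DDMParams"), args))
}

#' DelaySpec: inter-regional conduction delays
#'
#' Delays are Euclidean centroid distances divided by a constant propagation
#' speed (default 10 m/s).
#'
#' @slot distances symmetric matrix of pairwise distances (mm), zero diagonal.
#' @slot speed propagation speed (m/s).
#' @slot delays matrix of delays in seconds (distances / speed, mm to m).
#' @exportClass DelaySpec
setClass("DelaySpec",
  representation(distances = "matrix", speed = "numeric", delays = "matrix")
)

setValidity("DelaySpec", function(object) {
  msg <- character(0)
  d <- object@distances
  if (nrow(d) != ncol(d)) msg <- c(msg, "distances must be square")
  else {
    if (any(abs(d - t(d)) > 1e-9)) msg <- c(msg, "distances must be symmetric")
    if (any(diag(d) != 0)) msg <- c(msg, "distance diagonal must be zero")
  }
  if (object@speed <= 0) msg <- c(msg, "speed must be positive")
  if (length(msg)) msg else TRUE
})
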
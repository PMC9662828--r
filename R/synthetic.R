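#' @include AllClasses.R connectome-io.R
NULL

#' Generate a synthetic brain-like connectome
#'
#' Draws a weighted undirected network with the statistical structure the
#' downstream analyses assume: a stochastic block model with
#' \code{nModules} modules replicated across two hemispheric blocks,
#' log-normal (heavy-tailed) edge weights, max-normalization, and an
#' optional monotone anterior-posterior gradient of regional strength.
#' Region centroids are placed on two parallel anterior-posterior rows
#' (left/right hemisphere) so distance/delay and gradient-association
#' analyses are possible.
#'
#' Edges are sampled without replacement with probability proportional to a
#' block affinity (higher within module and within hemisphere), so the
#' realized edge count is exactly \code{round(density * n(n-1)/2)}. If the
#' sampled graph is disconnected, it is resampled up to \code{maxTries}
#' times; as a last resort components are joined by minimum-weight bridging
#' edges (and the globally weakest dispensable edges are removed to keep
#' the edge count).
#'
#' The gradient multiplies the weight of edge (i, j) by
#' \code{sqrt(g_i g_j)} with \code{g_i = exp(gradientStrength * (x_i - 1/2))}
#' and \code{x_i} the normalized anterior-posterior position, producing a
#' monotone scaling of expected regional strength along the axis;
#' \code{gradientStrength = 0} leaves strengths exchangeable.
#'
#' @param nRegions number of regions (default 114).
#' @param density target edge density in (0, 1] (default 0.13).
#' @param nModules number of modules per hemisphere-pair (default 7).
#' @param hemispheres logical; impose a 2-block hemispheric structure.
#' @param gradientStrength nonnegative scaling of the anterior-posterior
#'   strength gradient (0 = none).
#' @param weightDispersion log-normal sigma of edge weights (default 1).
#' @param seed integer RNG seed.
#' @param maxTries resampling attempts before bridging repair (default 100).
#' @return a connected, max-normalized [Connectome-class] with module
#'   partition, hemisphere labels and centroids attached.
#' @examples
#' C <- syntheticConnectome(nRegions = 30, density = 0.2, seed = 1)
#' edgeDensity(C)
#' @export
syntheticConnectome <- function(nRegions = 114, density = 0.13,
                                nModules = 7, hemispheres = TRUE,
                                gradientStrength = 0,
                                weightDispersion = 1, seed = 1,
                                maxTries = 100) {
  stopifnot(nRegions >= 2, density > 0, density <= 1,
            gradientStrength >= 0, weightDispersion >= 0, nModules >= 1)
  n <- as.integer(nRegions)
  nPairs <- n * (n - 1) / 2
  m <- max(1L, as.integer(round(density * nPairs)))
  if (m < n - 1 && density < 1) {
    stop(sprintf(
      "unsatisfiable: %d edges cannot connect %d regions (need >= %d)",
      m, n, n - 1))
  }
  set.seed(seed)

  geo <- syntheticGeometry(n, hemispheres, nModules)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  aff <- rep(1, nrow(ut))
  sameMod <- geo$module[ut[, 1]] == geo$module[ut[, 2]]
  sameHem <- geo$hemi[ut[, 1]] == geo$hemi[ut[, 2]]
  aff[sameMod] <- aff[sameMod] * 4
  if (hemispheres) aff[sameHem] <- aff[sameHem] * 2

  w <- NULL
  for (try in seq_len(maxTries)) {
    sel <- sample.int(nrow(ut), m, prob = aff)
    wTry <- matrix(0, n, n)
    wts <- stats::rlnorm(m, meanlog = 0, sdlog = weightDispersion)
    wTry[ut[sel, , drop = FALSE]] <- wts
    wTry <- wTry + t(wTry)
    if (isConnectedMatrix(wTry)) { w <- wTry; break }
  }
  if (is.null(w)) {
    w <- bridgeComponents(wTry)
  }

  if (gradientStrength > 0) {
    g <- exp(gradientStrength * (geo$pos - 0.5))
    scale <- sqrt(outer(g, g))
    w <- w * scale
  }
  w <- w / max(w)
  Connectome(w, regionLabels = geo$labels, hemisphere = geo$hemi,
             partition = geo$module, centroids = geo$centroids)
}

## internal: two parallel anterior-posterior rows of centroids, module ids
## mirrored across hemispheres, positions normalized to [0, 1]
syntheticGeometry <- function(n, hemispheres, nModules) {
  if (hemispheres) {
    nL <- ceiling(n / 2); nR <- n - nL
    hemi <- c(rep("L", nL), rep("R", nR))
    idxWithin <- c(seq_len(nL), seq_len(nR))
    sizeWithin <- c(rep(nL, nL), rep(nR, nR))
  } else {
    hemi <- rep(NA_character_, n)
    idxWithin <- seq_len(n)
    sizeWithin <- rep(n, n)
  }
  pos <- (idxWithin - 1) / pmax(sizeWithin - 1, 1)
  module <- pmin(nModules, 1L + as.integer(floor(pos * nModules)))
  ## anterior-posterior extent ~140 mm, hemispheres 30 mm apart
  centroids <- cbind(x = pos * 140,
                     y = ifelse(is.na(hemi) | hemi == "L", -15, 15),
                     z = 0)
  labels <- sprintf("%s%03d", ifelse(is.na(hemi), "R", hemi),
                    seq_len(n))
  if (!anyNA(hemi)) labels <- paste0(hemi, sprintf("%03d", idxWithin))
  labels <- make.unique(labels)
  list(hemi = hemi, pos = pos, module = module, centroids = centroids,
       labels = labels)
}

isConnectedMatrix <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  igraph::is_connected(g)
}

## internal: join components with minimum-weight bridges, then drop the
## weakest dispensable edges to restore the original edge count
bridgeComponents <- function(w) {
  minw <- min(w[w > 0])
  repeat {
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no == 1) break
    i <- which(comp$membership == 1)[1]
    j <- which(comp$membership == 2)[1]
    w[i, j] <- w[j, i] <- minw
    ## remove the weakest edge whose removal keeps the graph connected
    ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    ord <- order(w[ut])
    for (k in ord) {
      a <- ut[k, 1]; b <- ut[k, 2]
      if (a == i && b == j) next
      w2 <- w; w2[a, b] <- w2[b, a] <- 0
      if (isConnectedMatrix(w2)) { w <- w2; break }
    }
  }
  w
}

#' Generate a cohort of subject-level connectomes
#'
#' All subjects share the group skeleton produced by
#' [syntheticConnectome()]; each subject's edge weights are perturbed
#' multiplicatively with log-normal dispersion \code{variability}, and a
#' random fraction \code{dropFraction} of the subject's edges is removed so
#' that consistency thresholding has something to do.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param variability log-normal sigma of multiplicative weight noise
#'   (0 = identical weights).
#' @param dropFraction per-subject fraction of edges deleted (default 0.1).
#' @param seed integer RNG seed (controls both skeleton and perturbations).
#' @param ... arguments passed to [syntheticConnectome()].
#' @return list of \code{nSubjects} [Connectome-class] objects.
#' @export
syntheticCohort <- function(nSubjects, variability = 0.3,
                            dropFraction = 0.1, seed = 1, ...) {
  stopifnot(nSubjects >= 1, variability >= 0,
            dropFraction >= 0, dropFraction < 1)
  skeleton <- syntheticConnectome(seed = seed, ...)
  w0 <- weights(skeleton)
  ut <- which(upper.tri(w0) & w0 > 0, arr.ind = TRUE)
  set.seed(seed + 104729L)  # offset so subject noise is not the skeleton draw
  lapply(seq_len(nSubjects), function(s) {
    w <- w0
    if (variability > 0) {
      noise <- stats::rlnorm(nrow(ut), meanlog = 0, sdlog = variability)
      w[ut] <- w0[ut] * noise
      w[ut[, c(2, 1), drop = FALSE]] <- w[ut]
    }
    if (dropFraction > 0) {
      nDrop <- floor(dropFraction * nrow(ut))
      if (nDrop > 0) {
        drop <- ut[sample.int(nrow(ut), nDrop), , drop = FALSE]
        w[drop] <- 0
        w[drop[, c(2, 1), drop = FALSE]] <- 0
      }
    }
    replaceWeights(skeleton, w)
  })
}

#' Simulate a stationary Ornstein-Uhlenbeck signal
#'
#' Exact discretization of the OU process with unit stationary variance:
#' the autocorrelation decays as exp(-t / timescale). Used as a ground-truth
#' input for timescale estimation.
#'
#' @param timescale decay constant tau (s).
#' @param dt sampling step (s), less than \code{timescale}.
#' @param duration total length (s), greater than \code{timescale}.
#' @param seed integer RNG seed.
#' @return a [SimulationTrace-class] with a single channel.
#' @export
ouSignal <- function(timescale, dt = 0.01, duration = 720, seed = 1) {
  stopifnot(dt > 0, timescale > dt, duration > timescale)
  set.seed(seed)
  nSteps <- floor(duration / dt)
  phi <- exp(-dt / timescale)
  innovSD <- sqrt(1 - phi^2)
  x <- numeric(nSteps + 1)
  x[1] <- stats::rnorm(1)
  eps <- stats::rnorm(nSteps)
  for (k in seq_len(nSteps)) x[k + 1] <- phi * x[k] + innovSD * eps[k]
  new("SimulationTrace", t = seq(0, by = dt, length.out = nSteps + 1),
      states = matrix(x, ncol = 1, dimnames = list(NULL, "ou")),
      dt = dt, transientCut = 0, seed = as.integer(seed), model = "ou")
}
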
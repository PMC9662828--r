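#' @include AllClasses.R AllGenerics.R connectome-io.R
NULL

asUndirectedMatrix <- function(C) {
  w <- weights(C)
  if (C@directed) (w + t(w)) / 2 else w
}

igraphFromMatrix <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted regional clustering coefficients
#'
#' Onnela-style weighted clustering: for region i with binary degree k_i,
#' C_i = (1 / (k_i (k_i - 1))) * sum over pairs (j, k) of
#' (w_ij w_jk w_ik)^(1/3), with weights first normalized by the matrix
#' maximum so values lie in [0, 1]. Regions with fewer than two neighbours
#' get 0. Directed input must be symmetrized first (an error otherwise).
#'
#' @param C an undirected [Connectome-class].
#' @return a [RegionalMap-class] of clustering coefficients.
#' @export
clusteringCoefficients <- function(C) {
  if (C@directed) {
    stop("clusteringCoefficients expects an undirected connectome; ",
         "symmetrize directed input first")
  }
  w <- weights(C)
  mx <- max(w)
  if (mx > 0) w <- w / mx
  cube <- w^(1 / 3)
  tri <- diag(cube %*% cube %*% cube)  # 2 * sum of triangle intensities
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  RegionalMap(cc, labels = regionLabels(C), name = "clustering")
}

#' Regional path lengths
#'
#' Shortest paths are computed with Dijkstra's algorithm on topological
#' distances 1/weight; the regional value is the mean distance from a
#' region to all other regions. The graph must be connected.
#'
#' @param C an undirected, connected [Connectome-class].
#' @return a [RegionalMap-class] of mean shortest-path distances.
#' @export
pathLengths <- function(C) {
  w <- asUndirectedMatrix(C)
  d <- pairwiseDistances(w)
  if (any(!is.finite(d))) {
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    comp <- igraph::components(g)
    stop("graph is disconnected: ", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  }
  n <- nrow(d)
  RegionalMap(rowSums(d) / (n - 1), labels = regionLabels(C),
              name = "path_length", units = "1/weight")
}

## internal: all-pairs shortest-path distances on 1/weight (Dijkstra)
pairwiseDistances <- function(w) {
  g <- igraphFromMatrix(w)
  ew <- igraph::E(g)$weight
  igraph::distances(g, weights = 1 / ew, algorithm = "dijkstra")
}

#' Characteristic path length and mean clustering of a weight matrix
#' @noRd
networkSummaries <- function(w) {
  d <- pairwiseDistances(w)
  fin <- d[upper.tri(d)]
  fin <- fin[is.finite(fin)]
  L <- if (length(fin)) mean(fin) else NA_real_
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  cube <- wn^(1 / 3)
  tri <- diag(cube %*% cube %*% cube)
  k <- rowSums(wn > 0)
  Cc <- mean(ifelse(k >= 2, tri / (k * (k - 1)), 0))
  list(C = Cc, L = L)
}

#' Small-world propensity
#'
#' phi = 1 - sqrt((dC^2 + dL^2) / 2), where dC and dL measure how far the
#' observed mean clustering and characteristic path length deviate from
#' weight-preserving lattice and random null ensembles:
#' dC = (C_latt - C_obs) / (C_latt - C_rand) and
#' dL = (L_obs - L_rand) / (L_latt - L_rand), each clipped to [0, 1].
#' Nulls keep the observed weight multiset: the random null places the
#' edges uniformly at random; the lattice null places the strongest weights
#' closest to the diagonal (ring-lattice order).
#'
#' @param C an undirected, connected [Connectome-class].
#' @param nNull null-ensemble size per family (default 10).
#' @param seed integer RNG seed.
#' @return small-world propensity in [0, 1].
#' @export
smallWorldPropensity <- function(C, nNull = 10, seed = 1) {
  if (nNull < 1) stop("nNull must be >= 1")
  w <- asUndirectedMatrix(C)
  n <- nrow(w)
  obs <- networkSummaries(w)
  wts <- sort(w[upper.tri(w) & w > 0], decreasing = TRUE)
  m <- length(wts)
  ut <- which(upper.tri(w), arr.ind = TRUE)

  ## lattice null: fill positions by circular distance to the diagonal,
  ## strongest weights first; randomize order within equal distances
  circ <- pmin(abs(ut[, 1] - ut[, 2]), n - abs(ut[, 1] - ut[, 2]))
  set.seed(seed)
  latt <- replicate(nNull, {
    ordPos <- order(circ, stats::runif(length(circ)))
    wl <- matrix(0, n, n)
    fill <- ut[ordPos[seq_len(m)], , drop = FALSE]
    wl[fill] <- wts
    wl + t(wl)
  }, simplify = FALSE)
  rand <- replicate(nNull, {
    sel <- sample.int(nrow(ut), m)
    wr <- matrix(0, n, n)
    wr[ut[sel, , drop = FALSE]] <- sample(wts)
    wr + t(wr)
  }, simplify = FALSE)
  cl <- vapply(latt, function(x) unlist(networkSummaries(x)), numeric(2))
  cr <- vapply(rand, function(x) unlist(networkSummaries(x)), numeric(2))
  Clatt <- mean(cl[1, ]); Llatt <- mean(cl[2, ], na.rm = TRUE)
  Crand <- mean(cr[1, ]); Lrand <- mean(cr[2, ], na.rm = TRUE)
  dC <- (Clatt - obs$C) / (Clatt - Crand)
  dL <- (obs$L - Lrand) / (Llatt - Lrand)
  dC <- min(max(dC, 0), 1)
  dL <- min(max(dL, 0), 1)
  if (!is.finite(dC)) dC <- 0
  if (!is.finite(dL)) dL <- 0
  1 - sqrt((dC^2 + dL^2) / 2)
}

#' Weighted modularity via Louvain community detection
#'
#' Runs the Louvain heuristic \code{nRestarts} times (resolution 1) and
#' returns the maximum Newman weighted modularity Q together with the
#' partition achieving it.
#'
#' @param C an undirected [Connectome-class] with nonnegative weights.
#' @param nRestarts number of Louvain runs (default 100).
#' @param seed integer RNG seed.
#' @return list with elements \code{Q} (numeric) and \code{partition}
#'   (integer module ids per region).
#' @export
modularityQ <- function(C, nRestarts = 100, seed = 1) {
  w <- asUndirectedMatrix(C)
  if (sum(w) == 0) stop("modularity of an empty graph is undefined")
  g <- igraphFromMatrix(w)
  set.seed(seed)
  best <- list(Q = -Inf, partition = NULL)
  for (r in seq_len(nRestarts)) {
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best$Q) {
      best <- list(Q = q, partition = as.integer(igraph::membership(cl)))
    }
  }
  names(best$partition) <- regionLabels(C)
  best
}

#' Regional path lengths of a functional-connectivity matrix
#'
#' Treats an FC (correlation) matrix as a weighted graph with distance
#' 1/weight; nonpositive correlations are treated as absent edges. The
#' resulting graph must be connected.
#'
#' @param FC symmetric correlation matrix with unit diagonal.
#' @param labels optional region names.
#' @return a [RegionalMap-class] of mean shortest-path distances.
#' @export
functionalPathLengths <- function(FC, labels = NULL) {
  FC <- as.matrix(FC)
  if (nrow(FC) != ncol(FC) || max(abs(FC - t(FC))) > 1e-8) {
    stop("FC must be a symmetric square matrix")
  }
  if (max(abs(diag(FC) - 1)) > 1e-8) stop("FC must have unit diagonal")
  w <- FC
  diag(w) <- 0
  w[w <= 0] <- 0
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(w)))
  pathLengths(Connectome(w, regionLabels = labels))
}
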
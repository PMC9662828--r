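#' @include AllClasses.R AllGenerics.R
NULL

## Dense format: header-less numeric rows. Edge list: "label label weight".
## A sidecar label table (region, hemisphere, network, x, y, z) carries
## metadata for either format.

#' Read a connectome from disk
#'
#' Supported formats: header-less dense CSV/TSV matrices and whitespace- or
#' comma-separated weighted edge lists (\code{from to weight}). An optional
#' sidecar label table (columns \code{region}, \code{hemisphere},
#' \code{network}, \code{x}, \code{y}, \code{z}) supplies region metadata.
#'
#' @param path file to read.
#' @param format one of \code{"dense_csv"}, \code{"dense_tsv"},
#'   \code{"edge_list"}.
#' @param directed logical; dense asymmetric input is only accepted with
#'   \code{directed = TRUE}; undirected edge lists are symmetrized.
#' @param labelsPath optional sidecar label table (CSV with header).
#' @return a [Connectome-class].
#' @export
readConnectome <- function(path, format = c("dense_csv", "dense_tsv",
                                            "edge_list"),
                           directed = FALSE, labelsPath = NULL) {
  format <- match.arg(format)
  if (format %in% c("dense_csv", "dense_tsv")) {
    sep <- if (format == "dense_csv") "," else "\t"
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) {
      stop("dense connectome must be square: got ", nrow(m), " x ", ncol(m))
    }
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric or NaN entry at row %d, column %d",
                   bad[1], bad[2]))
    }
    if (any(m < 0)) stop("negative weights are not allowed")
    if (!directed && max(abs(m - t(m))) > 1e-10 * max(1, max(m))) {
      stop("asymmetric matrix; pass directed = TRUE to accept it")
    }
    labels <- paste0("R", seq_len(nrow(m)))
    weightsMat <- m
  } else {
    el <- utils::read.table(path, header = FALSE,
                            col.names = c("from", "to", "weight"),
                            colClasses = c("character", "character",
                                           "numeric"))
    if (anyNA(el$weight)) stop("edge list contains non-numeric weights")
    if (any(el$weight < 0)) stop("negative weights are not allowed")
    labels <- sort(unique(c(el$from, el$to)))
    n <- length(labels)
    weightsMat <- matrix(0, n, n)
    i <- match(el$from, labels); j <- match(el$to, labels)
    weightsMat[cbind(i, j)] <- el$weight
    if (!directed) {
      weightsMat[cbind(j, i)] <- el$weight
    }
  }
  diag(weightsMat) <- 0
  meta <- list(hemisphere = NULL, partition = NULL, centroids = NULL)
  if (!is.null(labelsPath)) {
    lab <- utils::read.csv(labelsPath, stringsAsFactors = FALSE)
    if (!"region" %in% names(lab)) stop("sidecar must have a 'region' column")
    if (format == "edge_list") {
      ord <- match(labels, lab$region)
      if (anyNA(ord)) stop("sidecar is missing regions: ",
                           paste(labels[is.na(ord)], collapse = ", "))
      lab <- lab[ord, ]
    } else {
      if (nrow(lab) != nrow(weightsMat)) {
        stop("sidecar row count does not match matrix size")
      }
      labels <- lab$region
    }
    if ("hemisphere" %in% names(lab)) meta$hemisphere <- lab$hemisphere
    if ("network" %in% names(lab)) meta$partition <- lab$network
    if (all(c("x", "y", "z") %in% names(lab))) {
      meta$centroids <- as.matrix(lab[, c("x", "y", "z")])
    }
  }
  Connectome(weightsMat, regionLabels = labels,
             hemisphere = meta$hemisphere, partition = meta$partition,
             centroids = meta$centroids, directed = directed)
}

#' Write a connectome to disk
#'
#' Dense output is written with \code{write.table} at full precision
#' (15 significant digits) so a dense round trip is bit-identical.
#'
#' @param C a [Connectome-class].
#' @param path output file.
#' @param format \code{"dense_csv"}, \code{"dense_tsv"} or
#'   \code{"edge_list"}.
#' @param labelsPath optional path for the sidecar label table.
#' @return \code{path}, invisibly.
#' @export
writeConnectome <- function(C, path, format = c("dense_csv", "dense_tsv",
                                                "edge_list"),
                            labelsPath = NULL) {
  format <- match.arg(format)
  w <- weights(C)
  if (format %in% c("dense_csv", "dense_tsv")) {
    sep <- if (format == "dense_csv") "," else "\t"
    lines <- apply(w, 1, function(r) {
      paste(formatC(r, format = "g", digits = 17), collapse = sep)
    })
    writeLines(lines, path)
  } else {
    idx <- which(if (C@directed) w > 0 else upper.tri(w) & w > 0,
                 arr.ind = TRUE)
    lab <- regionLabels(C)
    writeLines(sprintf("%s %s %s", lab[idx[, 1]], lab[idx[, 2]],
                       formatC(w[idx], format = "g", digits = 17)), path)
  }
  if (!is.null(labelsPath)) {
    lab <- data.frame(region = regionLabels(C), hemisphere = hemisphere(C),
                      network = if (length(C@partition)) C@partition
                                else NA_integer_)
    cc <- centroids(C)
    if (!is.null(cc)) {
      lab$x <- cc[, 1]; lab$y <- cc[, 2]; lab$z <- cc[, 3]
    }
    utils::write.csv(lab, labelsPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Normalize a connectome by its maximum weight
#'
#' Divides every weight by the matrix maximum so the strongest connection
#' has weight exactly 1; weight ratios are preserved. Idempotent.
#'
#' @param C a [Connectome-class] with at least one positive weight.
#' @return the normalized [Connectome-class].
#' @export
normalizeByMax <- function(C) {
  w <- weights(C)
  mx <- max(w)
  if (mx <= 0) stop("cannot normalize an all-zero connectome")
  replaceWeights(C, w / mx)
}

## internal: swap in a new weight matrix, keeping metadata
replaceWeights <- function(C, w) {
  dimnames(w) <- list(regionLabels(C), regionLabels(C))
  initialize(C, weights = w)
}

#' Group-average a cohort with a consistency threshold
#'
#' An edge is retained iff present (weight > 0) in at least
#' \code{consistency} fraction of subjects; a retained edge's weight is the
#' mean over the subjects in which it is present (set
#' \code{includeZeros = TRUE} to average over all subjects instead).
#'
#' @param cohort list of [Connectome-class] objects on one parcellation.
#' @param consistency fraction in (0, 1]; default 0.6.
#' @param includeZeros average over all subjects rather than only those
#'   possessing the edge.
#' @return the group-averaged [Connectome-class].
#' @export
groupAverage <- function(cohort, consistency = 0.6, includeZeros = FALSE) {
  checkCohort(cohort)
  stopifnot(consistency > 0, consistency <= 1)
  arr <- simplify2array(lapply(cohort, weights))
  present <- arr > 0
  frac <- apply(present, c(1, 2), mean)
  keep <- frac >= consistency - 1e-12
  avg <- if (includeZeros) {
    apply(arr, c(1, 2), mean)
  } else {
    s <- apply(arr, c(1, 2), sum)
    cnt <- apply(present, c(1, 2), sum)
    out <- matrix(0, nrow(s), ncol(s))
    nz <- cnt > 0
    out[nz] <- s[nz] / cnt[nz]
    out
  }
  avg[!keep] <- 0
  diag(avg) <- 0
  replaceWeights(cohort[[1]], avg)
}

#' Average the nonzero weights of a cohort
#'
#' Each edge of the result is the mean of its nonzero values across
#' subjects; an edge is absent only if zero in every subject. This is the
#' convention used for tract-tracing cohorts.
#'
#' @inheritParams groupAverage
#' @return the averaged [Connectome-class].
#' @export
averageNonzero <- function(cohort) {
  groupAverage(cohort, consistency = 1e-9, includeZeros = FALSE)
}

checkCohort <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) >= 1)
  lab <- regionLabels(cohort[[1]])
  for (C in cohort) {
    if (!identical(regionLabels(C), lab) ||
        nRegions(C) != length(lab)) {
      stop("cohort members must share dimension and region labels")
    }
  }
  invisible(TRUE)
}

#' Threshold a connectome to a target edge density
#'
#' Removes the weakest edges until the density is within one edge of
#' \code{targetDensity}; surviving weights are unchanged. Ties at the cutoff
#' weight are broken deterministically by (row, column) order.
#'
#' @param C an undirected [Connectome-class].
#' @param targetDensity fraction, at most the current density.
#' @return the pruned [Connectome-class].
#' @export
matchDensity <- function(C, targetDensity) {
  if (C@directed) stop("matchDensity expects an undirected connectome")
  cur <- edgeDensity(C)
  if (targetDensity > cur + 1e-12) {
    stop(sprintf("target density %.4f exceeds current density %.4f",
                 targetDensity, cur))
  }
  n <- nRegions(C)
  nPairs <- n * (n - 1) / 2
  mTarget <- round(targetDensity * nPairs)
  w <- weights(C)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(ut) <= mTarget) return(C)
  wt <- w[ut]
  ## keep the mTarget strongest; break ties by (row, col) ascending,
  ## i.e. among equal weights the earliest-indexed edges survive
  ord <- order(-wt, ut[, 1], ut[, 2])
  drop <- ut[ord[-seq_len(mTarget)], , drop = FALSE]
  w[drop] <- 0
  w[drop[, c(2, 1), drop = FALSE]] <- 0
  replaceWeights(C, w)
}

#' Classify connections as shared or species-specific
#'
#' Compares two connectomes on the same parcellation: an edge present
#' (weight > 0) in both is shared (with paired weights returned for
#' correlation), otherwise it is specific to the connectome possessing it.
#' When hemisphere labels are available, the fraction of specific edges
#' that are intrahemispheric is reported.
#'
#' @param C1,C2 undirected [Connectome-class] objects with identical labels.
#' @return an [EdgeClassification-class].
#' @export
classifyConnections <- function(C1, C2) {
  if (!identical(regionLabels(C1), regionLabels(C2))) {
    stop("connectomes must share region labels")
  }
  w1 <- weights(C1); w2 <- weights(C2)
  ut <- which(upper.tri(w1), arr.ind = TRUE)
  p1 <- w1[ut] > 0; p2 <- w2[ut] > 0
  lab <- regionLabels(C1)
  idx <- function(sel) ut[sel, , drop = FALSE]
  shared <- data.frame(from = lab[idx(p1 & p2)[, 1]],
                       to = lab[idx(p1 & p2)[, 2]],
                       w1 = w1[idx(p1 & p2)], w2 = w2[idx(p1 & p2)],
                       stringsAsFactors = FALSE)
  sp1 <- data.frame(from = lab[idx(p1 & !p2)[, 1]],
                    to = lab[idx(p1 & !p2)[, 2]],
                    w = w1[idx(p1 & !p2)], stringsAsFactors = FALSE)
  sp2 <- data.frame(from = lab[idx(!p1 & p2)[, 1]],
                    to = lab[idx(!p1 & p2)[, 2]],
                    w = w2[idx(!p1 & p2)], stringsAsFactors = FALSE)
  intraFrac <- function(d, hemi) {
    if (!nrow(d) || anyNA(hemi)) return(NA_real_)
    h <- stats::setNames(hemi, lab)
    mean(h[d$from] == h[d$to])
  }
  new("EdgeClassification", shared = shared, specific1 = sp1,
      specific2 = sp2,
      intraFrac1 = intraFrac(sp1, hemisphere(C1)),
      intraFrac2 = intraFrac(sp2, hemisphere(C2)))
}

#' Rescale edge weights by another cohort's inter-individual variability
#'
#' Multiplies each weight by \code{sdOther/sdSelf} so that the rescaled
#' connectome matches the other cohort's edge-wise variability. Edges where
#' either SD is zero are left unchanged (with a warning).
#'
#' @param C a [Connectome-class].
#' @param sdSelf,sdOther nonnegative matrices of edge-wise across-subject
#'   SDs, same shape as \code{weights(C)}.
#' @return the rescaled [Connectome-class].
#' @export
rescaleByVariability <- function(C, sdSelf, sdOther) {
  w <- weights(C)
  if (!all(dim(sdSelf) == dim(w)) || !all(dim(sdOther) == dim(w))) {
    stop("SD matrices must have the same shape as the weight matrix")
  }
  if (any(sdSelf < 0) || any(sdOther < 0)) stop("SDs must be nonnegative")
  ok <- sdSelf > 0 & sdOther > 0
  nZero <- sum(w > 0 & !ok)
  if (nZero > 0) {
    warning(nZero, " edges with zero SD left unchanged")
  }
  w[ok] <- w[ok] * sdOther[ok] / sdSelf[ok]
  replaceWeights(C, w)
}

#' Edge-wise across-subject SD of a cohort
#'
#' @param cohort list of [Connectome-class] objects.
#' @return matrix of per-edge standard deviations across subjects.
#' @export
cohortEdgeSD <- function(cohort) {
  checkCohort(cohort)
  arr <- simplify2array(lapply(cohort, weights))
  apply(arr, c(1, 2), stats::sd)
}

#' Group averages of random cohort subsamples
#'
#' Draws \code{nTrials} without-replacement subsamples of size \code{n} and
#' returns the consistency-thresholded group average of each, e.g. to match
#' a larger cohort's sample size to a smaller one's.
#'
#' @param cohort list of [Connectome-class] objects.
#' @param n subsample size (at most the cohort size).
#' @param nTrials number of subsamples; default 100.
#' @param consistency consistency threshold passed to [groupAverage()].
#' @param seed integer RNG seed.
#' @return list of \code{nTrials} group-averaged [Connectome-class] objects.
#' @export
subsampleGroup <- function(cohort, n, nTrials = 100, consistency = 0.6,
                           seed = 1) {
  checkCohort(cohort)
  if (n > length(cohort)) stop("n exceeds cohort size")
  set.seed(seed)
  lapply(seq_len(nTrials), function(i) {
    groupAverage(cohort[sample.int(length(cohort), n)],
                 consistency = consistency)
  })
}

#' Graph Laplacian of a connectome
#'
#' L = D - A, where D is the diagonal matrix of node strengths
#' (row sums of A). Every row of L sums to zero.
#'
#' @param C a [Connectome-class].
#' @return the n x n Laplacian matrix.
#' @export
graphLaplacian <- function(C) {
  A <- weights(C)
  diag(rowSums(A), nrow(A)) - A
}
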
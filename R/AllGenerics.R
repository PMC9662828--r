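#' @include AllClasses.R
NULL

#' Accessors for conndyn classes
#'
#' Small accessor generics used throughout the package instead of direct
#' slot access.
#'
#' @param object a conndyn S4 object.
#' @return \code{weights} the adjacency matrix; \code{nRegions} the region
#'   count; \code{regionLabels} the region names; \code{hemisphere} the
#'   hemisphere labels; \code{networkPartition} the module/network ids (or
#'   \code{NULL}); \code{centroids} the centroid matrix (or \code{NULL});
#'   \code{mapValues} the numeric vector of a \code{RegionalMap}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("weights")

#' @rdname accessors
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("hemisphere", function(object) standardGeneric("hemisphere"))

#' @rdname accessors
#' @export
setGeneric("networkPartition",
           function(object) standardGeneric("networkPartition"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname accessors
setMethod("weights", "Connectome", function(object, ...) object@weights)

#' @rdname accessors
setMethod("nRegions", "Connectome", function(object) nrow(object@weights))

#' @rdname accessors
setMethod("regionLabels", "Connectome", function(object) object@regionLabels)

#' @rdname accessors
setMethod("hemisphere", "Connectome", function(object) object@hemisphere)

#' @rdname accessors
setMethod("networkPartition", "Connectome", function(object) {
  if (length(object@partition)) object@partition else NULL
})

#' @rdname accessors
setMethod("centroids", "Connectome", function(object) {
  if (nrow(object@centroids)) object@centroids else NULL
})

#' @rdname accessors
setMethod("mapValues", "RegionalMap", function(object) {
  stats::setNames(object@values, object@labels)
})

#' @rdname accessors
setMethod("regionLabels", "RegionalMap", function(object) object@labels)

#' @rdname accessors
setMethod("regionLabels", "ResponseFunction",
          function(object) object@regionLabels)

#' Edge density of a connectome
#'
#' Fraction of possible (off-diagonal) connections with positive weight.
#' For undirected connectomes the denominator is n(n-1)/2.
#'
#' @param object a [Connectome-class].
#' @return density in [0, 1].
#' @export
setGeneric("edgeDensity", function(object) standardGeneric("edgeDensity"))

#' @rdname edgeDensity
setMethod("edgeDensity", "Connectome", function(object) {
  n <- nRegions(object)
  if (n < 2) return(0)
  w <- weights(object)
  if (object@directed) {
    sum(w > 0) / (n * (n - 1))
  } else {
    sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
  }
})

#' Node strengths
#'
#' Row sums of the weight matrix: s_i = sum_j A_ij.
#'
#' @param object a [Connectome-class].
#' @return a named numeric vector of strengths.
#' @export
setGeneric("nodeStrengths", function(object) standardGeneric("nodeStrengths"))

#' @rdname nodeStrengths
setMethod("nodeStrengths", "Connectome", function(object) {
  rowSums(weights(object))
})

setMethod("show", "Connectome", function(object) {
  n <- nRegions(object)
  cat(sprintf("Connectome: %d regions, %s, density %.3f\n",
              n, if (object@directed) "directed" else "undirected",
              edgeDensity(object)))
  if (n) {
    cat(sprintf("  weights: max %.4g, nonzero %d\n",
                max(weights(object)), sum(weights(object) > 0)))
  }
  if (length(object@partition)) {
    cat(sprintf("  partition: %d modules\n",
                length(unique(object@partition))))
  }
  if (nrow(object@centroids)) cat("  centroids: present\n")
  invisible(object)
})

setMethod("show", "RegionalMap", function(object) {
  cat(sprintf("RegionalMap '%s' (%s): %d regions\n", object@name,
              if (nzchar(object@units)) object@units else "unitless",
              length(object@values)))
  v <- object@values[is.finite(object@values)]
  if (length(v)) {
    cat(sprintf("  range [%.4g, %.4g], mean %.4g, NA %d\n",
                min(v), max(v), mean(v), sum(!is.finite(object@values))))
  }
  invisible(object)
})

setMethod("show", "SimulationTrace", function(object) {
  cat(sprintf("SimulationTrace (%s): %d steps x %d regions, dt = %g s\n",
              object@model, nrow(object@states), ncol(object@states),
              object@dt))
  invisible(object)
})

setMethod("show", "ResponseFunction", function(object) {
  cat(sprintf("ResponseFunction (%s): %d regions x %d grid points, w in [%g, %g]\n",
              object@model, nrow(object@sBar), length(object@wGrid),
              min(object@wGrid), max(object@wGrid)))
  invisible(object)
})

setMethod("show", "DynamicRangeProfile", function(object) {
  cat(sprintf("DynamicRangeProfile: %d/%d regions defined, sigma = %.4g\n",
              object@nDefined, length(object@dr), object@sigma))
  invisible(object)
})

setMethod("show", "AccuracyCurve", function(object) {
  cat(sprintf("AccuracyCurve: %d regions, %d trials, horizon %.2f s, terminal whole-brain accuracy %.3f\n",
              ncol(object@regional), object@nTrials, max(object@t),
              object@wholeBrain[length(object@wholeBrain)]))
  invisible(object)
})

setMethod("show", "EdgeClassification", function(object) {
  cat(sprintf("EdgeClassification: %d shared, %d specific to 1 (%.1f%% intra), %d specific to 2 (%.1f%% intra)\n",
              nrow(object@shared), nrow(object@specific1),
              100 * object@intraFrac1, nrow(object@specific2),
              100 * object@intraFrac2))
  invisible(object)
})

## tidy extractors --------------------------------------------------------

#' Tidy data.frame views of result objects
#'
#' @param object a ResponseFunction, DynamicRangeProfile or AccuracyCurve.
#' @return a long-format data.frame.
#' @export
setGeneric("asTidy", function(object) standardGeneric("asTidy"))

#' @rdname asTidy
setMethod("asTidy", "ResponseFunction", function(object) {
  data.frame(
    region = rep(object@regionLabels, times = length(object@wGrid)),
    w = rep(object@wGrid, each = nrow(object@sBar)),
    s_bar = as.vector(object@sBar)
  )
})

#' @rdname asTidy
setMethod("asTidy", "DynamicRangeProfile", function(object) {
  data.frame(region = object@labels, dr = object@dr, w10 = object@w10,
             w90 = object@w90, zscore = object@zscores)
})

#' @rdname asTidy
setMethod("asTidy", "AccuracyCurve", function(object) {
  data.frame(
    region = rep(object@labels, each = length(object@t)),
    t = rep(object@t, times = ncol(object@regional)),
    accuracy = as.vector(object@regional)
  )
})
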
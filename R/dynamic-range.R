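#' @include AllClasses.R AllGenerics.R
NULL

#' Dynamic range of a single response curve
#'
#' The response span is normalized between the observed sweep extremes:
#' S_x = S_min + (x/100)(S_max - S_min). w10 and w90 are located at the
#' FIRST upward crossing of S_10 and S_90 by linear interpolation on the
#' grid, and the dynamic range is 10 log10(w90 / w10), i.e. the width (in
#' decibel-like units) of the excitability window over which the region's
#' response moves through the central 80% of its span. Undefined (NA, with
#' a warning) when the curve is flat or the 10% crossing sits at or before
#' w = 0.
#'
#' @param sBar response values at the grid points.
#' @param wGrid strictly increasing grid of recurrent strengths (>= 3
#'   points).
#' @param smooth apply a 3-point running-median pre-smoothing (off by
#'   default); useful when noise creates spurious first crossings.
#' @return named vector \code{c(dr, w10, w90)} (all NA when undefined).
#' @examples
#' w <- seq(0, 1, 0.01)
#' dynamicRange(w, w)["dr"]  # linear ramp: 10 log10(0.9 / 0.1)
#' @export
dynamicRange <- function(sBar, wGrid, smooth = FALSE) {
  stopifnot(length(sBar) == length(wGrid), length(wGrid) >= 3,
            all(diff(wGrid) > 0))
  if (smooth && length(sBar) >= 3) {
    sBar <- stats::runmed(sBar, 3, endrule = "keep")
  }
  smin <- min(sBar); smax <- max(sBar)
  if (smax <= smin) {
    warning("flat response curve: dynamic range undefined")
    return(c(dr = NA_real_, w10 = NA_real_, w90 = NA_real_))
  }
  crossing <- function(x) {
    target <- smin + (x / 100) * (smax - smin)
    if (sBar[1] >= target) return(wGrid[1])
    above <- which(sBar >= target)
    k <- above[1]
    w0 <- wGrid[k - 1]; w1 <- wGrid[k]
    s0 <- sBar[k - 1]; s1 <- sBar[k]
    w0 + (target - s0) / (s1 - s0) * (w1 - w0)
  }
  w10 <- crossing(10)
  w90 <- crossing(90)
  if (w10 <= 0) {
    warning("10% crossing at or before w = 0: dynamic range undefined")
    return(c(dr = NA_real_, w10 = NA_real_, w90 = NA_real_))
  }
  c(dr = 10 * log10(w90 / w10), w10 = w10, w90 = w90)
}

#' Dynamic-range profile of a response-function sweep
#'
#' Applies [dynamicRange()] region by region, then summarizes the
#' distribution: its standard deviation sigma over regions with a defined
#' value, and per-region z-scores on the same set. Regions with an
#' undefined dynamic range are excluded from sigma (their count is
#' reported), not imputed.
#'
#' @param rf a [ResponseFunction-class].
#' @param smooth passed to [dynamicRange()].
#' @return a [DynamicRangeProfile-class].
#' @export
drProfile <- function(rf, smooth = FALSE) {
  n <- nrow(rf@sBar)
  res <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("dr", "w10", "w90")))
  for (i in seq_len(n)) {
    res[i, ] <- suppressWarnings(
      dynamicRange(rf@sBar[i, ], rf@wGrid, smooth = smooth))
  }
  dr <- res[, "dr"]
  ok <- is.finite(dr)
  if (!any(ok)) stop("dynamic range undefined for every region")
  sigma <- stats::sd(dr[ok])
  z <- rep(NA_real_, n)
  if (sigma > 0) z[ok] <- (dr[ok] - mean(dr[ok])) / sigma
  else z[ok] <- 0
  new("DynamicRangeProfile", dr = dr, w10 = res[, "w10"],
      w90 = res[, "w90"], sigma = sigma, zscores = z,
      labels = rf@regionLabels, nDefined = sum(ok))
}

#' Split a regional map by network partition
#'
#' @param map a [RegionalMap-class].
#' @param partition per-region network ids covering all regions.
#' @return a list with \code{values} (named list of per-network value
#'   vectors) and \code{medians} (named numeric vector).
#' @export
groupByNetwork <- function(map, partition) {
  v <- map@values
  if (length(partition) != length(v)) {
    stop("partition must assign a network to every region")
  }
  if (anyNA(partition)) {
    stop("region(s) without a network id: ",
         paste(map@labels[is.na(partition)], collapse = ", "))
  }
  groups <- split(v, partition)
  list(values = groups,
       medians = vapply(groups, stats::median, numeric(1), na.rm = TRUE))
}

#' Correlate two regional maps
#'
#' Pearson or Spearman association between two per-region maps on the same
#' parcellation, with listwise deletion of missing values.
#'
#' @param map1,map2 [RegionalMap-class] objects over the same regions.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return named vector \code{c(estimate, p)}.
#' @export
associateMaps <- function(map1, map2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(map1@values) != length(map2@values)) {
    stop("maps must cover the same regions")
  }
  x <- map1@values; y <- map2@values
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 complete region pairs")
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
  c(estimate = unname(ct$estimate), p = ct$p.value)
}
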
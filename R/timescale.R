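#' @include AllClasses.R AllGenerics.R neural-sim.R
NULL

#' Normalized sample autocorrelation
#'
#' Biased (divide-by-N) normalized estimator, value exactly 1 at lag 0 —
#' the standard choice for fitting monotone-decaying autocorrelations.
#'
#' @param signal numeric vector (non-constant).
#' @param dt sampling interval (s).
#' @param maxLag largest lag (s), default 1.
#' @return data.frame with columns \code{lag} (s) and \code{acf}.
#' @export
autocorrelationCurve <- function(signal, dt, maxLag = 1) {
  nLags <- floor(maxLag / dt)
  if (length(signal) <= nLags + 1) stop("signal too short for maxLag")
  if (stats::sd(signal) == 0) stop("constant signal has no autocorrelation")
  a <- stats::acf(signal, lag.max = nLags, plot = FALSE, demean = TRUE)
  data.frame(lag = a$lag[, 1, 1] * dt, acf = a$acf[, 1, 1])
}

#' Fit a single-exponential decay to an autocorrelation curve
#'
#' Nonlinear least squares of c1 exp(-t / tau) + c2 with the constraint
#' tau > 0 (Levenberg-Marquardt with bounds). Initializer (c1, tau, c2) =
#' (1, 0.1, 0); tau is bounded to [dt, span/4 by default]. A flat curve is
#' unidentifiable and is reported as non-converged.
#'
#' @param acfCurve data.frame from [autocorrelationCurve()] (>= 5 lags).
#' @param dt sampling interval (s), used for the lower tau bound.
#' @param tauUpper upper bound for tau (default: curve span, i.e. the
#'   largest lag; at least 10 dt).
#' @return list with \code{tau}, \code{c1}, \code{c2}, \code{rss},
#'   \code{converged}.
#' @export
fitTimescale <- function(acfCurve, dt, tauUpper = NULL) {
  stopifnot(nrow(acfCurve) >= 5)
  tt <- acfCurve$lag
  yy <- acfCurve$acf
  if (is.null(tauUpper)) tauUpper <- max(max(tt), 10 * dt)
  if (stats::sd(yy) < 1e-12) {
    return(list(tau = NA_real_, c1 = NA_real_, c2 = mean(yy),
                rss = 0, converged = FALSE))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ c1 * exp(-tt / tau) + c2,
      start = list(c1 = 1, tau = 0.1, c2 = 0),
      lower = c(c1 = -Inf, tau = dt, c2 = -Inf),
      upper = c(c1 = Inf, tau = tauUpper, c2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(tau = NA_real_, c1 = NA_real_, c2 = NA_real_,
                rss = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  ## a fit pinned to a bound or with negligible decay amplitude is not a
  ## trustworthy timescale
  converged <- is.finite(cf[["tau"]]) && cf[["tau"]] > dt * 1.001 &&
    cf[["tau"]] < tauUpper * 0.999 && abs(cf[["c1"]]) > 1e-3
  list(tau = unname(cf[["tau"]]), c1 = unname(cf[["c1"]]),
       c2 = unname(cf[["c2"]]),
       rss = sum(stats::residuals(fit)^2), converged = converged)
}

#' Fit a double-exponential decay (robustness check)
#'
#' c1 exp(-t/tau1) + c3 exp(-t/tau2) + c2, initialized from the
#' single-exponential fit. On a curve that is truly single-exponential the
#' two components are only weakly identified (the amplitude splits
#' arbitrarily between similar taus), so the reported \code{tau} is the
#' amplitude-weighted mean of tau1 and tau2 — the effective decay constant.
#'
#' @inheritParams fitTimescale
#' @return list with \code{tau} (amplitude-weighted effective timescale),
#'   \code{tau1}, \code{tau2}, \code{converged}.
#' @export
fitTimescaleDouble <- function(acfCurve, dt, tauUpper = NULL) {
  tt <- acfCurve$lag
  yy <- acfCurve$acf
  if (is.null(tauUpper)) tauUpper <- max(max(tt), 10 * dt)
  single <- fitTimescale(acfCurve, dt, tauUpper)
  tau0 <- if (is.finite(single$tau)) single$tau else 0.1
  starts <- list(
    list(c1 = 0.3, tau1 = max(dt * 2, tau0 / 3), c3 = 0.7, tau2 = tau0,
         c2 = single$c2 %||NA% 0),
    list(c1 = 0.5, tau1 = max(dt * 2, 0.05), c3 = 0.5, tau2 = 0.2,
         c2 = 0))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ c1 * exp(-tt / tau1) + c3 * exp(-tt / tau2) + c2,
        start = st,
        lower = c(-Inf, dt, -Inf, dt, -Inf),
        upper = c(Inf, tauUpper, Inf, tauUpper, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(list(tau = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  a1 <- abs(cf[["c1"]]); a2 <- abs(cf[["c3"]])
  eff <- (a1 * cf[["tau1"]] + a2 * cf[["tau2"]]) / (a1 + a2)
  list(tau = unname(eff), tau1 = unname(cf[["tau1"]]),
       tau2 = unname(cf[["tau2"]]), converged = TRUE)
}

`%||NA%` <- function(a, b) if (is.null(a) || !is.finite(a)) b else a

#' Regional intrinsic timescales from a Wong-Wang simulation
#'
#' Simulates the model at a fixed recurrent strength (default w = 0.45, a
#' biologically plausible low-firing, not fully synchronized regime),
#' computes each region's autocorrelation after the transient, and fits
#' the single-exponential decay to obtain per-region tau.
#'
#' @param C a [Connectome-class].
#' @param params a [WWParams-class] (its \code{w} slot is used; default
#'   0.45).
#' @param duration,dt simulation length and step (s).
#' @param seed integer RNG seed.
#' @param maxLag autocorrelation window (s), default 1.
#' @return a [RegionalMap-class] of timescales (s); non-converged fits are
#'   NA.
#' @export
regionalTimescales <- function(C, params = wwParams(), duration = 720,
                               dt = 0.01, seed = 1, maxLag = 1) {
  tr <- simulateWW(C, params, duration = duration, dt = dt, seed = seed)
  keep <- tr@t >= tr@transientCut
  X <- tr@states[keep, , drop = FALSE]
  taus <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0) return(NA_real_)
    ac <- autocorrelationCurve(X[, j], dt, maxLag = maxLag)
    ft <- fitTimescale(ac, dt)
    if (ft$converged) ft$tau else NA_real_
  }, numeric(1))
  RegionalMap(taus, labels = regionLabels(C), name = "timescale",
              units = "s")
}
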
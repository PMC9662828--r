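test_that("dynamic range of analytic curves matches closed forms", {
  w <- seq(0, 1, by = 0.01)
  res <- dynamicRange(w, w)  # linear ramp S = w
  expect_equal(res[["w10"]], 0.1, tolerance = 1e-12)
  expect_equal(res[["w90"]], 0.9, tolerance = 1e-12)
  expect_equal(res[["dr"]], 10 * log10(9), tolerance = 1e-12)
})

test_that("a step response collapses the dynamic range with grid refinement", {
  drAt <- function(h) {
    w <- seq(0, 1, by = h)
    s <- as.numeric(w >= 0.5)
    dynamicRange(s, w)[["dr"]]
  }
  drs <- vapply(c(0.1, 0.01, 0.001), drAt, numeric(1))
  expect_true(all(diff(drs) < 0))   # shrinks as the grid refines
  expect_lt(drs[3], 0.02)           # -> 0 in the limit
})

test_that("dynamic range is invariant to affine response and horizontal scaling", {
  set.seed(1)
  w <- seq(0.01, 1, by = 0.01)
  s <- 1 / (1 + exp(-(w - 0.4) / 0.08))
  base <- dynamicRange(s, w)
  aff <- dynamicRange(0.2 + 0.3 * s, w)       # affine in S
  expect_equal(aff[["dr"]], base[["dr"]], tolerance = 1e-10)
  stretch <- dynamicRange(s, 3 * w)           # w -> c w
  expect_equal(stretch[["dr"]], base[["dr"]], tolerance = 1e-10)
})

test_that("interpolated crossings agree with a dense nearest-point oracle", {
  w <- seq(0, 1, by = 0.02)
  s <- 1 / (1 + exp(-(w - 0.45) / 0.06))
  got <- dynamicRange(s, w)
  # oracle: refine the grid 100x, take the first grid point beyond target
  wf <- seq(0, 1, by = 0.0002)
  sf <- approx(w, s, xout = wf)$y
  smin <- min(s); smax <- max(s)
  oracleW <- function(x) {
    target <- smin + x / 100 * (smax - smin)
    wf[which(sf >= target)[1]]
  }
  oracleDr <- 10 * log10(oracleW(90) / oracleW(10))
  # agreement within the dr increment induced by one coarse grid step
  tolDr <- abs(10 * log10((got[["w10"]] + 0.02) / got[["w10"]]))
  expect_lt(abs(got[["dr"]] - oracleDr), tolDr)
})

test_that("degenerate curves are reported as undefined", {
  w <- seq(0, 1, by = 0.1)
  expect_warning(res <- dynamicRange(rep(0.3, 11), w), "flat")
  expect_true(all(is.na(res)))
  # non-monotone curve whose w = 0 value already exceeds the 10% level:
  # the first crossing sits at the origin, so the log-ratio is undefined
  s <- c(0.5, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1.0)
  expect_warning(res2 <- dynamicRange(s, w), "undefined")
  expect_true(is.na(res2[["dr"]]))
})

test_that("profiles summarize the regional distribution correctly", {
  w <- seq(0.01, 1, by = 0.01)
  curves <- rbind(
    1 / (1 + exp(-(w - 0.3) / 0.05)),
    1 / (1 + exp(-(w - 0.5) / 0.10)),
    1 / (1 + exp(-(w - 0.6) / 0.02)))
  rf <- new("ResponseFunction", wGrid = w, sBar = curves,
            model = "wong_wang", regionLabels = paste0("R", 1:3))
  prof <- drProfile(rf)
  expect_equal(prof@nDefined, 3L)
  expect_equal(prof@sigma, sd(prof@dr))
  expect_equal(mean(prof@zscores), 0, tolerance = 1e-12)
  expect_equal(sd(prof@zscores), 1, tolerance = 1e-12)
  # identical curves across regions: zero spread
  rfSame <- new("ResponseFunction", wGrid = w,
                sBar = curves[c(1, 1, 1), ], model = "wong_wang",
                regionLabels = paste0("R", 1:3))
  expect_equal(drProfile(rfSame)@sigma, 0)
})

test_that("an imposed strength gradient widens the dynamic-range distribution", {
  wg <- seq(0, 1, by = 0.05)
  C0 <- syntheticConnectome(nRegions = 40, density = 0.2,
                            gradientStrength = 0, seed = 12)
  C2 <- syntheticConnectome(nRegions = 40, density = 0.2,
                            gradientStrength = 2, seed = 12)
  s0 <- drProfile(responseFunction(C0, wGrid = wg, duration = 30,
                                   dt = 0.01, seed = 3))@sigma
  s2 <- drProfile(responseFunction(C2, wGrid = wg, duration = 30,
                                   dt = 0.01, seed = 3))@sigma
  expect_gt(s2, s0)
})

test_that("network grouping and map association behave as documented", {
  m <- RegionalMap(c(1, 1, 2, 2), name = "x")
  g <- groupByNetwork(m, c(1, 1, 2, 2))
  expect_equal(unname(g$medians), c(1, 2))
  expect_equal(groupByNetwork(m, rep(1, 4))$medians[["1"]], 1.5)
  # permuting regions leaves group medians unchanged
  perm <- c(3, 1, 4, 2)
  g2 <- groupByNetwork(RegionalMap(m@values[perm]),
                       c(1, 1, 2, 2)[perm])
  expect_equal(g2$medians, g$medians)
  expect_error(groupByNetwork(m, c(1, NA, 2, 2)), "without a network")

  set.seed(2)
  x <- RegionalMap(rnorm(30))
  y <- RegionalMap(x@values * 2 + 1)
  expect_equal(associateMaps(x, y)[["estimate"]], 1)
  expect_equal(associateMaps(x, RegionalMap(-x@values))[["estimate"]], -1)
  # spearman on raw values equals pearson on ranks
  z <- RegionalMap(rnorm(30))
  expect_equal(
    associateMaps(x, z, "spearman")[["estimate"]],
    unname(cor(rank(x@values), rank(z@values))), tolerance = 1e-12)
  short <- RegionalMap(c(1, 2, NA))
  expect_error(associateMaps(short, RegionalMap(c(1, NA, 3))), "3 complete")
})
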
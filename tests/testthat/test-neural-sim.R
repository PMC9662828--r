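test_that("firing-rate function is continuous with the right asymptotes", {
  p <- wwParams()
  # removable singularity at a x = b: limit is 1/d
  expect_equal(firingRate(p@b / p@a), 1 / p@d, tolerance = 1e-10)
  # smooth through the singularity
  eps <- 1e-9
  expect_equal(firingRate(p@b / p@a + eps), 1 / p@d, tolerance = 1e-6)
  # near-zero input: direct evaluation of the sigmoid
  expect_equal(firingRate(0), -p@b / (1 - exp(p@d * p@b)),
               tolerance = 1e-10)
  # linear asymptote for large input
  x <- (30 + p@b) / p@a * 2
  expect_lt(abs(firingRate(x) - (p@a * x - p@b)) / (p@a * x - p@b), 1e-6)
  expect_true(all(firingRate(seq(-1, 2, by = 0.01)) >= 0))
})

test_that("uncoupled noiseless simulation settles on the root-finder fixed point", {
  C <- randomConnectome(8, 0.5, seed = 3)
  for (w in c(0, 0.45, 0.8)) {
    p <- wwParams(w = w, G = 0, D = 0)
    sstar <- wwFixedPoint(p)
    tr <- simulateWW(C, p, duration = 8, dt = 0.01, seed = 1)
    expect_equal(unname(tr@states[nrow(tr@states), ]), rep(sstar, 8),
                 tolerance = 1e-6)
  }
})

test_that("simulation traces are deterministic under a fixed seed", {
  C <- randomConnectome(10, 0.4, seed = 2)
  t1 <- simulateWW(C, duration = 2, dt = 0.01, seed = 42)
  t2 <- simulateWW(C, duration = 2, dt = 0.01, seed = 42)
  expect_identical(t1@states, t2@states)
  expect_false(identical(
    t1@states, simulateWW(C, duration = 2, dt = 0.01, seed = 43)@states))
})

test_that("zero delays reproduce the instantaneous path bit-for-bit", {
  C <- randomConnectome(10, 0.4, seed = 2)
  zero <- computeDelays(matrix(0, 10, 3) , speed = 10)
  expect_error(computeDelays(matrix(0, 1, 3)), "two")
  t0 <- simulateWW(C, duration = 1, dt = 0.01, seed = 7)
  tz <- simulateWW(C, duration = 1, dt = 0.01, seed = 7, delays = zero)
  expect_identical(t0@states, tz@states)
  # infinite-speed limit: delays round to zero steps
  fast <- computeDelays(C, speed = 1e9)
  tf <- simulateWW(C, duration = 1, dt = 0.01, seed = 7, delays = fast)
  expect_identical(t0@states, tf@states)
  # finite speed changes the trajectory
  slow <- computeDelays(C, speed = 1)
  ts <- simulateWW(C, duration = 1, dt = 0.01, seed = 7, delays = slow)
  expect_false(identical(t0@states, ts@states))
})

test_that("delay computation follows distance over speed", {
  d <- computeDelays(rbind(c(0, 0, 0), c(10, 0, 0)), speed = 10)
  expect_equal(d@delays[1, 2], 0.001)  # 10 mm at 10 m/s = 1 ms
  same <- computeDelays(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same@delays[1, 2], 0)
  d2 <- computeDelays(rbind(c(0, 0, 0), c(20, 0, 0)), speed = 10)
  expect_equal(d2@delays, d@delays * 2)
})

test_that("response functions rise with recurrent strength", {
  C <- syntheticConnectome(nRegions = 20, density = 0.25, seed = 5)
  rf <- responseFunction(C, wGrid = seq(0, 1, by = 0.05), duration = 20,
                         dt = 0.01, seed = 9)
  expect_s4_class(rf, "ResponseFunction")
  for (i in seq_len(nrow(rf@sBar))) {
    expect_gt(cor(rf@sBar[i, ], rf@wGrid, method = "spearman"), 0.9)
  }
  # uncoupled zero-recurrence mean sits at the low fixed point
  p0 <- wwParams(w = 0, G = 0)
  rf0 <- responseFunction(C, p0, wGrid = c(0, 0.01), duration = 60,
                          dt = 0.01, seed = 2)
  expect_equal(unname(rf0@sBar[, 1]),
               rep(wwFixedPoint(wwParams(w = 0, G = 0)), 20),
               tolerance = 0.01)
})

test_that("identical regions on a complete graph give identical curves", {
  K <- Connectome(matrix(1, 6, 6) - diag(6))
  rf <- responseFunction(K, wGrid = seq(0, 0.6, by = 0.1), duration = 30,
                         dt = 0.01, seed = 3)
  spread <- apply(rf@sBar, 2, function(x) diff(range(x)))
  expect_true(all(spread < 0.02))
})

test_that("time-averaged activity is stable across seeds", {
  C <- syntheticConnectome(nRegions = 15, density = 0.3, seed = 6)
  sbars <- vapply(1:5, function(s) {
    rf <- responseFunction(C, wGrid = c(0.45, 0.46), duration = 120,
                           dt = 0.01, seed = s)
    rf@sBar[, 1]
  }, numeric(15))
  expect_lt(max(apply(sbars, 1, sd)), 0.01)
})

test_that("heterogeneous inputs are linear in the strength rank", {
  # strengths 1 < 3 < 2 across the three regions
  C <- edgesConnectome(3, list(c(1, 2, 1), c(2, 3, 2)))
  s <- unname(nodeStrengths(C))
  expect_equal(s, c(1, 3, 2))
  inp <- unname(heterogeneousInputs(C)@values)
  # linear in ascending rank: weakest 0.33, middle 0.305, strongest 0.28
  expect_equal(inp, c(0.33, 0.28, 0.305), tolerance = 1e-12)
  # equal bounds reduce to the homogeneous model
  expect_equal(heterogeneousInputs(C, 0.33, 0.33)@values, rep(0.33, 3))
  # ties share averaged ranks
  K <- Connectome(matrix(1, 4, 4) - diag(4))
  expect_equal(heterogeneousInputs(K)@values, rep(mean(c(0.33, 0.28)), 4))
  # simulateWW accepts the map in place of I0
  tr <- simulateWW(C, wwParams(D = 0, G = 0), duration = 1, dt = 0.01,
                   iRegional = heterogeneousInputs(C))
  expect_true(all(is.finite(tr@states)))
})

test_that("Wilson-Cowan dynamics settle on the 2-D fixed point and stay bounded", {
  C <- randomConnectome(6, 0.5, seed = 4)
  p <- wcParams(G = 0, DE = 0, DI = 0)
  fp <- wcFixedPoint(p)
  tr <- simulateWC(C, p, duration = 1, dt = 0.001, seed = 1)
  expect_equal(unname(tr@states[nrow(tr@states), ]), rep(fp[["SE"]], 6),
               tolerance = 1e-6)
  expect_equal(unname(tr@extra$SI[nrow(tr@extra$SI), ]),
               rep(fp[["SI"]], 6), tolerance = 1e-6)
  # with noise, states stay clamped in [0, 1]
  trn <- simulateWC(C, wcParams(DE = 0.01, DI = 0.01), duration = 0.5,
                    dt = 0.001, seed = 2)
  expect_true(all(trn@states >= 0 & trn@states <= 1))
})

test_that("a Wilson-Cowan wEE sweep feeds the dynamic-range profile", {
  C <- randomConnectome(8, 0.4, seed = 9)
  rf <- responseFunction(C, wcParams(), wGrid = seq(10, 20, by = 1),
                         duration = 3, dt = 0.001, seed = 1)
  expect_identical(rf@model, "wilson_cowan")
  prof <- drProfile(rf)
  expect_s4_class(prof, "DynamicRangeProfile")
  expect_gte(prof@nDefined, 1)
})

test_that("noiseless Euler tracks a high-accuracy RK4 reference", {
  skip_if_not_installed("deSolve")
  C <- randomConnectome(10, 0.4, seed = 2)
  p <- wwParams(D = 0)
  A <- weights(C)
  rhs <- function(t, S, parms) {
    x <- p@w * p@J * S + p@G * p@J * (A %*% S) + p@I0
    list(-S / p@tauS + p@gammaS * (1 - S) * firingRate(x, p))
  }
  ref <- deSolve::ode(rep(0.001, 10), seq(0, 10, by = 5e-4), rhs, NULL,
                      method = "rk4")
  tr <- simulateWW(C, p, duration = 10, dt = 0.005, seed = 1)
  refAt <- ref[seq(1, nrow(ref), by = 10), -1]
  expect_lt(max(abs(tr@states - refAt)), 1e-3)
})
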
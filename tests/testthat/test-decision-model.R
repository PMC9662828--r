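test_that("a deterministic single accumulator decides at theta over beta", {
  L <- matrix(0, 1, 1)
  res <- simulateDDMTrial(L, ddmParams(D = 0), seed = 1)
  expect_equal(res$decision, "correct")
  expect_equal(res$decisionTime, 1.0)  # theta / beta with dt = 0.01
})

test_that("ensemble accuracy matches the closed-form absorption probability", {
  L <- matrix(0, 1, 1)
  cases <- list(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1))
  for (cs in cases) {
    p <- ddmParams(beta = cs[1], D = cs[2], theta = cs[3], nTrials = 1000)
    ac <- accuracyCurves(L, p, seed = 11)
    pCorrect <- ddmAbsorptionProbability(cs[1], cs[2], cs[3])
    se <- sqrt(pCorrect * (1 - pCorrect) / 1000)
    expect_lt(abs(ac@wholeBrain[length(ac@wholeBrain)] - pCorrect), 3 * se)
  }
})

test_that("an unbiased accumulator is symmetric", {
  L <- matrix(0, 1, 1)
  ac <- accuracyCurves(L, ddmParams(beta = 0, nTrials = 2000), seed = 3)
  res <- conndyn:::ddmEnsemble(L, ddmParams(beta = 0, nTrials = 2000),
                               2000, seed = 3)
  decided <- res$hit_sign[res$hit_sign != 0]
  expect_gt(length(decided), 1500)
  expect_lt(abs(mean(decided == 1) - 0.5), 3 * sqrt(0.25 / length(decided)))
})

test_that("accuracy curves are monotone and permutation invariant", {
  C <- syntheticConnectome(nRegions = 12, density = 0.3, seed = 5)
  L <- graphLaplacian(C)
  ac <- accuracyCurves(L, ddmParams(nTrials = 300), seed = 7)
  expect_true(all(apply(ac@regional, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(ac@regional >= 0 & ac@regional <= 1))
  # relabeling regions permutes regional curves, whole brain unchanged
  perm <- sample(12)
  ac2 <- accuracyCurves(L[perm, perm], ddmParams(nTrials = 300), seed = 7)
  expect_equal(ac2@wholeBrain[length(ac2@wholeBrain)],
               ac@wholeBrain[length(ac@wholeBrain)], tolerance = 0.05)
})

test_that("regions are exchangeable when uncoupled and identical", {
  L <- matrix(0, 4, 4)
  ac <- accuracyCurves(L, ddmParams(nTrials = 1000), seed = 9)
  terminal <- ac@regional[nrow(ac@regional), ]
  p <- ddmAbsorptionProbability()
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(terminal - p) < 4 * se))
})

test_that("accuracy differences are antisymmetric with first-index ties", {
  L <- matrix(0, 2, 2)
  a <- accuracyCurves(L, ddmParams(nTrials = 200), seed = 2)
  d <- accuracyDifference(a, a)
  expect_true(all(d$diff == 0))
  expect_equal(d$tMin, d$t[1])  # first index on ties
  b <- accuracyCurves(L, ddmParams(nTrials = 200), seed = 5)
  dab <- accuracyDifference(a, b)
  dba <- accuracyDifference(b, a)
  expect_equal(dab$diff, -dba$diff)
  short <- new("AccuracyCurve", t = a@t[1:10],
               regional = a@regional[1:10, , drop = FALSE],
               wholeBrain = a@wholeBrain[1:10], nTrials = 200L,
               labels = a@labels)
  expect_error(accuracyDifference(a, short), "time grid")
})

test_that("absorbed regions can be clamped or left diffusing", {
  C <- syntheticConnectome(nRegions = 8, density = 0.4, seed = 6)
  L <- graphLaplacian(C)
  acClamp <- accuracyCurves(L, ddmParams(nTrials = 200), seed = 4,
                            absorb = "clamp")
  acFree <- accuracyCurves(L, ddmParams(nTrials = 200), seed = 4,
                           absorb = "free")
  expect_s4_class(acFree, "AccuracyCurve")
  # both estimate the same process; terminal accuracies stay close
  expect_lt(abs(acClamp@wholeBrain[length(acClamp@wholeBrain)] -
                acFree@wholeBrain[length(acFree@wholeBrain)]), 0.1)
})

test_that("self-coupling lambda speeds decisions and inhibition slows them", {
  C <- syntheticConnectome(nRegions = 10, density = 0.3, seed = 8)
  L <- graphLaplacian(C)
  p <- ddmParams(nTrials = 400)
  meanTime <- function(lam, seed) {
    res <- conndyn:::ddmEnsemble(L, initialize(p, lam = lam), 400, seed)
    mean(res$hit_step[res$hit_step > 0]) * p@dt
  }
  tExc <- meanTime(1.5, 3)
  t0 <- meanTime(0, 3)
  expect_lt(tExc, t0)  # excitation shortens decision times
  # inhibition lowers early whole-brain accuracy on the same seed ladder
  accAt <- function(lam, tIdx) {
    ac <- accuracyCurves(L, initialize(p, lam = lam), seed = 3)
    ac@wholeBrain[tIdx]
  }
  expect_lt(accAt(-1.5, 100), accAt(0, 100))  # t = 1 s
})

test_that("matchExcitation finds the smallest sufficient lambda", {
  C <- syntheticConnectome(nRegions = 10, density = 0.3, seed = 8)
  L <- graphLaplacian(C)
  p <- ddmParams(nTrials = 300)
  same <- matchExcitation(L, L, p, lamGrid = c(0, 0.5, 1), tRef = 2,
                          seed = 6)
  expect_equal(same$lambdaStar, 0)  # A = B needs no extra excitation
  # an unattainable target is reported, not invented
  hard <- matchExcitation(L, L, initialize(p, lam = 0),
                          lamGrid = c(-3, -2.5), tRef = 0.5, seed = 6)
  expect_true(is.na(hard$lambdaStar))
  expect_true(is.finite(hard$achieved))
})

test_that("network accuracy aggregates regional curves consistently", {
  C <- syntheticConnectome(nRegions = 12, density = 0.3, seed = 5)
  part <- networkPartition(C)
  ac <- accuracyCurves(C, ddmParams(nTrials = 200), seed = 1)
  # single-network partition equals the whole-brain curve
  expect_equal(networkAccuracy(ac, rep(1L, 12), 1), ac@wholeBrain)
  # one-region network equals that region's curve
  solo <- c(2L, rep(1L, 11))
  expect_equal(networkAccuracy(ac, solo, 2), unname(ac@regional[, 1]))
  # size-weighted mean over networks reconstructs the whole-brain curve
  sizes <- table(part)
  weighted <- Reduce(`+`, lapply(names(sizes), function(k) {
    networkAccuracy(ac, part, as.integer(k)) * sizes[[k]]
  })) / sum(sizes)
  expect_equal(weighted, ac@wholeBrain, tolerance = 1e-12)
  expect_error(networkAccuracy(ac, part, 999L), "unknown network")
})

test_that("Laplacian input is validated", {
  notL <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_error(accuracyCurves(notL, ddmParams(nTrials = 10)), "sum")
})
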
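test_that("dense round trip is bit-identical and edge lists symmetrize", {
  C <- syntheticConnectome(nRegions = 15, density = 0.3, seed = 2)
  f <- tempfile(fileext = ".csv")
  writeConnectome(C, f, format = "dense_csv")
  C2 <- readConnectome(f, format = "dense_csv")
  expect_identical(unname(weights(C2)), unname(weights(C)))

  el <- tempfile()
  writeLines(c("A B 2.0", "B C 1.0"), el)
  Ce <- readConnectome(el, format = "edge_list")
  expect_equal(regionLabels(Ce), c("A", "B", "C"))
  expect_equal(weights(Ce)["A", "B"], 2)
  expect_equal(weights(Ce)["B", "A"], 2)
  expect_equal(weights(Ce)["C", "B"], 1)

  # sidecar label round trip
  lf <- tempfile(fileext = ".csv")
  writeConnectome(C, f, format = "dense_csv", labelsPath = lf)
  C3 <- readConnectome(f, format = "dense_csv", labelsPath = lf)
  expect_identical(regionLabels(C3), regionLabels(C))
  expect_identical(hemisphere(C3), hemisphere(C))
  expect_equal(centroids(C3), unname(centroids(C)), ignore_attr = TRUE)
})

test_that("malformed dense input is rejected with a located error", {
  f <- tempfile()
  writeLines(c("0,1,2", "1,0,3"), f)          # non-square
  expect_error(readConnectome(f, "dense_csv"), "square")
  writeLines(c("0,1", "NaN,0"), f)            # NaN named by position
  expect_error(readConnectome(f, "dense_csv"), "row 2, column 1")
  writeLines(c("0,-1", "-1,0"), f)            # negative weight
  expect_error(readConnectome(f, "dense_csv"), "negative")
  writeLines(c("0,1,0", "0,0,1", "0,0,0"), f) # asymmetric without flag
  expect_error(readConnectome(f, "dense_csv"), "directed")
  expect_s4_class(readConnectome(f, "dense_csv", directed = TRUE),
                  "Connectome")
})

test_that("an all-zero dense matrix is a valid empty connectome", {
  f <- tempfile()
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), f)
  C <- readConnectome(f, "dense_csv")
  expect_equal(edgeDensity(C), 0)
})

test_that("max-normalization scales correctly and is idempotent", {
  C <- edgesConnectome(3, list(c(1, 2, 2), c(2, 3, 4)))
  Cn <- normalizeByMax(C)
  expect_equal(sort(unique(weights(Cn)[weights(Cn) > 0])), c(0.5, 1))
  expect_identical(weights(normalizeByMax(Cn)), weights(Cn))
  C1 <- edgesConnectome(2, list(c(1, 2, 7)))
  expect_equal(max(weights(normalizeByMax(C1))), 1)
  expect_error(normalizeByMax(Connectome(matrix(0, 2, 2))), "all-zero")
})

test_that("consistency-thresholded group average follows the stated rule", {
  mk <- function(w12, w13) edgesConnectome(3, list(c(1, 2, w12),
                                                   c(1, 3, w13)))
  coh <- list(mk(2, 1), mk(4, 1), mk(0, 1))
  g <- groupAverage(coh, consistency = 0.6)
  # edge present in 2/3 >= 0.6: mean over possessing subjects = (2+4)/2
  expect_equal(weights(g)[1, 2], 3)
  coh2 <- list(mk(5, 1), mk(0, 1), mk(0, 1))
  expect_equal(weights(groupAverage(coh2, 0.6))[1, 2], 0)  # 1/3 < 0.6
  # averaging over all subjects is available as the alternative convention
  expect_equal(weights(groupAverage(coh, 0.6, includeZeros = TRUE))[1, 2], 2)
  # identical subjects: any consistency returns any single subject
  same <- list(mk(2, 3), mk(2, 3), mk(2, 3))
  for (cons in c(0.2, 0.6, 1)) {
    expect_equal(weights(groupAverage(same, cons)), weights(same[[1]]))
  }
  expect_error(groupAverage(list(mk(1, 1), triangleConnectome())), "labels")
})

test_that("nonzero averaging ignores absent subjects per edge", {
  mk <- function(w) edgesConnectome(3, list(c(1, 2, w), c(2, 3, 1)))
  coh <- list(mk(2), mk(0), mk(4))
  g <- averageNonzero(coh)
  expect_equal(weights(g)[1, 2], 3)
  expect_equal(weights(averageNonzero(list(mk(2))))[1, 2], 2)  # identity
  zero <- edgesConnectome(3, list(c(2, 3, 1)))
  expect_equal(weights(averageNonzero(list(zero, zero)))[1, 2], 0)
})

test_that("density matching keeps the strongest edges and is idempotent", {
  set.seed(42)
  C <- randomConnectome(12, 0.5, seed = 6)
  w <- weights(C)
  m <- sum(w[upper.tri(w)] > 0)
  target <- 5 / (12 * 11 / 2)
  Cm <- matchDensity(C, target)
  wm <- weights(Cm)
  kept <- wm[upper.tri(wm)][wm[upper.tri(wm)] > 0]
  expect_length(kept, 5)
  # sort oracle: the 5 strongest survive
  expect_setequal(kept, sort(w[upper.tri(w)], decreasing = TRUE)[1:5])
  # idempotence at the achieved density
  expect_identical(weights(matchDensity(Cm, target)), wm)
  # unchanged at current density
  expect_identical(weights(matchDensity(C, edgeDensity(C))), w)
  expect_error(matchDensity(Cm, 0.9), "exceeds")
})

test_that("density matching breaks weight ties deterministically", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 4] <- w[4, 2] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.5
  C <- Connectome(w)
  target <- 2 / 6
  Cm1 <- matchDensity(C, target)
  Cm2 <- matchDensity(C, target)
  expect_identical(weights(Cm1), weights(Cm2))
  expect_equal(sum(weights(Cm1) > 0) / 2, 2)
  expect_equal(weights(Cm1)[1, 2], 1)              # strongest always kept
  expect_equal(weights(Cm1)[1, 3], 0.5)            # earliest-indexed tie
})

test_that("edge classification is exact set algebra with swap symmetry", {
  C1 <- edgesConnectome(4, list(c(1, 2, 1), c(2, 3, 2)))   # ab, bc
  C2 <- edgesConnectome(4, list(c(2, 3, 3), c(3, 4, 1)))   # bc, cd
  cl <- classifyConnections(C1, C2)
  expect_equal(nrow(cl@shared), 1)
  expect_equal(cl@shared$w1, 2)
  expect_equal(cl@shared$w2, 3)
  expect_equal(nrow(cl@specific1), 1)
  expect_equal(nrow(cl@specific2), 1)
  # swapping arguments swaps the specific sets exactly
  cl2 <- classifyConnections(C2, C1)
  expect_identical(cl2@specific1, cl@specific2)
  expect_identical(cl2@specific2, cl@specific1)
  # identical connectomes: no specifics, perfectly correlated weights
  C <- randomConnectome(15, 0.3, seed = 3)
  cs <- classifyConnections(C, C)
  expect_equal(nrow(cs@specific1), 0)
  expect_equal(cor(cs@shared$w1, cs@shared$w2), 1)
  # intrahemispheric fractions come from hemisphere labels
  Ch <- syntheticConnectome(nRegions = 16, density = 0.4, seed = 3)
  cl3 <- classifyConnections(Ch, matchDensity(Ch, 0.25))
  expect_true(is.finite(cl3@intraFrac1))
  expect_gte(cl3@intraFrac1, 0)
  expect_lte(cl3@intraFrac1, 1)
})

test_that("variability rescaling multiplies by the SD ratio edge-wise", {
  C <- edgesConnectome(2, list(c(1, 2, 0.4)))
  sdS <- matrix(0.2, 2, 2); sdO <- matrix(0.1, 2, 2)
  expect_equal(weights(rescaleByVariability(C, sdS, sdO))[1, 2], 0.2)
  expect_equal(weights(rescaleByVariability(C, sdS, sdS)), weights(C))
  expect_warning(
    out <- rescaleByVariability(C, matrix(0, 2, 2), sdO), "zero SD")
  expect_equal(weights(out), weights(C))
  expect_error(rescaleByVariability(C, matrix(1, 3, 3), sdO), "shape")
})

test_that("subsampled group averages are reproducible and exact at full n", {
  coh <- syntheticCohort(8, variability = 0.4, dropFraction = 0.15,
                         seed = 11, nRegions = 20, density = 0.3)
  full <- groupAverage(coh, 0.6)
  subs <- subsampleGroup(coh, n = 8, nTrials = 3, seed = 1)
  for (s in subs) expect_equal(weights(s), weights(full))
  s1 <- subsampleGroup(coh, n = 4, nTrials = 5, seed = 2)
  s2 <- subsampleGroup(coh, n = 4, nTrials = 5, seed = 2)
  expect_identical(lapply(s1, weights), lapply(s2, weights))
  one <- subsampleGroup(coh, n = 1, nTrials = 2, seed = 3)
  expect_true(all(vapply(one, function(x) {
    any(vapply(coh, function(y) identical(weights(x), weights(y)),
               logical(1)))
  }, logical(1))))
  expect_error(subsampleGroup(coh, n = 9), "exceeds")
})

test_that("graph Laplacian is strength-diagonal minus adjacency", {
  C2 <- edgesConnectome(2, list(c(1, 2, 1)))
  expect_equal(unname(graphLaplacian(C2)),
               matrix(c(1, -1, -1, 1), 2, 2))
  Ls <- graphLaplacian(starConnectome())
  expect_equal(unname(diag(Ls)), c(3, 1, 1, 1))
  C <- randomConnectome(20, 0.3, seed = 4)
  expect_equal(max(abs(graphLaplacian(C) %*% rep(1, 20))), 0,
               tolerance = 1e-12)
})
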
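# Small graphs built in code, used across test files.

# unit-weight triangle
triangleConnectome <- function() {
  w <- matrix(1, 3, 3); diag(w) <- 0
  Connectome(w, regionLabels = c("a", "b", "c"))
}

# star K_{1,3}, hub first
starConnectome <- function() {
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- 1; w[2:4, 1] <- 1
  Connectome(w)
}

# 3-node chain a-b-c with unit weights
chainConnectome <- function(weight = 1) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- weight
  w[2, 3] <- w[3, 2] <- weight
  Connectome(w)
}

# random connected weighted graph (for oracle comparisons)
randomConnectome <- function(n = 20, density = 0.3, seed = 1) {
  syntheticConnectome(nRegions = n, density = density, seed = seed,
                      hemispheres = FALSE, nModules = 2)
}

# build a connectome from an explicit upper-triangle edge list
edgesConnectome <- function(n, edges) {
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- w[e[2], e[1]] <- e[3]
  }
  Connectome(w)
}

# independent all-pairs shortest paths (Floyd-Warshall on 1/weight)
floydWarshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# brute-force Onnela clustering by enumerating all triples
bruteClustering <- function(w) {
  wn <- w / max(w)
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(wn[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        j <- nb[a]; l <- nb[b]
        s <- s + (wn[i, j] * wn[j, l] * wn[i, l])^(1 / 3)
      }
    }
    s / (k * (k - 1))
  }, numeric(1))
}
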
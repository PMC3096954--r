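# Shared fixtures and independent oracles used across test files.

# random gene-by-sample matrix with ids
randomMatrix <- function(nGenes, nSamples, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, sd = sd), nGenes, nSamples,
         dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                         sprintf("s%03d", seq_len(nSamples))))
}

# naive O(n^3) UPGMA on a distance matrix: returns merge heights and the
# leaf sets of every internal node (order-free representation)
naiveUPGMA <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  leafSets <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      if (d[a, b] < bh) { bh <- d[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    newIdx <- nrow(d) + 1
    merged <- c(clusters[[a]], clusters[[b]])
    clusters[[newIdx]] <- merged
    sizes[newIdx] <- sizes[a] + sizes[b]
    # average linkage: size-weighted mean of distances
    newRow <- rep(Inf, newIdx)
    for (k in active) if (k != a && k != b)
      newRow[k] <- (sizes[a] * d[a, k] + sizes[b] * d[b, k]) /
        (sizes[a] + sizes[b])
    d <- rbind(cbind(d, Inf), Inf)
    d[newIdx, seq_len(newIdx - 1)] <- newRow[seq_len(newIdx - 1)]
    d[seq_len(newIdx - 1), newIdx] <- newRow[seq_len(newIdx - 1)]
    active <- c(setdiff(active, c(a, b)), newIdx)
    heights <- c(heights, bh)
    leafSets[[length(leafSets) + 1]] <- sort(merged)
  }
  list(heights = heights, leafSets = leafSets)
}

# Breslow partial log-likelihood for a single binary/numeric covariate
breslowLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    dead <- which(time == t & event == 1)
    atRisk <- which(time >= t)
    ll <- ll + sum(x[dead]) * beta -
      length(dead) * log(sum(exp(x[atRisk] * beta)))
  }
  ll
}

# leaf sets of all subtrees of a GeneDendrogram (for brute-force checks)
allSubtreeLeafSets <- function(dend) {
  m <- dend@merge
  labs <- dend@labels
  out <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    stack <- k; leaves <- integer()
    while (length(stack)) {
      node <- stack[[1]]; stack <- stack[-1]
      for (ch in m[node, ]) {
        if (ch < 0) leaves <- c(leaves, -ch) else stack <- c(stack, ch)
      }
    }
    out[[k]] <- sort(labs[leaves])
  }
  out
}
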
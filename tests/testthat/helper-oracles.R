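# Independent oracles kept deliberately naive: brute-force summation,
# quadrature on fine grids, and direct pair counting.  They never share a
# code path with the implementation they check.

# naive digit sum by repeated division
naiveDigitSum <- function(i, k) {
  s <- 0
  while (i > 0) { s <- s + i %% k; i <- i %/% k }
  s
}

# naive S_k(n) = sum of naive digit sums
naiveSumsOfDigits <- function(n, k) {
  if (n == 0) return(0)
  sum(vapply(0:(n - 1), naiveDigitSum, numeric(1), k = k))
}

# midpoint-rule quadrature of the step integrand of the one-level Delange
# integral (independent of the closed-form segment evaluation)
quadD0 <- function(x, k, m = 2e5) {
  t <- seq(0, x, length.out = m + 1)
  t <- (t[-1] + t[-(m + 1)]) / 2
  sum(2 * k * floor(t) - 2 * floor(k * t) + k - 1) * (x / m)
}

# direct partial sum of the Delange series
partialDelange <- function(x, k, terms = 60) {
  sum(vapply(0:(terms - 1),
             function(n) delangeD0(k^n * x, k) / k^n, numeric(1)))
}

# direct O(n^2) induced edge count by pairwise Hamming distance
pairwiseEdgeCount <- function(vertices, space) {
  if (length(vertices) < 2) return(0)
  g <- vertexToGenotype(vertices, space)
  cnt <- 0
  for (i in seq_along(g)[-1]) for (j in seq_len(i - 1)) {
    d <- sum(strsplit(g[i], "")[[1]] != strsplit(g[j], "")[[1]])
    if (d == 1) cnt <- cnt + 1
  }
  cnt
}

# merged-pair robustness recomputed from raw edge counts of two sets
mergedRhoFromEdges <- function(a, b, space) {
  n <- length(a) + length(b)
  e <- inducedEdgeCount(a, space) + inducedEdgeCount(b, space) +
    crossEdgeCount(a, b, space)
  2 * e / (hammingDegree(space) * n)
}
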
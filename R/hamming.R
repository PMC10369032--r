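## Hamming-graph combinatorics.  Vertices are integer labels 0..k^l-1 in
## base-k reading of the genotype string (position 1 = most significant
## digit).  Edges are never materialised for whole spaces except where a
## full streaming pass is itself the computation.

checkVertices <- function(v, space) {
  N <- nGenotypes(space)
  if (anyNA(v) || any(v < 0) || any(v >= N) || any(v != round(v)))
    stop("vertex labels must be integers in [0, k^l)")
  v
}

#' Convert between integer vertex labels and genotype strings
#'
#' Mutually inverse bijections between the canonical integer labels of a
#' [GenotypeSpace-class] and genotype strings.  The first string position is
#' the most-significant base-k digit; the i-th symbol of the space's
#' alphabet represents digit i-1.
#'
#' @param v integer vertex label(s) in \eqn{[0, k^\ell)}.
#' @param sequence genotype string(s) of length \eqn{\ell} over the space's
#'   alphabet.
#' @param space a [GenotypeSpace-class].
#' @return `vertexToGenotype`: character vector; `genotypeToVertex`:
#'   numeric vector of integer labels.
#' @examples
#' sp <- GenotypeSpace(2, 3)
#' vertexToGenotype(5, sp)      # "101"
#' genotypeToVertex("101", sp)  # 5
#' @export
vertexToGenotype <- function(v, space) {
  v <- checkVertices(v, space)
  k <- space@k; l <- space@length
  out <- matrix("", nrow = l, ncol = length(v))
  for (p in seq_len(l)) {           # p = 1 is most significant
    pw <- k^(l - p)
    out[p, ] <- space@symbols[(v %/% pw) %% k + 1]
  }
  apply(out, 2, paste, collapse = "")
}

#' @rdname vertexToGenotype
#' @export
genotypeToVertex <- function(sequence, space) {
  k <- space@k; l <- space@length
  if (any(nchar(sequence) != l))
    stop("genotype strings must have length ", l)
  chars <- strsplit(sequence, "", fixed = TRUE)
  vapply(chars, function(cs) {
    d <- match(cs, space@symbols) - 1
    if (anyNA(d)) stop("unknown symbol in genotype: ",
                       paste(cs[is.na(d)], collapse = ""))
    sum(d * k^((l - 1):0))
  }, numeric(1))
}

#' Single-mutation neighbours of a vertex
#'
#' Returns the \eqn{\ell(k-1)} vertex labels whose genotypes differ from
#' `v` at exactly one position.
#'
#' @param v a single vertex label.
#' @param space a [GenotypeSpace-class].
#' @return sorted numeric vector of \eqn{\ell(k-1)} labels.
#' @examples
#' hammingNeighbors(0, GenotypeSpace(2, 3))  # 1 2 4
#' @export
hammingNeighbors <- function(v, space) {
  if (length(v) != 1L) stop("'v' must be a single label")
  checkVertices(v, space)
  sort(neighborMatrix(v, space)[1L, ])
}

## All neighbours of a vector of vertices as an m x l(k-1) matrix.
## Column-blocks: position p (1..l), digit offset s (1..k-1).
neighborMatrix <- function(v, space) {
  k <- space@k; l <- space@length
  out <- matrix(0, nrow = length(v), ncol = l * (k - 1))
  col <- 0L
  for (p in seq_len(l)) {
    pw <- k^(l - p)
    d <- (v %/% pw) %% k
    for (s in seq_len(k - 1)) {
      col <- col + 1L
      out[, col] <- v + (((d + s) %% k) - d) * pw
    }
  }
  out
}

#' Count edges inside and between vertex sets
#'
#' `inducedEdgeCount` counts the edges of the subgraph of the Hamming graph
#' induced by a vertex set (each unordered within-set pair once).
#' `crossEdgeCount` counts edges with one endpoint in each of two disjoint
#' sets (each unordered cross pair once).  Both stream over neighbours and
#' never materialise the ambient edge set.
#'
#' @param vertices,a,b numeric vectors of vertex labels; `a` and `b` must
#'   be disjoint.
#' @param space a [GenotypeSpace-class].
#' @return a single non-negative count.
#' @examples
#' sp <- GenotypeSpace(2, 3)
#' inducedEdgeCount(0:7, sp)      # 12 edges of the 3-cube
#' crossEdgeCount(0, 1, sp)       # 1
#' @export
inducedEdgeCount <- function(vertices, space) {
  vertices <- unique(checkVertices(vertices, space))
  if (length(vertices) < 2L) return(0)
  member <- logical(nGenotypes(space))
  member[vertices + 1] <- TRUE
  nb <- neighborMatrix(vertices, space)
  sum(member[nb + 1] & nb > vertices) # each edge counted from its lower end
}

#' @rdname inducedEdgeCount
#' @export
crossEdgeCount <- function(a, b, space) {
  a <- unique(checkVertices(a, space))
  b <- unique(checkVertices(b, space))
  if (length(intersect(a, b))) stop("'a' and 'b' must be disjoint")
  inB <- logical(nGenotypes(space))
  inB[b + 1] <- TRUE
  nb <- neighborMatrix(a, space)
  sum(inB[nb + 1])
}

#' Neutral components of a vertex set
#'
#' Partitions a vertex set into its maximal subsets connected by
#' single-character mutations (the neutral components of a neutral set).
#' Components are returned sorted by their smallest vertex label, each
#' component's members ascending, so output is deterministic.
#'
#' @param vertices numeric vector of vertex labels.
#' @param space a [GenotypeSpace-class].
#' @return list of numeric vectors partitioning `vertices`.
#' @examples
#' sp <- GenotypeSpace(2, 2)
#' neutralComponents(c(0, 3), sp)  # two singletons: opposite corners
#' @export
neutralComponents <- function(vertices, space) {
  vertices <- sort(unique(checkVertices(vertices, space)))
  if (!length(vertices)) return(list())
  member <- logical(nGenotypes(space))
  member[vertices + 1] <- TRUE
  nb <- neighborMatrix(vertices, space)
  keep <- member[nb + 1]
  from <- rep(vertices, ncol(nb))[keep]
  to <- nb[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(vertices)))
  comp <- igraph::components(g)$membership
  parts <- unname(split(as.numeric(names(comp)), comp))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

#' Bricklayer's graph on the first n vertices
#'
#' The bricklayer's graph \eqn{G_{n,k}} is the subgraph of \eqn{H_{\ell,k}}
#' induced by the integer labels \eqn{\{0, \dots, n-1\}} -- the way a
#' bricklayer would fill the Hamming graph row by row.  Among all n-vertex
#' induced subgraphs it attains the maximum edge count, which equals the
#' sums-of-digits value \eqn{S_k(n)}; the edge count returned here is
#' obtained by direct neighbour counting, so equality with
#' [sumsOfDigits()] is a non-trivial cross-check (exercised in the tests).
#'
#' @param n number of vertices, \eqn{0 \le n \le k^\ell}.
#' @param space a [GenotypeSpace-class].
#' @return list with `space`, `n`, `vertices` and the directly counted
#'   `edgeCount`.
#' @examples
#' bricklayerGraph(5, GenotypeSpace(2, 3))$edgeCount  # 5 = S_2(5)
#' @export
bricklayerGraph <- function(n, space) {
  n <- checkCount(n, "n")
  if (n > nGenotypes(space)) stop("'n' exceeds the number of genotypes")
  vertices <- if (n > 0) 0:(n - 1) else numeric(0)
  edges <- if (n > 1) inducedEdgeCount(vertices, space) else 0
  structure(list(space = space, n = n, vertices = vertices,
                 edgeCount = edges),
            class = "bricklayerGraph")
}

#' @export
print.bricklayerGraph <- function(x, ...) {
  cat(sprintf("Bricklayer's graph G_{n,k}: n = %d on H_{%d,%d}, %d edges\n",
              as.integer(x$n), as.integer(x$space@length),
              as.integer(x$space@k), as.integer(x$edgeCount)))
  invisible(x)
}

#' Exhaustive maximum edge count over all n-subsets
#'
#' Brute-force oracle for the edge-isoperimetric optimum: enumerates every
#' n-subset of the Hamming graph's vertices and returns the maximum induced
#' edge count.  Refuses (with an error) rather than sampling when
#' \eqn{\binom{k^\ell}{n}} exceeds `budget`, so the oracle is exact or
#' absent.
#'
#' @param n subset size.
#' @param space a [GenotypeSpace-class] (small!).
#' @param budget maximum number of subsets to enumerate (default \eqn{10^7}).
#' @return maximum induced edge count over all n-subsets.
#' @examples
#' maxEdgesBruteForce(5, GenotypeSpace(2, 3))  # 5
#' @export
maxEdgesBruteForce <- function(n, space, budget = 1e7) {
  n <- checkCount(n, "n")
  N <- nGenotypes(space)
  if (n > N) stop("'n' exceeds the number of genotypes")
  if (choose(N, n) > budget)
    stop("enumeration budget exceeded: choose(", N, ", ", n, ") > ", budget,
         call. = FALSE)
  if (n < 2) return(0)
  adj <- adjacencyMatrix(space)
  best <- 0
  ## lexicographic subset enumeration
  subsets <- utils::combn(N, n)
  for (j in seq_len(ncol(subsets))) {
    s <- subsets[, j]
    e <- sum(adj[s, s]) / 2
    if (e > best) best <- e
  }
  best
}

## dense 0/1 adjacency of a small Hamming graph (vertex i+1 <-> label i)
adjacencyMatrix <- function(space) {
  N <- nGenotypes(space)
  if (N > 4096) stop("adjacency matrix only for small spaces")
  v <- 0:(N - 1)
  nb <- neighborMatrix(v, space)
  adj <- matrix(0L, N, N)
  adj[cbind(rep(v + 1, ncol(nb)), as.vector(nb) + 1)] <- 1L
  adj
}

## full edge list (u < v) of a Hamming space, as a 2-column matrix;
## used by transition-matrix construction on complete GP maps.
hammingEdges <- function(space) {
  N <- nGenotypes(space)
  v <- 0:(N - 1)
  nb <- neighborMatrix(v, space)
  keep <- nb > v
  cbind(rep(v, ncol(nb))[keep], nb[keep])
}
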
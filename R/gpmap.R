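## Analysis of complete GP maps: per-phenotype statistics with
## bound-attainment flags, the phenotype transition matrix, the
## multi-component deviation table, and the two map generators (random
## null, bricklayer-packed) used as study fixtures.

#' Per-phenotype neutral-set and neutral-component statistics
#'
#' For every phenotype of a complete [GPMap-class]: neutral-set size
#' \eqn{n_p}, frequency \eqn{f_p}, induced edge count, robustness
#' \eqn{\rho_p = 2|E|/(\ell(k-1)n_p)}, number of neutral components, and
#' per-component statistics with attainment flags.  A component *attains
#' the maximum* when its edge count equals the sums-of-digits value
#' \eqn{S_k(n)} (decided by exact integer comparison, never floats) and
#' *attains the minimum* when it has \eqn{n - 1} edges, the fewest any
#' connected graph allows.
#'
#' @param map a [GPMap-class].
#' @return data.frame (one row per phenotype, canonical label order) with
#'   columns `label`, `n`, `f`, `edges`, `rho`, `n_components`, and a
#'   list-column `components` of per-component data.frames with columns
#'   `size`, `edges`, `rho`, `attains_max`, `attains_min`.
#' @examples
#' sp <- GenotypeSpace(2, 3)
#' m <- bricklayerPackedMap(sp, c(5, 3))
#' phenotypeStats(m)[, c("label", "n", "rho")]
#' @export
phenotypeStats <- function(map) {
  space <- map@space
  deg <- hammingDegree(space)
  rows <- lapply(map@labels, function(lab) {
    v <- neutralSet(map, lab)
    comps <- neutralComponents(v, space)
    cstat <- data.frame(
      size = vapply(comps, length, numeric(1)),
      edges = vapply(comps, inducedEdgeCount, numeric(1), space = space))
    cstat$rho <- ifelse(cstat$size > 0,
                        2 * cstat$edges / (deg * cstat$size), 0)
    cstat$attains_max <- cstat$edges == sumsOfDigits(cstat$size, space@k)
    cstat$attains_min <- cstat$edges == cstat$size - 1
    edges <- sum(cstat$edges)
    data.frame(label = lab, n = length(v), f = length(v) / nGenotypes(space),
               edges = edges, rho = 2 * edges / (deg * length(v)),
               n_components = nrow(cstat),
               components = I(list(cstat)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$label
  names(out$components) <- out$label
  out
}

#' Phenotype transition matrix of a complete GP map
#'
#' Builds the [TransitionMatrix-class] whose off-diagonal entries are the
#' single-mutation transition probabilities
#' \eqn{\phi_{ts} = |E(G_s, G_t)| / (\ell(k-1)|V_s|)} and whose diagonal
#' is the phenotype robustness \eqn{\rho_s} (within-set edges counted
#' twice, once per direction).  Because the map is total, every mutation
#' lands on some phenotype and columns sum to one exactly.
#'
#' @param map a [GPMap-class].
#' @return a [TransitionMatrix-class] in canonical label order.
#' @examples
#' sp <- GenotypeSpace(2, 2)
#' tm <- transitionMatrix(GPMap(sp, c("A", "A", "B", "B")))
#' transitionProbs(tm)   # all entries 1/2
#' @export
transitionMatrix <- function(map) {
  space <- map@space
  labs <- map@labels
  deg <- hammingDegree(space)
  sizes <- vapply(labs, function(l) sum(map@assignment == l), numeric(1))
  edges <- hammingEdges(space)
  pu <- factor(map@assignment[edges[, 1] + 1], levels = labs)
  pv <- factor(map@assignment[edges[, 2] + 1], levels = labs)
  counts <- table(pu, pv)                       # edge counted once (u < v)
  cross <- unclass(counts + t(counts))          # symmetric; diag = 2|E(G_s)|
  phi <- sweep(cross, 2, deg * sizes, "/")
  dimnames(phi) <- list(labs, labs)
  newTransitionMatrix(space, stats::setNames(sizes / nGenotypes(space), labs),
                      phi)
}

#' Deviation of each phenotype from the single-component maximum
#'
#' For each phenotype, compares the actual robustness deficit
#' \deqn{LHS = \rho^{max}(n_p) - \frac{1}{n_p}\sum_i n_i\,\rho(A_i)}
#' (components \eqn{A_i} with their measured robustness) against the
#' theoretical lower bound on that deficit from
#' [multicomponentDeviationBound()].  The bound is proven for phenotypes
#' with at most `k` components (`proven = TRUE`); rows with more components
#' evaluate the same expression from the `k-1` smallest components and are
#' flagged unproven.
#'
#' @param map a [GPMap-class].
#' @return data.frame with columns `label`, `n`, `m`, `lhs`, `rhs`,
#'   `proven`, `holds` (`lhs >= rhs`, meaningful where proven).
#' @export
deviationTable <- function(map) {
  stats <- phenotypeStats(map)
  space <- map@space
  rows <- lapply(seq_len(nrow(stats)), function(i) {
    cs <- stats$components[[i]]
    n <- stats$n[i]
    lhs <- rhoMax(n, space) - sum(cs$size * cs$rho) / n
    b <- multicomponentDeviationBound(cs$size, space)
    data.frame(label = stats$label[i], n = n, m = b$m,
               lhs = lhs, rhs = b$bound, proven = b$proven,
               holds = lhs >= b$bound - 1e-12)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$label
  out
}

#' Generate a random-null GP map
#'
#' Genotypes are attributed to phenotypes uniformly at random under the
#' constraint that the neutral-set sizes are fixed: the vertex labels are
#' randomly permuted and cut into consecutive blocks of the requested
#' sizes.  This is the null ensemble in which robustness scales with
#' frequency (\eqn{\rho_p \approx f_p}).
#'
#' @param space a [GenotypeSpace-class].
#' @param sizes positive integers summing to \eqn{k^\ell}; block `j` is
#'   labelled `P<j>`.
#' @param seed integer seed; required, so that every generated map is
#'   reproducible.  The caller's RNG state is left untouched.
#' @return a [GPMap-class].
#' @examples
#' randomNullMap(GenotypeSpace(2, 3), c(4, 4), seed = 7)
#' @export
randomNullMap <- function(space, sizes, seed) {
  sizes <- checkCount(sizes, "sizes", min = 1)
  if (missing(seed)) stop("'seed' is required")
  seed <- checkCount(seed, "seed")  # force now: the caller's RNG state is
                                    # snapshotted next, and evaluating a
                                    # lazy seed expression after that would
                                    # be undone by the restore
  N <- nGenotypes(space)
  if (sum(sizes) != N)
    stop("sizes must sum to k^l = ", N, " (got ", sum(sizes), ")")
  perm <- withPrivateSeed(seed, sample.int(N))   # vertices 1..N shuffled
  assignment <- character(N)
  labels <- paste0("P", seq_along(sizes))
  offset <- 0
  for (j in seq_along(sizes)) {
    assignment[perm[offset + seq_len(sizes[j])]] <- labels[j]
    offset <- offset + sizes[j]
  }
  GPMap(space, assignment)
}

## run expr under a local RNG seed, restoring the caller's state
withPrivateSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a bricklayer-packed GP map
#'
#' Phenotype blocks occupy consecutive integer vertex labels: block `j`
#' covers \eqn{[o_j, o_j + size_j)} with \eqn{o_j = \sum_{i<j} size_i}.
#' The first block is exactly the bricklayer's graph \eqn{G_{n,k}} and
#' therefore attains the maximum robustness for its size; later blocks are
#' translated intervals and respect (but need not attain) the bound.
#'
#' @inheritParams randomNullMap
#' @return a [GPMap-class].
#' @examples
#' m <- bricklayerPackedMap(GenotypeSpace(2, 3), c(5, 3))
#' phenotypeStats(m)[1, "rho"]  # 2/3 = rhoMax(5, .)
#' @export
bricklayerPackedMap <- function(space, sizes) {
  sizes <- checkCount(sizes, "sizes", min = 1)
  N <- nGenotypes(space)
  if (sum(sizes) != N)
    stop("sizes must sum to k^l = ", N, " (got ", sum(sizes), ")")
  assignment <- rep(paste0("P", seq_along(sizes)), times = sizes)
  GPMap(space, assignment)
}
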
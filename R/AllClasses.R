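#' @import methods
NULL

#' GenotypeSpace: the Hamming graph of all sequences
#'
#' A `GenotypeSpace` describes the Hamming graph \eqn{H_{\ell,k}} whose
#' vertices are all \eqn{k^\ell} sequences of length \eqn{\ell} over a
#' \eqn{k}-letter alphabet, with an edge between two sequences exactly when
#' they differ at a single position.  Every vertex therefore has degree
#' \eqn{\ell(k-1)}, the number of possible single-character mutations.
#'
#' Vertices are canonically labelled by the integers \eqn{0, \dots, k^\ell-1}
#' read as base-\eqn{k} numbers: position 1 of the sequence is the
#' most-significant digit, and the i-th alphabet symbol stands for digit
#' \eqn{i-1}.  Genotype strings appear only at the I/O boundary; all internal
#' computation uses the integer labels.
#'
#' @slot k alphabet size (integer \eqn{\ge 2}).
#' @slot length sequence length \eqn{\ell} (integer \eqn{\ge 1}).
#' @slot symbols character vector of `k` distinct single characters, in digit
#'   order.
#'
#' @examples
#' sp <- GenotypeSpace(k = 2, length = 3)
#' nGenotypes(sp)       # 8
#' hammingDegree(sp)    # 3
#' @seealso [GenotypeSpace()], [vertexToGenotype()], [hammingNeighbors()]
#' @export
setClass("GenotypeSpace",
  representation(k = "numeric", length = "numeric", symbols = "character"))

setValidity("GenotypeSpace", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 2 || object@k != round(object@k))
    msg <- c(msg, "'k' must be a single integer >= 2")
  if (length(object@length) != 1L || object@length < 1 ||
      object@length != round(object@length))
    msg <- c(msg, "'length' must be a single integer >= 1")
  if (length(object@symbols) != object@k)
    msg <- c(msg, "need exactly k symbols")
  if (anyDuplicated(object@symbols))
    msg <- c(msg, "symbols must be distinct")
  if (any(nchar(object@symbols) != 1L))
    msg <- c(msg, "symbols must be single characters")
  if (object@k^object@length > 2^53)
    msg <- c(msg, "k^length exceeds exact double-precision integer range")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeSpace
#'
#' @param k alphabet size (integer \eqn{\ge 2}).
#' @param length sequence length \eqn{\ell \ge 1}.
#' @param symbols optional character vector of `k` distinct single characters
#'   used for genotype strings; defaults to `0,1,...,9,a,b,...` in digit
#'   order.  Pass e.g. `c("A","C","G","U")` for RNA.
#' @return a [GenotypeSpace-class] object.
#' @examples
#' GenotypeSpace(4, 12, symbols = c("A", "C", "G", "U"))
#' @export
GenotypeSpace <- function(k, length, symbols = NULL) {
  if (is.null(symbols)) {
    pool <- c(as.character(0:9), letters, LETTERS)
    if (k > length(pool))
      stop("supply 'symbols' explicitly for k > ", length(pool))
    symbols <- pool[seq_len(k)]
  }
  new("GenotypeSpace", k = as.numeric(k), length = as.numeric(length),
      symbols = as.character(symbols))
}

#' @describeIn GenotypeSpace alphabet size \eqn{k}.
#' @param object,x a `GenotypeSpace`.
#' @export
alphabetSize <- function(x) x@k

#' @describeIn GenotypeSpace sequence length \eqn{\ell}.
#' @export
seqLength <- function(x) x@length

#' @describeIn GenotypeSpace the alphabet, in digit order.
#' @export
genotypeSymbols <- function(x) x@symbols

#' @describeIn GenotypeSpace number of genotypes \eqn{k^\ell}.
#' @export
nGenotypes <- function(x) x@k^x@length

#' @describeIn GenotypeSpace vertex degree \eqn{\ell(k-1)}, the number of
#'   single-character mutants of any genotype.
#' @export
hammingDegree <- function(x) x@length * (x@k - 1)

setMethod("show", "GenotypeSpace", function(object) {
  cat(sprintf("GenotypeSpace H_{l,k}: l = %d, k = %d (%s); %s vertices, degree %d\n",
              as.integer(object@length), as.integer(object@k),
              paste(object@symbols, collapse = ""),
              format(nGenotypes(object), big.mark = ","),
              as.integer(hammingDegree(object))))
})

#' GPMap: a complete genotype-phenotype map
#'
#' A `GPMap` assigns every vertex of a [GenotypeSpace-class] (every genotype)
#' to exactly one phenotype label.  The set of genotypes sharing a label is
#' that phenotype's *neutral set*, an induced subgraph of the Hamming graph;
#' its maximal connected pieces under single-character mutation are the
#' *neutral components*.
#'
#' The map must be total: partial maps (e.g. tables listing only folded
#' sequences) can be completed with a default label at read time, see
#' [readGPMap()].  Phenotype labels are ordered by descending neutral-set
#' size, ties broken lexicographically, so that all derived tables and
#' matrices are deterministic.
#'
#' @slot space the [GenotypeSpace-class].
#' @slot assignment character vector of length \eqn{k^\ell}; element `i` is
#'   the phenotype of vertex `i - 1`.
#' @slot labels phenotype labels in canonical order.
#' @seealso [GPMap()], [readGPMap()], [phenotypeStats()], [transitionMatrix()]
#' @export
setClass("GPMap",
  representation(space = "GenotypeSpace", assignment = "character",
                 labels = "character"))

setValidity("GPMap", function(object) {
  msg <- character()
  if (length(object@assignment) != nGenotypes(object@space))
    msg <- c(msg, "assignment must cover every vertex exactly once")
  if (anyNA(object@assignment))
    msg <- c(msg, "assignment contains NA")
  if (!setequal(unique(object@assignment), object@labels))
    msg <- c(msg, "labels do not match assignment")
  if (length(msg)) msg else TRUE
})

#' Construct a GPMap from a phenotype assignment vector
#'
#' @param space a [GenotypeSpace-class].
#' @param assignment character vector of length \eqn{k^\ell} giving the
#'   phenotype of vertices \eqn{0, \dots, k^\ell - 1} in label order.
#' @return a [GPMap-class].
#' @examples
#' sp <- GenotypeSpace(2, 2)
#' GPMap(sp, c("A", "A", "B", "B"))
#' @export
GPMap <- function(space, assignment) {
  assignment <- as.character(assignment)
  new("GPMap", space = space, assignment = assignment,
      labels = orderPhenotypeLabels(assignment))
}

## canonical label order: descending neutral-set size, ties lexicographic
orderPhenotypeLabels <- function(assignment) {
  tab <- table(assignment)
  names(tab)[order(-as.numeric(tab), names(tab), method = "radix")]
}

#' @describeIn GPMap the underlying genotype space.
#' @param x,object a `GPMap`.
#' @export
genotypeSpace <- function(x) x@space

#' @describeIn GPMap phenotype labels in canonical order (descending
#'   neutral-set size, ties lexicographic).
#' @export
phenotypeLabels <- function(x) x@labels

#' @describeIn GPMap the full vertex-to-phenotype assignment vector.
#' @export
phenotypeAssignment <- function(x) x@assignment

#' @describeIn GPMap integer vertex labels of one phenotype's neutral set.
#' @param label a phenotype label.
#' @export
neutralSet <- function(x, label) {
  if (!label %in% x@labels) stop("unknown phenotype label: ", label)
  which(x@assignment == label) - 1
}

setMethod("show", "GPMap", function(object) {
  cat(sprintf("GPMap on H_{%d,%d}: %s genotypes, %d phenotypes\n",
              as.integer(object@space@length), as.integer(object@space@k),
              format(nGenotypes(object@space), big.mark = ","),
              length(object@labels)))
  n <- sort(table(object@assignment), decreasing = TRUE)
  show <- utils::head(n, 6L)
  cat("  neutral set sizes: ",
      paste(sprintf("%s=%d", names(show), as.integer(show)), collapse = ", "),
      if (length(n) > 6L) ", ..." else "", "\n", sep = "")
})

#' TransitionMatrix: phenotype robustness and transition probabilities
#'
#' Square column-stochastic matrix \eqn{\phi} over a set of phenotypes.  The
#' off-diagonal entry \eqn{\phi_{ts}} is the probability that a single
#' random character mutation of a random genotype of phenotype s yields
#' phenotype t, i.e. the cross-edge count between the two neutral sets
#' normalised by \eqn{\ell(k-1)|V_s|}.  The diagonal entry is the phenotype
#' robustness \eqn{\rho_s} (which carries a factor 2 relative to the naive
#' edge count, because each within-set edge is a neutral mutation in both
#' directions).  Columns sum to one: every mutation lands on some phenotype.
#' Detailed balance \eqn{\phi_{ts} f_s = \phi_{st} f_t} holds because both
#' sides count the same edges.
#'
#' @slot space the [GenotypeSpace-class] the phenotypes live in.
#' @slot f named vector of phenotype frequencies \eqn{f_s = |V_s|/k^\ell}.
#' @slot phi the matrix, `phi[t, s]` = \eqn{\phi_{ts}}, dimnames are the
#'   phenotype labels.
#' @seealso [transitionMatrix()], [coarseGrain()], [classifyPairs()]
#' @export
setClass("TransitionMatrix",
  representation(space = "GenotypeSpace", f = "numeric", phi = "matrix"))

setValidity("TransitionMatrix", function(object) {
  msg <- character()
  np <- length(object@f)
  if (!identical(dim(object@phi), c(np, np)))
    msg <- c(msg, "phi must be square with one row/column per phenotype")
  if (is.null(names(object@f)) ||
      !identical(names(object@f), rownames(object@phi)) ||
      !identical(names(object@f), colnames(object@phi)))
    msg <- c(msg, "names of f and dimnames of phi must agree")
  if (any(object@f <= 0)) msg <- c(msg, "frequencies must be positive")
  if (abs(sum(object@f) - 1) > 1e-8)
    msg <- c(msg, "frequencies must sum to 1")
  if (any(object@phi < -1e-12)) msg <- c(msg, "phi must be non-negative")
  if (any(abs(colSums(object@phi) - 1) > 1e-8))
    msg <- c(msg, "columns of phi must sum to 1")
  bal <- object@phi %*% diag(object@f, np)   # phi_ts f_s, must be symmetric
  if (max(abs(bal - t(bal))) > 1e-10)
    msg <- c(msg, "detailed balance phi_ts f_s = phi_st f_t violated")
  if (length(msg)) msg else TRUE
})

newTransitionMatrix <- function(space, f, phi) {
  new("TransitionMatrix", space = space, f = f, phi = phi)
}

#' @describeIn TransitionMatrix phenotype frequencies \eqn{f_s}.
#' @param x,object a `TransitionMatrix`.
#' @export
phenotypeFrequencies <- function(x) x@f

#' @describeIn TransitionMatrix the matrix itself (`[t, s]` =
#'   \eqn{\phi_{ts}}).
#' @export
transitionProbs <- function(x) x@phi

#' @describeIn TransitionMatrix diagonal: per-phenotype robustness
#'   \eqn{\rho_s}.
#' @export
phenotypeRobustness <- function(x) {
  stats::setNames(diag(x@phi), names(x@f))
}

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix on H_{%d,%d}: %d phenotypes\n",
              as.integer(object@space@length), as.integer(object@space@k),
              length(object@f)))
  cat("  f:   ", paste(sprintf("%s=%.4g", names(object@f),
                               object@f)[seq_len(min(5, length(object@f)))],
                       collapse = ", "), "\n")
  cat("  rho: ", paste(sprintf("%s=%.4g", names(object@f),
                               diag(object@phi))[seq_len(min(5, length(object@f)))],
                       collapse = ", "), "\n")
})
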
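## Phenotype coarse-graining: merged robustness / transition algebra on
## the transition matrix, the equivalent map-level route, and critical
## transition-probability thresholds for pairwise merges in the
## high-robustness regime.

checkPartition <- function(partition, labels) {
  if (is.null(names(partition)))
    stop("partition must be a named vector: names = phenotype labels, ",
         "values = group labels")
  missing <- setdiff(labels, names(partition))
  if (length(missing))
    stop("partition does not cover phenotype(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(partition), labels)
  if (length(unknown))
    stop("partition names unknown to the matrix/map: ",
         paste(unknown, collapse = ", "))
  as.character(partition[labels])     # aligned to label order
}

#' Coarse-grain a phenotype transition matrix
#'
#' Merges phenotypes into groups and returns the transition matrix of the
#' coarse-grained phenotypes.  Frequencies add,
#' \eqn{f_S = \sum_{s \in S} f_s}; transition probabilities are
#' frequency-weighted averages,
#' \deqn{\phi_{TS} = \frac{\sum_{s\in S}\sum_{t\in T} \phi_{ts} f_s}{f_S},}
#' and with \eqn{\phi_{ss} = \rho_s} the same expression with \eqn{T = S}
#' yields the merged robustness: the frequency-weighted mean of the member
#' robustnesses plus twice the internal cross-transition mass.  Merging
#' *all* phenotypes of a complete map gives \eqn{\rho_S = 1} exactly.
#'
#' @param tm a [TransitionMatrix-class].
#' @param partition named character vector mapping every phenotype label of
#'   `tm` to a group label (see [readPartition()]).  Groups of one act as
#'   the identity.
#' @return a [TransitionMatrix-class] over the group labels (canonical
#'   order: descending merged frequency, ties lexicographic).
#' @examples
#' sp <- GenotypeSpace(2, 2)
#' tm <- transitionMatrix(GPMap(sp, c("A", "A", "B", "B")))
#' coarseGrain(tm, c(A = "all", B = "all"))  # 1x1 matrix [[1]]
#' @export
coarseGrain <- function(tm, partition) {
  labs <- names(tm@f)
  groups <- checkPartition(partition, labs)
  mass <- tm@phi %*% diag(tm@f, length(labs))   # phi_ts f_s (symmetric)
  fS <- tapply(tm@f, groups, sum)
  glabs <- names(fS)[order(-as.numeric(fS), names(fS), method = "radix")]
  ind <- outer(glabs, groups, "==") * 1         # group indicator matrix
  phiG <- (ind %*% mass %*% t(ind))
  phiG <- sweep(phiG, 2, as.numeric(fS[glabs]), "/")
  dimnames(phiG) <- list(glabs, glabs)
  newTransitionMatrix(tm@space,
                      stats::setNames(as.numeric(fS[glabs]), glabs), phiG)
}

#' Coarse-grain at the map level
#'
#' Relabels every genotype by its phenotype's group and computes the
#' transition matrix of the relabelled [GPMap-class] directly from edge
#' counts.  This is mathematically identical to coarse-graining the
#' original transition matrix with [coarseGrain()] (the route equivalence
#' is exercised in the tests), but returns the matrix from first
#' principles.
#'
#' @param map a [GPMap-class].
#' @param partition named character vector mapping every phenotype label of
#'   `map` to a group label.
#' @return a [TransitionMatrix-class] over the group labels.
#' @export
coarseGrainMap <- function(map, partition) {
  groups <- checkPartition(partition, map@labels)
  names(groups) <- map@labels
  transitionMatrix(GPMap(map@space, groups[map@assignment]))
}

#' Robustness of a pairwise phenotype merge
#'
#' Merging phenotypes p and q (frequencies \eqn{f_p, f_q}, robustness
#' \eqn{\rho_p, \rho_q}, transition probability \eqn{\phi_{qp}}) yields
#' \deqn{\rho_S = \frac{\rho_p f_p + \rho_q f_q + 2\phi_{qp} f_p}
#'   {f_p + f_q}.}
#' The factor 2 counts the cross edges once from each side (detailed
#' balance: \eqn{\phi_{qp} f_p = \phi_{pq} f_q}).
#'
#' @param fp,fq positive frequencies.
#' @param rhop,rhoq member robustnesses.
#' @param phiqp transition probability from p to q.
#' @return merged robustness \eqn{\rho_S}.
#' @examples
#' pairwiseMergedRho(0.5, 0.5, 0.5, 0.5, 0.5)  # 1: the whole-space merge
#' @export
pairwiseMergedRho <- function(fp, fq, rhop, rhoq, phiqp) {
  if (any(fp <= 0) || any(fq <= 0)) stop("frequencies must be positive")
  (rhop * fp + rhoq * fq + 2 * phiqp * fp) / (fp + fq)
}

#' Critical transition-probability window for a pairwise merge
#'
#' In the high-robustness regime each phenotype sits a displacement
#' \eqn{\Delta \ge 0} below the asymptotic optimal line:
#' \eqn{\rho_p = 1 + \log_k(f_p)/\ell - \Delta_p} (likewise q).  The merged
#' robustness, linear in \eqn{\phi_{qp}}, is
#' \deqn{\rho_S \approx 1 - \frac{f_p\Delta_p + f_q\Delta_q}{f_p+f_q}
#'   + \frac{f_p\log_k f_p + f_q\log_k f_q + 2\ell\,\phi_{qp} f_p}
#'     {\ell\,(f_p+f_q)},}
#' and the merge stays within displacement
#' \eqn{[\min(\Delta_p,\Delta_q),\ \max(\Delta_p,\Delta_q)]} of the line
#' exactly when \eqn{\phi_{qp}} lies between the two closed-form roots of
#' \eqn{\rho_S(\phi_{qp}) = 1 + \log_k(f_p+f_q)/\ell - \Delta} at
#' \eqn{\Delta = \max} (lower root) and \eqn{\Delta = \min} (upper root):
#' \deqn{\phi^{crit}(\Delta) = \frac{(f_p+f_q)\log_k(f_p+f_q)
#'   - f_p\log_k f_p - f_q\log_k f_q
#'   + \ell\,[f_p\Delta_p + f_q\Delta_q - (f_p+f_q)\Delta]}{2\,\ell\,f_p}.}
#' The two roots coincide when \eqn{\Delta_p = \Delta_q}.  Inputs are
#' relabelled internally so that \eqn{f_q \le f_p} (\eqn{\beta = f_q/f_p
#' \in (0,1]}); the returned bounds always refer to the transition
#' probability out of the *more frequent* phenotype.
#'
#' @param fp,fq positive frequencies (relabelled so `fq <= fp`).
#' @param deltap,deltaq non-negative displacements from the asymptotic
#'   optimal robustness line, in the same robustness units.
#' @param space a [GenotypeSpace-class] supplying \eqn{k} and \eqn{\ell}.
#' @return list with `phiLower`, `phiUpper`, `beta` and the (possibly
#'   swapped) `fp`, `fq`, `deltap`, `deltaq`.
#' @examples
#' sp <- GenotypeSpace(4, 12)
#' criticalPhiBounds(0.1, 0.05, 0.1, 0.02, sp)
#' @export
criticalPhiBounds <- function(fp, fq, deltap, deltaq, space) {
  if (fp <= 0 || fq <= 0) stop("frequencies must be positive")
  if (deltap < 0 || deltaq < 0) stop("displacements must be non-negative")
  if (fq > fp) {    # relabel so beta = fq/fp <= 1
    tmp <- fp; fp <- fq; fq <- tmp
    tmp <- deltap; deltap <- deltaq; deltaq <- tmp
  }
  k <- space@k; l <- space@length
  logk <- function(x) log(x) / log(k)
  fS <- fp + fq
  root <- function(delta)
    (fS * logk(fS) - fp * logk(fp) - fq * logk(fq) +
       l * (fp * deltap + fq * deltaq - fS * delta)) / (2 * l * fp)
  list(phiLower = root(max(deltap, deltaq)),
       phiUpper = root(min(deltap, deltaq)),
       beta = fq / fp, fp = fp, fq = fq,
       deltap = deltap, deltaq = deltaq)
}

#' Classify all phenotype pairs against the critical merge window
#'
#' For every unordered pair of phenotypes of a transition matrix, computes
#' the displacements \eqn{\Delta = 1 + \log_k(f)/\ell - \rho} from the
#' asymptotic optimal line (clipped at zero, with one summary warning, when
#' a small neutral set sits above the asymptotic line), the critical
#' transition-probability window from [criticalPhiBounds()], and classifies
#' the measured \eqn{\phi_{qp}} as `"undershoot"` (below the window: the
#' merge falls further off the optimal line than either member),
#' `"within"`, or `"overshoot"` (above: the merge moves closer to the
#' line).  Within each pair, p denotes the more frequent phenotype.
#'
#' @param tm a [TransitionMatrix-class].
#' @return data.frame with one row per unordered pair and columns `p`, `q`,
#'   `f_p`, `f_q`, `beta`, `delta_p`, `delta_q`, `phi_qp`, `phi_lower`,
#'   `phi_upper`, `class`.
#' @export
classifyPairs <- function(tm) {
  labs <- names(tm@f)
  if (length(labs) < 2L) stop("need at least two phenotypes")
  space <- tm@space
  k <- space@k; l <- space@length
  delta <- 1 + (log(tm@f) / log(k)) / l - diag(tm@phi)
  nClip <- sum(delta < 0)
  if (nClip > 0) {
    warning(nClip, " phenotype(s) above the asymptotic optimal line; ",
            "displacement clipped to 0")
    delta <- pmax(delta, 0)
  }
  pairs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ## p = more frequent member (ties: keep canonical order)
    if (tm@f[b] > tm@f[a]) { p <- b; q <- a } else { p <- a; q <- b }
    cb <- criticalPhiBounds(tm@f[p], tm@f[q], delta[p], delta[q], space)
    phiqp <- tm@phi[q, p]
    cls <- if (phiqp < cb$phiLower) "undershoot"
           else if (phiqp > cb$phiUpper) "overshoot"
           else "within"
    data.frame(p = p, q = q, f_p = unname(tm@f[p]), f_q = unname(tm@f[q]),
               beta = cb$beta, delta_p = unname(delta[p]),
               delta_q = unname(delta[q]), phi_qp = unname(phiqp),
               phi_lower = cb$phiLower, phi_upper = cb$phiUpper,
               class = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
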
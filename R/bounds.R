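## Robustness curves and inequalities: the exact maximum (bricklayer /
## blancmange) curve, its simple log upper bound and Galkin-Galkina lower
## bound, the connected-component minimum, the random-null expectation,
## percolation-type thresholds, and the multi-component deviation bound
## built on the superadditivity property of the sums-of-digits function.

#' Maximum phenotype robustness (bricklayer's bound)
#'
#' For a neutral set of `n` genotypes on \eqn{H_{\ell,k}}, the maximum
#' achievable robustness is attained by the bricklayer's graph:
#' \deqn{\rho^{max}(n) = \frac{2 S_k(n)}{n\,\ell\,(k-1)},}
#' computed from the exact integer sums-of-digits value.
#'
#' @param n neutral-set size(s), integer in \eqn{[1, k^\ell]}, vectorised.
#' @param space a [GenotypeSpace-class].
#' @return robustness value(s) in \eqn{[0, 1]}.
#' @examples
#' rhoMax(5, GenotypeSpace(2, 3))   # 2/3
#' rhoMax(8, GenotypeSpace(2, 3))   # 1: the whole cube
#' @export
rhoMax <- function(n, space) {
  n <- checkCount(n, "n", min = 1)
  if (any(n > nGenotypes(space))) stop("'n' exceeds the number of genotypes")
  2 * sumsOfDigits(n, space@k) / (n * hammingDegree(space))
}

#' Continuous interpolation of the maximum-robustness curve
#'
#' Evaluates the blancmange-like continuous curve
#' \deqn{\rho^{max}(n) = \frac{\log_k n - g_k(k^{\{\log_k n\}-1})/(k-1)}{\ell}}
#' for real \eqn{n \in [1, k^\ell]}; at integer `n` it coincides with
#' [rhoMax()] (to floating precision).  The curve is continuous everywhere
#' and differentiable nowhere -- for \eqn{k = 2} its fractal part is the
#' Takagi (blancmange) function.
#'
#' @param n real value(s) in \eqn{[1, k^\ell]}, vectorised.
#' @param space a [GenotypeSpace-class].
#' @param tol Delange-series tolerance.
#' @return robustness value(s).
#' @export
rhoMaxContinuous <- function(n, space, tol = 1e-12) {
  if (anyNA(n) || any(n < 1) || any(n > nGenotypes(space)))
    stop("'n' must lie in [1, k^l]")
  k <- space@k
  whole <- n == round(n)
  out <- numeric(length(n))
  if (any(whole)) {
    ## integer n: exact rational fractal argument x = n / k^(m+1), and
    ## log_k n = (m + 1) + log_k x, so no floating log of n is floored
    m <- floorLogK(n[whole], k)
    x <- n[whole] / k^(m + 1)
    out[whole] <- (m + 1 + log(x) / log(k) -
                     delangeG(x, k, tol) / (k - 1)) / space@length
  }
  if (any(!whole)) {
    nn <- n[!whole]
    lg <- log(nn) / log(k)
    x <- k^(lg - floor(lg) - 1)
    out[!whole] <- (lg - delangeG(x, k, tol) / (k - 1)) / space@length
  }
  out
}

#' Upper and lower bounds on the maximum robustness
#'
#' The maximum-robustness curve is sandwiched by
#' \deqn{\frac{\log_k n}{\ell} + \frac{2 A_k}{(k-1)\ell} \;\le\;
#'   \rho^{max}(n) \;\le\; \frac{\log_k n}{\ell},}
#' where \eqn{A_k \le 0} is the alphabet constant ([alphabetConstant()]).
#' The upper bound is the familiar empirical log-linear scaling
#' \eqn{\rho \approx 1 + \log_k f / \ell}; the lower bound differs from it
#' only by the constant correction \eqn{2A_k/((k-1)\ell)} (about
#' \eqn{-0.0283} for \eqn{k=4, \ell=12} and \eqn{-0.0226} for \eqn{\ell=15}).
#'
#' @param n real neutral-set size(s) \eqn{\ge 1}, vectorised.
#' @param space a [GenotypeSpace-class].
#' @param nMax scan range forwarded to [alphabetConstant()] when no closed
#'   form exists for `k`.
#' @return data.frame with columns `n`, `lower`, `upper`.
#' @export
rhoBounds <- function(n, space, nMax = 1e6) {
  if (anyNA(n) || any(n < 1)) stop("'n' must be >= 1")
  k <- space@k
  upper <- log(n) / log(k) / space@length
  A <- alphabetConstant(k, nMax)$A
  data.frame(n = n, lower = upper + 2 * A / ((k - 1) * space@length),
             upper = upper)
}

#' Minimum robustness of a connected neutral component
#'
#' A connected graph on `n` vertices has at least \eqn{n - 1} edges (path,
#' star, any tree), so a fully connected neutral component satisfies
#' \deqn{\rho^{min}(n) = \frac{2}{\ell(k-1)}\Big(1 - \frac{1}{n}\Big).}
#'
#' @inheritParams rhoMax
#' @return minimum robustness value(s).
#' @examples
#' rhoMin(2, GenotypeSpace(2, 3))  # 1/3
#' @export
rhoMin <- function(n, space) {
  n <- checkCount(n, "n", min = 1)
  2 / hammingDegree(space) * (1 - 1 / n)
}

#' Random-null robustness expectation
#'
#' Under the random null model (genotypes attributed to phenotypes at
#' random with neutral-set sizes fixed), robustness scales with frequency:
#' \eqn{\rho \approx f = n/k^\ell}.
#'
#' @inheritParams rhoMax
#' @return frequency value(s) \eqn{n/k^\ell}.
#' @export
rhoNull <- function(n, space) {
  n <- checkCount(n, "n", min = 1)
  if (any(n > nGenotypes(space))) stop("'n' exceeds the number of genotypes")
  n / nGenotypes(space)
}

#' Percolation and giant-component frequency thresholds
#'
#' `percolationThreshold` returns \eqn{1/[\ell(k-1)]}: phenotype
#' frequencies above it are expected to yield a percolating (system
#' spanning) neutral component.  `giantComponentThreshold` returns
#' \eqn{1 - k^{-1/(k-1)}}, above which the neutral components are expected
#' to coalesce into one (nearly) fully connected giant component.
#'
#' @param space a [GenotypeSpace-class].
#' @param k alphabet size.
#' @return a single threshold frequency.
#' @examples
#' percolationThreshold(GenotypeSpace(4, 12))  # 1/36
#' giantComponentThreshold(4)                  # 1 - 2^(-2/3)
#' @export
percolationThreshold <- function(space) 1 / hammingDegree(space)

#' @rdname percolationThreshold
#' @export
giantComponentThreshold <- function(k) {
  k <- checkBase(k)
  1 - k^(-1 / (k - 1))
}

#' Superadditivity-type inequality of the sums-of-digits function
#'
#' For `k` non-negative integers \eqn{n_1 \le \dots \le n_k},
#' \deqn{\sum_{i=1}^{k} S_k(n_i) + \sum_{i=1}^{k-1} (k-i)\,n_i \;\le\;
#'   S_k\Big(\sum_i n_i\Big).}
#' This property underlies the lower bound on how far a neutral set split
#' into several components must fall below the single-component maximum.
#'
#' @param sizes numeric vector of exactly `k` non-negative integers; sorted
#'   ascending internally (with a message if reordering was needed).
#'   Fewer than `k` components are represented by zero padding.
#' @param k alphabet size.
#' @return list with `lhs`, `rhs` and logical `holds` (always `TRUE`; the
#'   inequality is exact).
#' @examples
#' digitSumSplitInequality(c(1, 1), 2)  # equality: 1 <= S_2(2) = 1
#' @export
digitSumSplitInequality <- function(sizes, k) {
  k <- checkBase(k)
  sizes <- checkCount(sizes, "sizes")
  if (length(sizes) != k) stop("need exactly k sizes (pad with zeros)")
  if (is.unsorted(sizes)) {
    message("sizes reordered ascending")
    sizes <- sort(sizes)
  }
  lhs <- sum(sumsOfDigits(sizes, k)) +
    sum((k - seq_len(k - 1)) * sizes[seq_len(k - 1)])
  rhs <- sumsOfDigits(sum(sizes), k)
  list(lhs = lhs, rhs = rhs, holds = lhs <= rhs)
}

#' Lower bound on the robustness deficit of a multi-component neutral set
#'
#' If a neutral set of \eqn{n = \sum n_i} genotypes on \eqn{H_{\ell,k}}
#' splits into `m` neutral components of sizes \eqn{n_1 \le \dots \le n_m},
#' its robustness must fall below the single-component maximum
#' \eqn{\rho^{max}(n)} by at least
#' \deqn{\frac{2}{n\,\ell\,(k-1)} \sum_{i=1}^{k-1} (k-i)\, n_i,}
#' where the sum runs over the ascending sizes zero-padded to length `k`
#' (so only the \eqn{\min(m, k-1)} smallest components contribute).  The
#' bound is proven only for \eqn{m \le k}; for more components the same
#' expression is evaluated from the \eqn{k-1} smallest sizes and flagged
#' `proven = FALSE`.
#'
#' @param sizes component sizes (positive integers, any order).
#' @param space a [GenotypeSpace-class].
#' @return list with `bound`, `m`, `n` and logical `proven`.
#' @examples
#' multicomponentDeviationBound(c(1, 1), GenotypeSpace(2, 3))  # 1/3
#' @export
multicomponentDeviationBound <- function(sizes, space) {
  sizes <- checkCount(sizes, "sizes", min = 1)
  if (!length(sizes)) stop("'sizes' must be non-empty")
  k <- space@k
  m <- length(sizes)
  n <- sum(sizes)
  if (n > nGenotypes(space)) stop("component sizes exceed the space")
  asc <- sort(sizes)
  padded <- if (m <= k) c(numeric(k - m), asc) else asc[seq_len(k - 1)]
  ## weights (k - i) for the first k-1 positions of the ascending k-tuple
  w <- k - seq_len(k - 1)
  bound <- 2 / (n * hammingDegree(space)) *
    sum(w * padded[seq_len(k - 1)])
  list(bound = bound, m = m, n = n, proven = m <= k)
}

#' Tabulate all robustness curves over a grid of neutral-set sizes
#'
#' Produces the per-size table behind the standard robustness-versus-
#' frequency plot: exact maximum (bricklayer) robustness, its continuous
#' interpolation, the log upper bound, the Galkin-Galkina lower bound, the
#' connected-component minimum and the random-null expectation.
#'
#' @param space a [GenotypeSpace-class].
#' @param n sizes at which to evaluate; defaults to all integers
#'   \eqn{1, \dots, k^\ell} (capped at `maxRows`).  Non-integer values are
#'   allowed and evaluate the continuous curve with `rho_max = NA`.
#' @param tol Delange-series tolerance.
#' @param maxRows guard against accidentally tabulating a huge space.
#' @return data.frame with columns `n`, `f`, `rho_max`, `rho_max_cont`,
#'   `rho_upper`, `rho_lower`, `rho_min`, `rho_null`.
#' @examples
#' head(robustnessCurve(GenotypeSpace(2, 6)))
#' @export
robustnessCurve <- function(space, n = NULL, tol = 1e-12, maxRows = 1e6) {
  N <- nGenotypes(space)
  if (is.null(n)) {
    if (N > maxRows) stop("space too large; supply 'n' explicitly")
    n <- seq_len(N)
  }
  if (anyNA(n) || any(n < 1) || any(n > N)) stop("'n' must lie in [1, k^l]")
  whole <- n == round(n)
  b <- rhoBounds(n, space)
  rmax <- rep(NA_real_, length(n))
  rmax[whole] <- rhoMax(n[whole], space)
  data.frame(
    n = n,
    f = n / N,
    rho_max = rmax,
    rho_max_cont = rhoMaxContinuous(n, space, tol),
    rho_upper = b$upper,
    rho_lower = b$lower,
    rho_min = 2 / hammingDegree(space) * (1 - 1 / n),
    rho_null = n / N)
}
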
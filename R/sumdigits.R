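## Sums-of-digits machinery: s_k(i), S_k(n), the Trollope-Delange closed
## form with its fractal Delange (Takagi for k = 2) function, the Fourier
## expansion of the periodic part, and the Galkin-Galkina alphabet
## constants A_k.
##
## All integer quantities are held in doubles and are exact below 2^53;
## inputs are validated against that range.

checkCount <- function(x, name, min = 0) {
  if (length(x) < 1L || anyNA(x) || any(x < min) || any(x != round(x)))
    stop("'", name, "' must be integer-valued and >= ", min)
  if (any(x >= 2^53)) stop("'", name, "' exceeds exact integer range of doubles")
  x
}

checkBase <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 2 || k != round(k))
    stop("'k' must be a single integer >= 2")
  k
}

#' Base-k digit sum of an integer
#'
#' `digitSum(i, k)` returns \eqn{s_k(i)}, the sum of the digits of the
#' base-\eqn{k} representation of `i`.  Vectorised over `i`.
#'
#' @param i non-negative integer(s).
#' @param k base (integer \eqn{\ge 2}).
#' @return integer-valued numeric vector of digit sums.
#' @examples
#' digitSum(5, 2)    # 101 in binary -> 2
#' digitSum(999, 10) # 27
#' @seealso [sumsOfDigits()]
#' @export
digitSum <- function(i, k) {
  i <- checkCount(i, "i"); k <- checkBase(k)
  s <- numeric(length(i))
  while (any(i > 0)) {
    s <- s + i %% k
    i <- i %/% k
  }
  s
}

#' Cumulative sums-of-digits function S_k(n)
#'
#' Returns \eqn{S_k(n) = \sum_{i=0}^{n-1} s_k(i)}, the total of all
#' base-\eqn{k} digit sums below `n`.  This is exactly the number of edges
#' of the bricklayer's graph on the first `n` vertices of any Hamming graph
#' \eqn{H_{\ell,k}} large enough to contain them, and hence the maximum
#' number of edges of any `n`-vertex induced subgraph.
#'
#' The value is computed by an exact per-digit-position counting recursion,
#' \eqn{O(\log_k n)} per value, not by summing `n` digit sums: writing
#' \eqn{n = h k^{p+1} + d k^p + r} for position p, the digits at position p
#' of \eqn{0, \dots, n-1} contribute \eqn{h k^p k(k-1)/2 + k^p d(d-1)/2 + d r}.
#' All arithmetic is exact in doubles for \eqn{n < 2^{53}}.
#'
#' @param n non-negative integer(s), vectorised.
#' @param k base (integer \eqn{\ge 2}).
#' @return exact integer-valued numeric vector \eqn{S_k(n)}.
#' @examples
#' sumsOfDigits(5, 2)   # 0+1+1+2+1 = 5
#' sumsOfDigits(8, 2)   # 12, the edge count of the 3-cube
#' @references For the naive-summation cross-check see the package test
#'   suite; see also [trollopeDelangeS()] for the analytic closed form.
#' @export
sumsOfDigits <- function(n, k) {
  n <- checkCount(n, "n"); k <- checkBase(k)
  total <- numeric(length(n))
  pw <- 1  # k^p
  while (any(n > pw)) {
    h <- n %/% (pw * k)
    d <- (n %/% pw) %% k
    r <- n %% pw
    total <- total + h * pw * k * (k - 1) / 2 + pw * d * (d - 1) / 2 + d * r
    pw <- pw * k
  }
  total
}

## S_k(n) for all n = 0..nmax as a vector (index n+1); used by the
## numeric-scan alphabet constant and by vectorised curve sweeps.
sumsOfDigitsUpTo <- function(nmax, k) {
  nmax <- checkCount(nmax, "nmax"); k <- checkBase(k)
  i <- seq_len(nmax) - 1
  s <- numeric(nmax)
  while (any(i > 0)) {
    s <- s + i %% k
    i <- i %/% k
  }
  c(0, cumsum(s))
}

#' One level of the Delange function: exact piecewise-linear integral
#'
#' \eqn{D_{k,0}(x) = \int_0^x (2k[t] - 2[kt] + k - 1)\,dt}, where
#' \eqn{[\cdot]} is the integer part.  The integrand is a step function
#' taking value \eqn{k - 1 - 2j} on \eqn{[j/k, (j+1)/k)} within each unit
#' interval and integrating to zero over any full period, so
#' \eqn{D_{k,0}} is 1-periodic and is evaluated in closed form per segment;
#' no quadrature is involved.
#'
#' @param x non-negative real(s), vectorised.
#' @param k base (integer \eqn{\ge 2}).
#' @return \eqn{D_{k,0}(x)}.
#' @examples
#' delangeD0(0.5, 2)  # 0.5: integrand is 1 on [0, 0.5)
#' delangeD0(3, 5)    # 0 at any integer
#' @export
delangeD0 <- function(x, k) {
  if (anyNA(x) || any(x < 0)) stop("'x' must be non-negative")
  k <- checkBase(k)
  y <- x - floor(x)                 # 1-periodic
  j <- floor(k * y)                 # segment index 0..k-1
  j * (k - j) / k + (y - j / k) * (k - 1 - 2 * j)
}

#' The Delange function (Takagi/blancmange for k = 2)
#'
#' \eqn{D_k(x) = \sum_{n \ge 0} D_{k,0}(k^n x) / k^n}, the fractal
#' continuous-everywhere, differentiable-nowhere function entering the
#' Trollope-Delange closed form of [sumsOfDigits()].  For `k = 2` this is
#' the classical Takagi (blancmange) function.
#'
#' The series is truncated once the geometric tail bound
#' \eqn{\sup|D_{k,0}| \cdot k^{-N} / (1 - 1/k) < tol} is reached
#' (\eqn{\sup|D_{k,0}| \le k/4}); it also stops early when \eqn{k^n x}
#' becomes an exact integer, after which every remaining term vanishes --
#' for rational \eqn{x} with a power-of-k denominator the sum is then exact.
#'
#' @param x non-negative real(s), vectorised.
#' @param k base (integer \eqn{\ge 2}).
#' @param tol positive truncation tolerance for the series tail.
#' @return \eqn{D_k(x)} within `tol`.
#' @examples
#' delangeD(0.5, 2)       # 0.5, the Takagi function's maximum
#' delangeD(1/3, 2, 1e-12)
#' @export
delangeD <- function(x, k, tol = 1e-12) {
  if (anyNA(x) || any(x < 0)) stop("'x' must be non-negative")
  k <- checkBase(k)
  if (length(tol) != 1L || is.na(tol) || tol <= 0) stop("'tol' must be > 0")
  sup0 <- k / 4                       # sup |D_{k,0}|, attained mid-period
  nmax <- ceiling(log(sup0 / (tol * (1 - 1 / k))) / log(k)) + 1
  total <- numeric(length(x))
  y <- x
  live <- rep(TRUE, length(x))
  for (n in 0:max(nmax, 0)) {
    live <- live & y != floor(y)      # integer y: all further terms vanish
    if (!any(live)) break
    total[live] <- total[live] + delangeD0(y[live], k) / k^n
    y <- y * k
  }
  total
}

#' The periodic fluctuation g_k of the sums-of-digits closed form
#'
#' \eqn{g_k(x) = (k-1)\log_k x + D_k(x)/x}, evaluated on \eqn{(0, 1]}.
#' In the Trollope-Delange formula it is evaluated at
#' \eqn{x = k^{\{\log_k n\} - 1} \in [1/k, 1)}, and \eqn{g_k(1/k) =
#' g_k(1) = 0}.
#'
#' @param x real(s) in \eqn{(0, 1]} (values up to machine precision above 1
#'   are tolerated), vectorised.
#' @inheritParams delangeD
#' @return \eqn{g_k(x)}.
#' @export
delangeG <- function(x, k, tol = 1e-12) {
  if (anyNA(x) || any(x <= 0)) stop("'x' must be positive")
  k <- checkBase(k)
  (k - 1) * log(x) / log(k) + delangeD(x, k, tol) / x
}

#' Trollope-Delange closed form of the sums-of-digits function
#'
#' Evaluates the exact analytic expression
#' \deqn{S_k(n) = (n/2)\,[(k-1)\log_k n - g_k(k^{\{\log_k n\}-1})],}
#' where \eqn{\{\cdot\}} is the fractional part.  Rounding the result to
#' the nearest integer reproduces the exact [sumsOfDigits()] value.
#'
#' Numerically, the exact power \eqn{m = \lfloor \log_k n \rfloor} is found
#' by integer comparison (never by flooring a floating log, which can land
#' at \eqn{m - \epsilon} for \eqn{n = k^m}), and the fractal argument is
#' formed as the exact rational \eqn{k^{\{\log_k n\}-1} = n / k^{m+1}}.
#' The two logarithmic terms are then combined analytically, leaving
#' \deqn{S_k(n) = (n/2)(k-1)(m+1) - k^{m+1} D_k(n/k^{m+1})/2,}
#' in which the Delange series is finite and exact.
#'
#' @param n positive integer(s), vectorised.
#' @param k base (integer \eqn{\ge 2}).
#' @param tol series tolerance passed to [delangeD()].
#' @return real vector; equals \eqn{S_k(n)} up to floating-point error.
#' @examples
#' round(trollopeDelangeS(5, 2))          # 5
#' trollopeDelangeS(10^4, 4) - sumsOfDigits(10^4, 4)  # ~1e-10
#' @export
trollopeDelangeS <- function(n, k, tol = 1e-12) {
  n <- checkCount(n, "n", min = 1); k <- checkBase(k)
  m <- floorLogK(n, k)
  x <- n / k^(m + 1)                    # k^{frac(log_k n) - 1}, exact
  n / 2 * (k - 1) * (m + 1) - k^(m + 1) * delangeD(x, k, tol) / 2
}

## floor(log_k n) by exact integer arithmetic; vectorised.
floorLogK <- function(n, k) {
  m <- numeric(length(n))
  pw <- rep(1, length(n))
  repeat {
    up <- pw * k <= n
    if (!any(up)) break
    pw[up] <- pw[up] * k
    m[up] <- m[up] + 1
  }
  m
}

#' Fourier coefficients of the periodic sums-of-digits fluctuation
#'
#' The function \eqn{x \mapsto g_k(k^{\{x\}-1})} has period one, and its
#' Fourier coefficients are
#' \deqn{c_n = \frac{-i(k-1)}{n\pi}\Big(1 + \frac{2\pi i n}{\log k}\Big)^{-1}
#'   \zeta\Big(\frac{2\pi i n}{\log k}\Big), \quad n \neq 0,}
#' with \eqn{\zeta} the Riemann zeta function evaluated on the imaginary
#' axis (see the internal Euler-Maclaurin evaluator, [zetaComplex()]).
#' The overall sign is fixed by requiring the partial sums to reconstruct
#' \eqn{g_k} itself in the \eqn{e^{+2\pi i n x}} convention (checked
#' against a quadrature oracle in the tests); published variants of this
#' coefficient differ in sign depending on whether the expanded
#' fluctuation is \eqn{g_k} or its negative.
#' The formula has a pole at `n = 0`; the mean value \eqn{c_0} is instead
#' obtained numerically by averaging the function over one period
#' ([fourierC0()]).  Since the expanded function is real,
#' \eqn{c_{-n} = \overline{c_n}}.
#'
#' @param n non-zero integer index (vectorised).
#' @param k base (integer \eqn{\ge 2}).
#' @return complex vector of coefficients \eqn{c_n}.
#' @examples
#' fourierCoefficient(1, 2)
#' Conj(fourierCoefficient(3, 2)) == fourierCoefficient(-3, 2)
#' @export
fourierCoefficient <- function(n, k) {
  if (anyNA(n) || any(n == 0) || any(n != round(n)))
    stop("'n' must be a non-zero integer; use fourierC0() for the mean term")
  k <- checkBase(k)
  s <- complex(real = 0, imaginary = 2 * pi * n / log(k))
  -1i * (k - 1) / (n * pi) / (1 + s) * zetaComplex(s)
}

#' @describeIn fourierCoefficient the mean \eqn{c_0}, computed as the
#'   numeric average of \eqn{g_k(k^{\{x\}-1})} over one period on a fixed
#'   midpoint grid (the coefficient formula excludes `n = 0`, and adaptive
#'   quadrature is unreliable on a fractal integrand).
#' @param gridN midpoint-rule resolution.
#' @param tol Delange-series tolerance.
#' @export
fourierC0 <- function(k, gridN = 2^14, tol = 1e-10) {
  k <- checkBase(k)
  x <- (seq_len(gridN) - 0.5) / gridN
  mean(delangeG(k^(x - 1), k, tol))
}

#' Partial Fourier reconstruction of the periodic fluctuation
#'
#' Sums \eqn{c_0 + \sum_{0 < |n| \le N} c_n e^{2\pi i n x}}; used to verify
#' the coefficient formula against direct evaluation of [delangeG()].
#' Convergence is slow (the function is fractal), so agreement is only to a
#' few hundredths at moderate `N`.
#'
#' @param x evaluation points in \eqn{[0, 1)}, vectorised.
#' @param k base.
#' @param N maximum harmonic.
#' @return real vector of partial sums.
#' @export
fourierPartialSum <- function(x, k, N = 200L) {
  k <- checkBase(k)
  idx <- seq_len(N)
  cpos <- fourierCoefficient(idx, k)
  out <- rep(fourierC0(k), length(x))
  for (j in seq_along(x)) {
    ph <- exp(2i * pi * idx * x[j])
    out[j] <- out[j] + sum(2 * Re(cpos * ph))   # c_{-n} = Conj(c_n)
  }
  out
}

#' Alphabet constants A_k of the Galkin-Galkina bound
#'
#' The constant \eqn{A_k \le 0} is the infimum over \eqn{n \ge 1} of
#' \eqn{S_k(n)/n - ((k-1)/2)\log_k n}; it gives the additive correction of
#' the lower robustness bound, see [rhoBounds()].  Exact closed forms are
#' returned for the alphabets of greatest biological interest:
#' \deqn{A_2 = \log_4 3 - 1, \quad A_3 = \log_3 2 - 1, \quad
#'   A_4 = (3/4)\log_2 5 - 9/4,}
#' \deqn{A_{20} = 19 \log(84/23)/\log(400) - 355/46,}
#' (binary, ternary, nucleotide and amino-acid alphabets).  For any other
#' `k` the infimum is estimated by a numeric scan of \eqn{n \le n_{max}};
#' the scan minimum is an *upper* estimate of the true infimum and is
#' flagged as such in the `method` field.
#'
#' @param k alphabet size (integer \eqn{\ge 2}).
#' @param nMax scan range for the numeric estimate (default \eqn{10^6});
#'   ignored when a closed form exists.
#' @return list with elements `k`, `A`, `method` (`"closed_form"` or
#'   `"numeric_scan"`) and, for scans, `nMax`.
#' @examples
#' alphabetConstant(4)$A          # -0.5086 (RNA/DNA)
#' alphabetConstant(5, nMax = 1e5)
#' @export
alphabetConstant <- function(k, nMax = 1e6) {
  k <- checkBase(k)
  closed <- switch(as.character(k),
    "2"  = log(3) / log(4) - 1,
    "3"  = log(2) / log(3) - 1,
    "4"  = 3 / 4 * log(5) / log(2) - 9 / 4,
    "20" = 19 * log(84 / 23) / log(400) - 355 / 46,
    NULL)
  if (!is.null(closed))
    return(list(k = k, A = closed, method = "closed_form"))
  nMax <- checkCount(nMax, "nMax", min = 1)
  n <- seq_len(nMax)
  excess <- sumsOfDigitsUpTo(nMax, k)[-1] / n - (k - 1) / 2 * log(n) / log(k)
  list(k = k, A = min(excess), method = "numeric_scan", nMax = nMax)
}
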
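#' Riemann zeta on the imaginary axis (Euler-Maclaurin)
#'
#' Evaluates \eqn{\zeta(s)} for complex \eqn{s} with \eqn{Re(s) \ge 0},
#' \eqn{s \ne 1}, by Euler-Maclaurin summation:
#' \deqn{\zeta(s) \approx \sum_{j<N} j^{-s} + \frac{N^{1-s}}{s-1} +
#'   \frac{N^{-s}}{2} + \sum_{r} \frac{B_{2r}}{(2r)!}
#'   s(s+1)\cdots(s+2r-2)\, N^{-s-2r+1}.}
#' The cut-off grows with \eqn{|Im(s)|} (we use \eqn{N \approx
#' 3|Im(s)|/2\pi}), which keeps the Bernoulli tail geometric even high up
#' the imaginary axis -- the regime needed for the Fourier coefficients of
#' the sums-of-digits fluctuation, where general-purpose series
#' accelerations of the Dirichlet eta function lose all accuracy.
#' Accuracy is ~1e-9 absolute up to \eqn{|Im(s)| \sim 2000}.
#'
#' @param s complex scalar or vector, \eqn{Re(s) \ge 0}, \eqn{s \ne 1}.
#' @return complex vector \eqn{\zeta(s)}.
#' @examples
#' zetaComplex(2 + 0i)            # pi^2/6
#' zetaComplex(complex(real = 0, imaginary = 14.13))
#' @export
zetaComplex <- function(s) {
  if (any(Re(s) < 0)) stop("zetaComplex requires Re(s) >= 0")
  if (any(s == 1)) stop("zeta has a pole at s = 1")
  vapply(s, zetaEM1, complex(1))
}

# Bernoulli numbers B_2, B_4, ..., B_16
.bernoulli <- c(1/6, -1/30, 1/42, -1/30, 5/66, -691/2730, 7/6, -3617/510)

zetaEM1 <- function(s) {
  N <- max(25, ceiling(abs(Im(s)) / (2 * pi) * 3) + 30)
  j <- seq_len(N - 1)
  out <- sum(exp(-s * log(j))) + exp((1 - s) * log(N)) / (s - 1) +
    0.5 * exp(-s * log(N))
  poch <- 1 + 0i
  corr <- 0 + 0i
  for (r in seq_along(.bernoulli)) {
    poch <- if (r == 1) s else poch * (s + 2 * r - 3) * (s + 2 * r - 2)
    corr <- corr + .bernoulli[r] / factorial(2 * r) * poch *
      exp(-(s + 2 * r - 1) * log(N))
  }
  out + corr
}
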
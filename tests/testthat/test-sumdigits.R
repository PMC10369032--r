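test_that("digit sums follow the base-k expansion", {
  expect_equal(digitSum(0, 7), 0)
  expect_equal(digitSum(5, 2), 2)
  expect_equal(digitSum(999, 10), 27)
  for (k in c(2, 3, 5, 16)) {
    i <- c(0:25, 999, 12345)
    expect_equal(digitSum(i, k),
                 vapply(i, naiveDigitSum, numeric(1), k = k))
  }
  expect_error(digitSum(-1, 2), "integer-valued")
  expect_error(digitSum(3, 1), "k")
})

test_that("position-counting S_k agrees with naive summation", {
  expect_equal(sumsOfDigits(0, 3), 0)
  expect_equal(sumsOfDigits(5, 2), 5)
  expect_equal(sumsOfDigits(8, 2), 12)   # edges of the 3-cube
  for (k in c(2, 3, 4, 5, 10)) {
    n <- c(1:50, 511, 512, 513, 9999)
    expect_equal(sumsOfDigits(n, k),
                 vapply(n, naiveSumsOfDigits, numeric(1), k = k),
                 info = paste("k =", k))
    ## cumulative helper is an independent (vectorised-naive) path
    expect_equal(sumsOfDigits(0:2000, k),
                 bricklayer:::sumsOfDigitsUpTo(2000, k)[1:2001])
  }
})

test_that("one-level Delange integral matches quadrature of its step integrand", {
  expect_equal(delangeD0(0, 5), 0)
  expect_equal(delangeD0(0.5, 2), 0.5)
  for (m in 0:3) expect_equal(delangeD0(m, 3), 0)  # cancels per unit period
  for (k in c(2, 3, 5)) for (x in c(0.23, 0.5, 0.77, 1.31, 2.6))
    expect_equal(delangeD0(x, k), quadD0(x, k), tolerance = 1e-4)
  expect_error(delangeD0(-0.1, 2), "non-negative")
})

test_that("Delange series matches direct partial summation", {
  expect_equal(delangeD(0, 4), 0)
  expect_equal(delangeD(0.5, 2, 1e-12), 0.5)  # only the n = 0 term survives
  for (k in c(2, 3)) for (x in c(1 / 3, 0.1, 0.62, 0.9)) {
    expect_equal(delangeD(x, k, 1e-10), partialDelange(x, k, 60),
                 tolerance = 1e-9)
  }
  expect_error(delangeD(0.5, 2, tol = 0), "tol")
})

test_that("periodic fluctuation g_k vanishes at the period ends", {
  for (k in c(2, 3, 4, 7)) {
    expect_equal(delangeG(1, k, 1e-12), 0, tolerance = 1e-12)
    expect_equal(delangeG(1 / k, k, 1e-12), 0, tolerance = 1e-12)
  }
  ## round-trip oracle at n = 3, k = 2: {log2 3} - 1 = log2 0.75, so
  ## g_2(0.75) = log2 3 - (2/3) S_2(3)
  expect_equal(delangeG(0.75, 2, 1e-12),
               log(3) / log(2) - 2 / 3 * naiveSumsOfDigits(3, 2),
               tolerance = 1e-10)
  expect_error(delangeG(0, 2), "positive")
})

test_that("Trollope-Delange closed form rounds to the exact S_k", {
  expect_equal(trollopeDelangeS(1, 5), 0)
  expect_equal(round(trollopeDelangeS(5, 2, 1e-9)), 5)
  for (k in c(2, 3, 4)) {
    n <- 1:2000
    s <- trollopeDelangeS(n, k, 1e-12)
    exact <- bricklayer:::sumsOfDigitsUpTo(2000, k)[-1]
    expect_equal(round(s), exact, info = paste("k =", k))
    expect_lt(max(abs(s - exact) / pmax(1, exact)), 1e-6)
  }
  ## powers of k are the numerically dangerous points: S_k(k^m) must be
  ## exact (no fractional-part glitch from floating logs)
  for (k in c(2, 3, 4)) for (m in 1:12) {
    expect_equal(trollopeDelangeS(k^m, k), m * (k - 1) * k^m / 2,
                 tolerance = 1e-9, info = paste(k, m))
  }
  expect_error(trollopeDelangeS(0, 2), "integer-valued")
})

test_that("complex zeta matches reference values", {
  expect_equal(Re(zetaComplex(2 + 0i)), pi^2 / 6, tolerance = 1e-12)
  ## frozen multiprecision reference values on the imaginary axis
  expect_equal(zetaComplex(complex(real = 0, imaginary = 10)),
               complex(real = 1.75646859297496, imaginary = -0.101511985436171),
               tolerance = 1e-10)
  expect_equal(zetaComplex(complex(real = 0, imaginary = 1813)),
               complex(real = 34.8510420472643, imaginary = 22.0287089902125),
               tolerance = 1e-8)
  skip_if_not_installed("pracma")
  for (t in c(5, 15)) {  # pracma's series loses accuracy higher up the axis
    s <- complex(real = 0.5, imaginary = t)
    expect_equal(zetaComplex(s), pracma::zeta(s), tolerance = 1e-6)
  }
})

test_that("Fourier coefficients are conjugate-symmetric and reconstruct g_k", {
  for (n in 1:3)
    expect_equal(fourierCoefficient(-n, 2), Conj(fourierCoefficient(n, 2)))
  ## c_1 against a direct quadrature Fourier integral
  xs <- (0:8191 + 0.5) / 8192
  g <- delangeG(2^(xs - 1), 2, 1e-12)
  expect_equal(fourierCoefficient(1, 2), mean(g * exp(-2i * pi * xs)),
               tolerance = 1e-5)
  ## partial sums approximate the function pointwise
  for (x in c(0.11, 0.37, 0.83))
    expect_lt(abs(fourierPartialSum(x, 2, 200) - delangeG(2^(x - 1), 2, 1e-12)),
              0.05)
  expect_lt(abs(fourierPartialSum(0.2, 3, 100) - delangeG(3^(0.2 - 1), 3, 1e-12)),
            0.05)
  expect_error(fourierCoefficient(0, 2), "non-zero")
})

test_that("alphabet constants: closed forms, scan consistency, asymptotics", {
  expect_equal(alphabetConstant(2)$A, log(3) / log(4) - 1)
  expect_equal(alphabetConstant(3)$A, log(2) / log(3) - 1)
  expect_equal(alphabetConstant(4)$A, 3 / 4 * log(5) / log(2) - 9 / 4)
  expect_equal(alphabetConstant(20)$A, 19 * log(84 / 23) / log(400) - 355 / 46)
  expect_identical(alphabetConstant(4)$method, "closed_form")

  ## the numeric scan is an upper estimate of the infimum; at 1e5 it sits
  ## just above the known closed forms
  for (k in c(2, 3, 4)) {
    n <- seq_len(1e5)
    ex <- bricklayer:::sumsOfDigitsUpTo(1e5, k)[-1] / n -
      (k - 1) / 2 * log(n) / log(k)
    expect_gte(min(ex), alphabetConstant(k)$A)
    expect_lt(min(ex) - alphabetConstant(k)$A, 1e-3)
  }
  a5 <- alphabetConstant(5, nMax = 1e5)
  expect_identical(a5$method, "numeric_scan")
  expect_lte(a5$A, 0)

  ## superadditivity window: A_k <= S_k(n)/n - ((k-1)/2) log_k n <= 0
  for (k in c(2, 5)) {
    n <- seq_len(5000)
    ex <- bricklayer:::sumsOfDigitsUpTo(5000, k)[-1] / n -
      (k - 1) / 2 * log(n) / log(k)
    expect_true(all(ex <= 1e-12))
    expect_true(all(ex >= alphabetConstant(k, nMax = 5000)$A - 1e-12))
  }

  ## Bush asymptotics: S_k(n) ~ (n/2)(k-1) log_k n
  expect_gt(sumsOfDigits(1e6, 2) / ((1e6 / 2) * log(1e6) / log(2)), 0.9)
  expect_lte(sumsOfDigits(1e6, 2) / ((1e6 / 2) * log(1e6) / log(2)), 1)

  ## large-k trend: A_k / (-k/2) in (0,1), growing towards the
  ## 1 - log log k / log k regime
  r <- vapply(c(8, 16, 32),
              function(k) alphabetConstant(k, nMax = 1e5)$A / (-k / 2),
              numeric(1))
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(r) > 0))
})
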
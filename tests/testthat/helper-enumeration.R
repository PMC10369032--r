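# Exhaustive enumeration of the sums-of-digits split inequality over all
# ascending k-tuples with a bounded total.  Vectorised over the innermost
# indices so whole-range sweeps stay fast; S_k values come from the
# package's cumulative table and the scalar digitSumSplitInequality()
# operation is cross-checked against this sweep on sampled tuples.
splitInequalityHoldsAll <- function(k, total) {
  S <- bricklayer:::sumsOfDigitsUpTo(total, k)   # S[n + 1] = S_k(n)
  ok <- TRUE
  checkTail <- function(prefix, wsum, lo, budget) {
    # one free index left: n_k in [lo, budget], vectorised
    if (budget < lo) return(invisible())
    nk <- lo:budget
    lhs <- sum(S[prefix + 1]) + wsum + S[nk + 1]
    rhs <- S[sum(prefix) + nk + 1]
    if (any(lhs > rhs)) ok <<- FALSE
    invisible()
  }
  w <- k - seq_len(k - 1)                        # weights of n_1..n_{k-1}
  if (k == 2) {
    for (n1 in 0:(total %/% 2))
      checkTail(n1, w[1] * n1, n1, total - n1)
  } else if (k == 3) {
    for (n1 in 0:(total %/% 3))
      for (n2 in n1:((total - n1) %/% 2))
        checkTail(c(n1, n2), w[1] * n1 + w[2] * n2, n2, total - n1 - n2)
  } else if (k == 4) {
    for (n1 in 0:(total %/% 4))
      for (n2 in n1:((total - n1) %/% 3))
        for (n3 in n2:((total - n1 - n2) %/% 2))
          checkTail(c(n1, n2, n3),
                    w[1] * n1 + w[2] * n2 + w[3] * n3,
                    n3, total - n1 - n2 - n3)
  } else stop("helper supports k in 2:4")
  ok
}
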
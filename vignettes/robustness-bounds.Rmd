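---
title: "Robustness bounds for genotype-phenotype maps: model and methods"
author: "bricklayer package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness bounds for genotype-phenotype maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bricklayer)
```

## The model

A genotype-phenotype (GP) map assigns each of the $k^\ell$ sequences of
length $\ell$ over a $k$-letter alphabet to one phenotype.  The genotype
space is the Hamming graph $H_{\ell,k}$ (edges = single-character
mutations, every vertex of degree $\ell(k-1)$), a phenotype's neutral set
is the induced subgraph $G_p$ on its genotypes, and its mutational
robustness is the fraction of mutations that are neutral,
$$\rho_p = \frac{2|E(G_p)|}{\ell(k-1)\,|V(G_p)|} \in [0, 1].$$

Maximising $\rho_p$ at fixed $n = |V(G_p)|$ is the Hamming-graph
edge-isoperimetric problem.  Its optimum is the *bricklayer's graph*
$G_{n,k}$: label vertices $0,\dots,k^\ell-1$ by reading genotypes as
base-$k$ integers and take the first $n$ labels.  Its edge count is the
sums-of-digits function $S_k(n) = \sum_{i<n} s_k(i)$, giving the exact
maximum curve $\rho^{max}(n) = 2S_k(n)/(n\ell(k-1))$.  Three further
curves complete the picture:

* the continuous interpolation of $\rho^{max}$ through the
  Trollope-Delange closed form
  $S_k(n) = \tfrac n2[(k-1)\log_k n - g_k(k^{\{\log_k n\}-1})]$, whose
  periodic part $g_k$ contains the fractal Delange function $D_k$ (the
  Takagi/blancmange function when $k=2$);
* the sandwich $\log_k(n)/\ell + 2A_k/((k-1)\ell) \le \rho^{max}(n) \le
  \log_k(n)/\ell$ with the alphabet constant
  $A_k = \inf_n [S_k(n)/n - \tfrac{k-1}2\log_k n] \le 0$;
* the minimum for a *connected* neutral component,
  $\rho^{min}(n) = \tfrac{2}{\ell(k-1)}(1 - 1/n)$ (a connected graph has
  at least $n-1$ edges), and the random-null expectation
  $\rho \approx f = n/k^\ell$.

On top of the curves, the package analyses complete maps: neutral
components, a transition matrix $\phi_{ts}$ (column-stochastic, detailed
balance $\phi_{ts}f_s = \phi_{st}f_t$, diagonal $\rho_s$ with the factor-2
convention for within-set edges), a lower bound on the robustness deficit
of multi-component neutral sets derived from the superadditivity-type
inequality $\sum_i S_k(n_i) + \sum_{i<k}(k-i)n_i \le S_k(\sum_i n_i)$
(ascending $n_i$), and phenotype coarse-graining with critical
transition-probability windows.

## Parameters that matter

| parameter | meaning | default / range |
|---|---|---|
| $k$ | alphabet size | $\ge 2$; closed-form $A_k$ for $k \in \{2,3,4,20\}$ |
| $\ell$ | sequence length | $\ge 1$; $k^\ell < 2^{53}$ so counts stay exact |
| `tol` | Delange series truncation | `1e-12`; tail bound $\sup|D_{k,0}|\,k^{-N}/(1-1/k)$ with $\sup|D_{k,0}| = k/4$ |
| `nMax` | scan range for non-closed-form $A_k$ | $10^6$; the scan minimum is an *upper* estimate of the infimum and is flagged `numeric_scan` |
| `budget` | brute-force subset enumeration cap | $10^7$ subsets; above it the oracle refuses rather than samples |
| `seed` | random-null generator | required, no default: generated maps must be reproducible |

## Numerical choices

* **Integer arithmetic in doubles.**  All counts ($S_k$, edge counts,
  vertex labels) are exact below $2^{53}$; inputs are validated against
  that range.  $S_k(n)$ uses a per-digit-position counting recursion,
  $O(\log_k n)$, with naive digit-sum summation kept as the test oracle.
* **No floating logarithms where fractional parts are fragile.**  At
  $n = k^m$ a floating $\log_k n$ can land at $m - \epsilon$ and corrupt
  the fractal term.  Exact powers are found by integer comparison and the
  fractal argument is formed as the exact rational $x = n/k^{m+1}$; the
  log terms are then combined analytically, so the Delange series for
  rational $x$ terminates exactly (every term with $k^t x$ integer
  vanishes).  This is why `round(trollopeDelangeS(n, k))` reproduces
  $S_k(n)$ exactly for all tested $n \le 10^4$.
* **$D_{k,0}$ in closed form.**  The integrand $2k[t]-2[kt]+k-1$ is a
  step function, constant on $[j/k,(j+1)/k)$ and 1-periodic, so the
  integral is evaluated per segment; no quadrature.
* **Riemann zeta on the imaginary axis.**  The Fourier coefficients of
  the periodic fluctuation need $\zeta(2\pi i n/\log k)$ up to
  $|{\rm Im}| \approx 1800$.  An internal Euler-Maclaurin evaluator with
  cut-off $N \approx 3|{\rm Im}(s)|/2\pi$ and Bernoulli corrections to
  $B_{16}$ achieves $\sim 10^{-9}$ there; it is checked in the tests
  against frozen multiprecision reference values and against a quadrature
  Fourier integral.  The coefficient's overall sign is fixed by requiring
  partial sums to reconstruct $g_k$ itself in the $e^{+2\pi i n x}$
  convention (published variants differ in sign depending on whether the
  expanded fluctuation is $g_k$ or its negative); $c_0$, excluded by the
  coefficient formula's pole, is a midpoint-grid period mean, since
  adaptive quadrature is unreliable on a fractal integrand.
* **Attainment decided on integers.**  A neutral component "attains the
  maximum" iff its edge count equals $S_k(n)$ as integers; no float
  tolerance enters the headline claim.
* **Deterministic orderings.**  Phenotype labels are ordered by
  descending neutral-set size, ties lexicographic; components by smallest
  vertex label; all CSV exports are byte-stable re-runs.
* **Degenerate inputs.**  $n=0$ gives empty graphs with zero edges;
  single-phenotype maps give the $1\times1$ matrix $[1]$; a partition
  group of one is the identity.

## Design decisions

* **Multi-component bound beyond its proven range.**  The deficit bound
  is proven for $m \le k$ components.  Fewer components are zero-padded
  (harmless: $S_k(0)=0$ and zero sizes carry zero weight).  For $m > k$
  the same expression is evaluated from the $k-1$ smallest components —
  the natural truncation of the ascending-tuple structure — and flagged
  `proven = FALSE`; the package reports, and never asserts, the extension.
* **Critical merge window.**  The merged robustness is linear in
  $\phi_{qp}$, so the window follows by solving
  $\rho_S(\phi) = 1 + \log_k(f_p+f_q)/\ell - \Delta$ at
  $\Delta = \max(\Delta_p,\Delta_q)$ (lower edge) and $\min$ (upper
  edge) in closed form; a substitution oracle in the tests guards the
  algebra.  Base-$k$ logarithms are used throughout.  Displacements
  $\Delta = 1 + \log_k(f)/\ell - \rho$ are clipped at zero with a warning
  when a small neutral set sits above the *asymptotic* line, which the
  high-robustness approximation does not model.
* **Pair orientation.**  Within each pair $p$ is the more frequent
  phenotype, so $\beta = f_q/f_p \in (0,1]$, and the reported
  $\phi_{qp}$ is the transition probability out of $p$.
* **Totality of GP maps.**  The conservation laws (columns summing to 1,
  the full-merge identity) require the map to cover every genotype, so
  partial input files are an error unless a default label (e.g. `"."`
  for unfolded) is supplied; the trivial phenotype is an ordinary
  phenotype internally and can be excluded from *reports* only.
* **Interface.**  The analysis surface is the exported functions; the
  thin `inst/scripts/bricklayer-tool.R` wrapper (subcommands `curve`,
  `analyze`, `coarsegrain`, `fixtures`, `thresholds`; exit codes 0/2/3
  for success/usage/budget-refusal) adds shell scriptability without any
  logic of its own.

## What the generators emulate — and what they do not

`bricklayerPackedMap()` realises the extremal structure: consecutive
integer blocks, the first being exactly $G_{n,k}$.  `randomNullMap()`
draws a uniform random partition of the vertices with fixed block sizes —
the null ensemble in which $\rho_p \approx f_p$ and $\phi_{ts} \approx
f_t$.  Real GP maps (RNA secondary structure, HP protein folding) are
*neither*: they are strongly correlated, with robustness orders of
magnitude above the null yet below the bricklayer curve, and their
neutral components have biophysical structure (modularity, constrained
sites) that neither generator produces.  Passing tests therefore certify
the combinatorics, the curves and the algebra — not any biological claim
about where real maps sit between the curves.

A finite-size caveat worth recording: for a size-$n$ block of the random
null on $N = k^\ell$ vertices the exact expectation is
$E[\rho] = (n-1)/(N-1)$, which approaches the frequency $f = n/N$ only as
$N \to \infty$.  On spaces as small as $N = 64$ the gap
$(N-n)/(N(N-1))$ is resolvable by a few hundred Monte-Carlo replicates
(it sits near $3$ standard errors of a 200-replicate mean for every
block size), so stochastic checks of the $\rho \approx f$ scaling at that
size are intrinsically borderline; checks of the generator itself use
the exact expectation.

## Problem sizes used in the test suite

Exhaustive oracles run where exhaustion is feasible: brute-force subset
maxima on $H_{3,2}$, $H_{4,2}$, $H_{2,3}$ (all $2^{16}$ subsets at the
largest); bricklayer edge counts for $k \in \{2,3,4\}$, $\ell \in
\{2,3\}$; the split inequality for all ascending tuples with total
$\le 200$ for $k \in \{2,3,4\}$; the closed form against exact $S_k(n)$
for $n \le 10^4$; whole-space curve sweeps up to $k=4, \ell=10$
($\sim 10^6$ sizes); 200-replicate Monte-Carlo ensembles on $H_{6,2}$.

## Known limitations

* $A_k$ for $k \notin \{2,3,4,20\}$ is a numeric-scan estimate (an upper
  bound on the infimum), not the exact constant; the exact algorithm
  for general $k$ is out of scope.
* Fourier partial sums converge slowly (the function is fractal);
  reconstruction is a few $10^{-4}$ at 200 harmonics, and the package
  makes no uniform-convergence claim.
* Whole-map analyses materialise per-vertex structures; they are meant
  for spaces up to $\sim 10^6$ genotypes, not for the full RNA15 space.
* The package consumes already-folded GP maps; sequence-to-structure
  folding itself (ViennaRNA, HP lattice models) is out of scope.
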
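# bricklayer

Mutational robustness bounds for genotype–phenotype (GP) maps.

## The problem

A GP map assigns every sequence of length ℓ over a k-letter alphabet
(RNA: k = 4; proteins: k = 20) to a phenotype. The genotypes sharing a
phenotype form its *neutral set*, an induced subgraph of the Hamming graph
H<sub>ℓ,k</sub>, and the phenotype's mutational robustness is the fraction
of single-character mutations that stay inside the set:

ρ<sub>p</sub> = 2|E(G<sub>p</sub>)| / (ℓ(k−1)|V(G<sub>p</sub>)|).

How large can ρ<sub>p</sub> be for a neutral set of n genotypes? This is
the edge-isoperimetric problem on the Hamming graph: the optimum is the
**bricklayer's graph** — the subgraph induced by the first n integer
labels in base-k order — whose edge count is the number-theoretic
sums-of-digits function S<sub>k</sub>(n) = Σ<sub>i&lt;n</sub> s<sub>k</sub>(i).
Hence the exact maximum-robustness curve

ρ<sup>max</sup>(n) = 2 S<sub>k</sub>(n) / (n ℓ (k−1)),

a self-similar, continuous-everywhere / differentiable-nowhere
("blancmange-like") curve whose fractal part is the Delange function (the
Takagi function for k = 2). It is sandwiched by

log<sub>k</sub>(n)/ℓ + 2A<sub>k</sub>/((k−1)ℓ) ≤ ρ<sup>max</sup>(n) ≤ log<sub>k</sub>(n)/ℓ,

where A<sub>k</sub> ≤ 0 is an alphabet constant with closed forms for
k ∈ {2, 3, 4, 20}. The package computes these curves exactly, analyzes
complete GP maps against them (neutral sets, neutral components,
transition matrices, a deviation bound for multi-component neutral sets),
and implements phenotype coarse-graining with critical
transition-probability thresholds for pairwise merges.

For whom: researchers studying neutral networks, robustness and
evolvability in GP maps (RNA secondary structure, HP protein models,
gene-regulatory and other discrete input–output maps) who need exact
reference curves and map-level analyses.

## Worked example

```r
library(bricklayer)

sp <- GenotypeSpace(k = 2, length = 3)        # the 3-cube
rhoMax(5, sp)                                  # 0.6666667
sumsOfDigits(5, 2)                             # 5  (edges of G_{5,2})
round(trollopeDelangeS(5, 2))                  # 5  (fractal closed form)

# bounds for length-12 RNA (k = 4)
rna <- GenotypeSpace(4, 12, c("A", "C", "G", "U"))
alphabetConstant(4)$A                          # -0.5085539
b <- rhoBounds(1000, rna)
b$lower - b$upper                              # -0.02825299

# analyze a complete GP map
m  <- bricklayerPackedMap(sp, c(5, 3))
phenotypeStats(m)[, c("label", "n", "rho")]
#    label n       rho
# P1    P1 5 0.6666667     <- attains the bricklayer bound exactly
# P2    P2 3 0.4444444

tm <- transitionMatrix(m)
transitionProbs(tm)
#           P1        P2
# P1 0.6666667 0.5555556
# P2 0.3333333 0.4444444   (columns sum to 1)

# merge both phenotypes: the whole Hamming graph, robustness 1
coarseGrain(tm, c(P1 = "all", P2 = "all"))
```

The first phenotype of the packed map occupies vertices 000…100, i.e. the
bricklayer's graph G<sub>5,2</sub> with S<sub>2</sub>(5) = 5 edges, so its
robustness 2·5/(5·3·1) = 2/3 equals `rhoMax(5, sp)`. Cross-phenotype
entries of the transition matrix count boundary edges, and merging all
phenotypes turns every mutation neutral (ρ = 1).

A command-line wrapper with subcommands `curve`, `analyze`, `coarsegrain`,
`fixtures` and `thresholds` is installed at
`system.file("scripts", "bricklayer-tool.R", package = "bricklayer")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","bricklayer-tool.R",package="bricklayer"))')" \
  curve --k 2 --length 6 --out curve.csv
```

## Vignette

`vignettes/robustness-bounds.Rmd` documents the model, the numerical
choices (exact integer S<sub>k</sub>, rational fractal arguments,
Euler–Maclaurin zeta), the generators behind the tests, and known
limitations.
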
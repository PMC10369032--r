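Package: bricklayer
Title: Mutational Robustness Bounds for Genotype-Phenotype Maps
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact maximum, minimum and null mutational-robustness curves
    for genotype-phenotype maps on Hamming graphs. The maximum-robustness
    curve is computed from bricklayer's graphs, whose edge counts are given
    by the number-theoretic sums-of-digits function and its fractal
    Trollope-Delange closed form (the Takagi/blancmange function for binary
    alphabets). Includes Galkin-Galkina upper/lower bounds with exact
    alphabet constants, analysis of neutral sets, neutral components and
    phenotype transition matrices of complete genotype-phenotype maps
    against these bounds, a multi-component deviation bound from a
    superadditivity property of the sums-of-digits function, and phenotype
    coarse-graining with critical transition-probability thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph
Suggests: testthat (>= 3.0.0), jsonlite, optparse, pracma, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
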
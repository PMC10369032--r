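## High-level entry points mirroring the command-line tool: each takes a
## small set of scalar options, writes CSV, and returns the table(s)
## invisibly.  All outputs are deterministic given the inputs (and seed),
## and use '.' as the decimal separator regardless of locale.

writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate the robustness-curve table for a genotype space
#'
#' Tabulates, for every integer neutral-set size `n` (plus an optional
#' dense grid for the continuous blancmange interpolation), the exact
#' maximum robustness, the continuous curve, the log upper bound, the
#' Galkin-Galkina lower bound, the single-component minimum and the random
#' null expectation.  Mirrors the curve export of a robustness-bound
#' calculator: columns `n`, `f`, `rho_max`, `rho_max_cont`, `rho_upper`,
#' `rho_lower`, `rho_min`, `rho_null`.
#'
#' @param k alphabet size.
#' @param length sequence length \eqn{\ell}.
#' @param out optional CSV path.
#' @param gridPoints number of extra non-integer grid points interleaved
#'   for the continuous curve (0 for integer sizes only).
#' @param tol Delange-series tolerance.
#' @return the data.frame, invisibly when `out` is given.
#' @examples
#' head(runCurve(2, 4))
#' @export
runCurve <- function(k, length, out = NULL, gridPoints = 0L, tol = 1e-10) {
  space <- GenotypeSpace(k, length)
  N <- nGenotypes(space)
  n <- seq_len(N)
  if (gridPoints > 0) {
    dense <- exp(seq(log(1), log(N), length.out = gridPoints))
    n <- sort(unique(c(n, dense)))
  }
  curve <- robustnessCurve(space, n, tol = tol)
  if (!is.null(out)) { writeCsv(curve, out); return(invisible(curve)) }
  curve
}

#' Analyze a GP-map file against the robustness bounds
#'
#' Reads a complete GP map and writes/returns three tables: per-phenotype
#' statistics with per-component bound-attainment flags
#' ([phenotypeStats()]; the nested component table is flattened to one row
#' per component), the phenotype transition matrix, and the
#' multi-component deviation table ([deviationTable()]).
#'
#' @param path GP-map TSV (see [readGPMap()]).
#' @param outPrefix optional path prefix; writes
#'   `<prefix>_phenotypes.csv`, `<prefix>_components.csv`,
#'   `<prefix>_matrix.csv`, `<prefix>_deviation.csv`.
#' @param symbols,defaultPhenotype forwarded to [readGPMap()].
#' @param excludeLabel optional phenotype label (e.g. the unfolded/trivial
#'   phenotype) dropped from the *reported* phenotype/component/deviation
#'   tables; the transition matrix always keeps every phenotype so that
#'   its conservation laws stay intact.
#' @return list with `map`, `phenotypes`, `components`, `matrix`,
#'   `deviation`.
#' @export
runAnalyze <- function(path, outPrefix = NULL, symbols = NULL,
                       defaultPhenotype = NULL, excludeLabel = NULL) {
  map <- readGPMap(path, symbols, defaultPhenotype)
  stats <- phenotypeStats(map)
  comp <- do.call(rbind, lapply(seq_len(nrow(stats)), function(i)
    cbind(label = stats$label[i], component = seq_len(stats$n_components[i]),
          stats$components[[i]])))
  dev <- deviationTable(map)
  tm <- transitionMatrix(map)
  if (!is.null(excludeLabel)) {
    stats <- stats[stats$label != excludeLabel, , drop = FALSE]
    comp <- comp[comp$label != excludeLabel, , drop = FALSE]
    dev <- dev[dev$label != excludeLabel, , drop = FALSE]
  }
  if (!is.null(outPrefix)) {
    writeCsv(stats[, setdiff(names(stats), "components")],
             paste0(outPrefix, "_phenotypes.csv"))
    writeCsv(comp, paste0(outPrefix, "_components.csv"))
    writeTransitionMatrix(tm, paste0(outPrefix, "_matrix.csv"))
    writeCsv(dev, paste0(outPrefix, "_deviation.csv"))
  }
  invisible(list(map = map, phenotypes = stats, components = comp,
                 matrix = tm, deviation = dev))
}

#' Coarse-grain a GP map by a phenotype partition
#'
#' Reads a GP map and a phenotype partition, coarse-grains at the map
#' level, and classifies every pair of *original* phenotypes against the
#' critical transition-probability window ([classifyPairs()]).
#'
#' @param path GP-map TSV.
#' @param partitionPath partition TSV (see [readPartition()]).
#' @param outPrefix optional path prefix; writes `<prefix>_coarse.csv`
#'   (square matrix) and `<prefix>_pairs.csv`.
#' @param symbols,defaultPhenotype forwarded to [readGPMap()].
#' @return list with `coarse` ([TransitionMatrix-class]) and `pairs`
#'   (classification data.frame).
#' @export
runCoarseGrain <- function(path, partitionPath, outPrefix = NULL,
                           symbols = NULL, defaultPhenotype = NULL) {
  map <- readGPMap(path, symbols, defaultPhenotype)
  partition <- readPartition(partitionPath)
  coarse <- coarseGrainMap(map, partition)
  tm <- transitionMatrix(map)
  pairs <- if (length(phenotypeLabels(map)) >= 2L) classifyPairs(tm)
           else NULL
  if (!is.null(outPrefix)) {
    writeTransitionMatrix(coarse, paste0(outPrefix, "_coarse.csv"))
    if (!is.null(pairs)) writeCsv(pairs, paste0(outPrefix, "_pairs.csv"))
  }
  invisible(list(coarse = coarse, pairs = pairs))
}

#' Write generated GP-map fixtures
#'
#' Generates a random-null or bricklayer-packed GP map and writes it as a
#' GP-map TSV that round-trips through [readGPMap()].
#'
#' @param kind `"random"` or `"bricklayer"`.
#' @param k,length the genotype space.
#' @param sizes neutral-set sizes summing to \eqn{k^\ell}.
#' @param out output TSV path.
#' @param seed required for `kind = "random"`.
#' @return the generated [GPMap-class], invisibly.
#' @export
runFixture <- function(kind = c("random", "bricklayer"), k, length, sizes,
                       out, seed = NULL) {
  kind <- match.arg(kind)
  space <- GenotypeSpace(k, length)
  map <- switch(kind,
    random = {
      if (is.null(seed)) stop("'seed' is required for random fixtures")
      randomNullMap(space, sizes, seed)
    },
    bricklayer = bricklayerPackedMap(space, sizes))
  writeGPMap(map, out)
  invisible(map)
}

#' Report the percolation-type thresholds for a space
#'
#' @param k alphabet size.
#' @param length sequence length.
#' @return data.frame with the percolation threshold \eqn{1/[\ell(k-1)]}
#'   and the giant-component threshold \eqn{1 - k^{-1/(k-1)}}.
#' @export
runThresholds <- function(k, length) {
  space <- GenotypeSpace(k, length)
  data.frame(k = k, length = length,
             percolation = percolationThreshold(space),
             giant_component = giantComponentThreshold(k))
}
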
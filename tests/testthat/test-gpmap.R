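makeMap <- function(k, l, assignment) GPMap(GenotypeSpace(k, l), assignment)

test_that("GP-map files round-trip and are validated on read", {
  sp <- GenotypeSpace(2, 3)
  map <- bricklayerPackedMap(sp, c(5, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGPMap(map, path)
  back <- readGPMap(path)
  expect_equal(phenotypeAssignment(back), phenotypeAssignment(map))
  expect_equal(genotypeSymbols(genotypeSpace(back)), c("0", "1"))

  ## missing genotype: error without a default, filled with one
  lines <- readLines(path)
  writeLines(lines[-2], path)              # drop genotype "000"
  expect_error(readGPMap(path), "total")
  filled <- readGPMap(path, defaultPhenotype = ".")
  expect_equal(phenotypeAssignment(filled)[1], ".")

  ## duplicate consistent row accepted with a message, conflict rejected
  writeLines(c(lines, lines[2]), path)
  expect_message(readGPMap(path), "duplicate")
  writeLines(c(lines, "000\tZZ"), path)
  expect_error(readGPMap(path), "conflicting")

  ## ragged lengths and foreign symbols
  writeLines(c("00\tA", "111\tB"), path)
  expect_error(readGPMap(path), "ragged")
  writeLines(c("00\tA", "01\tA", "10\tB", "1x\tB"), path)
  expect_error(readGPMap(path, symbols = c("0", "1")), "outside")
})

test_that("phenotype statistics report robustness and bound attainment", {
  m <- makeMap(2, 3, c(rep("A", 5), rep("B", 3)))
  st <- phenotypeStats(m)
  expect_equal(st["A", "rho"], 2 / 3)
  expect_equal(st["A", "n_components"], 1)
  expect_true(st$components[["A"]]$attains_max)

  ## two opposite corners: two singleton components, zero robustness
  m2 <- makeMap(2, 2, c("A", "B", "B", "A"))
  st2 <- phenotypeStats(m2)
  expect_equal(st2["A", "rho"], 0)
  expect_equal(st2["A", "n_components"], 2)
  expect_true(all(st2$components[["A"]]$attains_max))  # S_k(1) = 0
  expect_true(all(st2$components[["A"]]$attains_min))

  ## single phenotype covers the space: robustness one
  m3 <- makeMap(2, 2, rep("all", 4))
  expect_equal(phenotypeStats(m3)$rho, 1)

  ## every phenotype of any map sits between the curves
  set.seed(8)
  sp <- GenotypeSpace(2, 4)
  for (rep in 1:5) {
    m <- randomNullMap(sp, c(6, 5, 5), seed = sample.int(1e6, 1))
    st <- phenotypeStats(m)
    for (i in seq_len(nrow(st))) {
      expect_lte(st$rho[i], rhoMax(st$n[i], sp) + 1e-12)
      cs <- st$components[[i]]
      expect_true(all(cs$rho >= rhoMin(cs$size, sp) - 1e-12))
      expect_equal(sum(cs$size), st$n[i])
      expect_equal(sum(cs$edges), st$edges[i])
    }
  }
})

test_that("transition matrix is column-stochastic with detailed balance", {
  m <- makeMap(2, 2, c("A", "A", "B", "B"))
  tm <- transitionMatrix(m)
  expect_equal(unname(transitionProbs(tm)), matrix(0.5, 2, 2))

  single <- transitionMatrix(makeMap(2, 2, rep("x", 4)))
  expect_equal(unname(transitionProbs(single)), matrix(1, 1, 1))

  set.seed(13)
  sp <- GenotypeSpace(3, 3)
  for (rep in 1:4) {
    m <- randomNullMap(sp, c(14, 8, 5), seed = sample.int(1e6, 1))
    tm <- transitionMatrix(m)
    phi <- transitionProbs(tm)
    f <- phenotypeFrequencies(tm)
    expect_equal(unname(colSums(phi)), rep(1, 3), tolerance = 1e-12)
    bal <- sweep(phi, 2, f, "*")
    expect_equal(bal, t(bal), tolerance = 1e-12)
    ## all neutral-plus-cross mutation mass adds to every Hamming edge
    expect_equal(sum(diag(phi) * f) +
                   2 * sum(bal[upper.tri(bal)]), 1, tolerance = 1e-12)
    ## diagonal equals per-phenotype robustness from the stats table
    st <- phenotypeStats(m)
    expect_equal(unname(diag(phi)), st$rho)
  }
})

test_that("random-null transitions scale like target frequency", {
  ## off-diagonal E[phi_ts] ~ f_t in the random-null ensemble
  sp <- GenotypeSpace(2, 5)
  phis <- replicate(150, {
    tm <- transitionMatrix(randomNullMap(sp, c(16, 16), seed = sample.int(1e6, 1)))
    transitionProbs(tm)["P2", "P1"]
  })
  ## exact expectation: cross edges between fixed-size random blocks
  N <- nGenotypes(sp); n1 <- 16; n2 <- 16
  exact <- n2 / (N - 1)     # = E|E(G1,G2)| / (deg * n1)
  expect_lt(abs(mean(phis) - exact), 3 * stats::sd(phis) / sqrt(length(phis)))
  expect_lt(abs(mean(phis) - n2 / N), 0.05)   # the f_t scaling itself
})

test_that("deviation table compares measured deficits with the proven bound", {
  ## a phenotype that IS a bricklayer's graph: zero deficit, zero bound
  m <- makeMap(2, 3, c(rep("A", 5), rep("B", 3)))
  dev <- deviationTable(m)
  expect_equal(dev["A", "lhs"], 0)
  expect_equal(dev["A", "rhs"], 0)

  ## two opposite corners of H_{2,2}: equality case of the bound
  m2 <- makeMap(2, 2, c("A", "B", "B", "A"))
  dev2 <- deviationTable(m2)
  expect_equal(dev2["A", "lhs"], rhoMax(2, GenotypeSpace(2, 2)))
  expect_equal(dev2["A", "lhs"], dev2["A", "rhs"])  # = 1/l = 1/2

  ## proven rows always satisfy the bound on random maps
  set.seed(17)
  sp <- GenotypeSpace(2, 4)
  for (rep in 1:10) {
    m <- randomNullMap(sp, c(8, 4, 4), seed = sample.int(1e6, 1))
    dev <- deviationTable(m)
    expect_true(all(dev$holds[dev$proven]))
  }
})

test_that("map generators honour sizes, seeds and the bricklayer contract", {
  sp <- GenotypeSpace(2, 3)
  m1 <- randomNullMap(sp, c(4, 4), seed = 7)
  m2 <- randomNullMap(sp, c(4, 4), seed = 7)
  expect_identical(phenotypeAssignment(m1), phenotypeAssignment(m2))
  m3 <- randomNullMap(sp, c(4, 4), seed = 8)
  expect_false(identical(phenotypeAssignment(m1), phenotypeAssignment(m3)))
  expect_error(randomNullMap(sp, c(4, 5), seed = 1), "sum to")
  expect_error(randomNullMap(sp, c(4, 4)), "required")

  trivial <- randomNullMap(sp, 8, seed = 1)
  expect_equal(phenotypeStats(trivial)$rho, 1)

  ## generating a map must not disturb the caller's RNG stream
  set.seed(42); a <- stats::runif(1)
  set.seed(42); invisible(randomNullMap(sp, c(4, 4), seed = 3))
  expect_identical(stats::runif(1), a)

  packed <- bricklayerPackedMap(sp, c(5, 3))
  expect_equal(neutralSet(packed, "P1"), 0:4)
  st <- phenotypeStats(packed)
  expect_equal(st["P1", "rho"], rhoMax(5, sp))
  expect_true(st$components[["P1"]]$attains_max)
  expect_lte(st["P2", "rho"], rhoMax(3, sp))
  expect_equal(phenotypeStats(bricklayerPackedMap(sp, 8))$rho, 1)
})

test_that("random-null robustness matches its exact expectation", {
  ## E[rho] for a size-n block of a uniform partition is (n-1)/(N-1)
  sp <- GenotypeSpace(2, 5)
  N <- nGenotypes(sp); n <- 12
  set.seed(4)
  rho <- replicate(200, {
    m <- randomNullMap(sp, c(n, N - n), seed = sample.int(1e6, 1))
    phenotypeStats(m)["P1", "rho"]
  })
  se <- stats::sd(rho) / sqrt(length(rho))
  expect_lt(abs(mean(rho) - (n - 1) / (N - 1)), 3 * se)
})
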
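test_that("the same seed gives identical sequences, different seeds not", {
  spec <- chainSpec(5000, 99, multipliers = c(CG = 0.3))
  a <- as.character(simulateGenome(spec))
  b <- as.character(simulateGenome(spec))
  expect_identical(a, b)
  c2 <- as.character(simulateGenome(chainSpec(5000, 100,
                                              multipliers = c(CG = 0.3))))
  expect_false(identical(a, c2))
})

test_that("simulateGenome leaves the caller's RNG state untouched", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulateGenome(chainSpec(1000, 5)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("the uniform chain has all dinucleotide expectations 1/16", {
  ex <- analyticDinucleotideExpectation(chainSpec(1000, 1))
  expect_equal(unname(ex$dinucleotide), rep(1 / 16, 16))
  expect_equal(unname(ex$mononucleotide), rep(1 / 4, 4))
  expect_equal(ex$cpgOE, 1)
})

test_that("multiplied cells hit multiplier * p_a * p_b exactly and the
           stationary marginals stay at the base probabilities", {
  spec <- chainSpec(1000, 1, multipliers = c(CG = 0.5))
  ex <- analyticDinucleotideExpectation(spec)
  expect_equal(unname(ex$dinucleotide[["CG"]]), 0.5 * 0.25 * 0.25)
  expect_equal(unname(ex$mononucleotide), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(ex$cpgOE, 0.5)
  ## the dinucleotide table is the stationary pair measure of the chain:
  ## entry CG equals stationary(C) * P(C -> G)
  P <- transitionMatrix(spec)
  expect_equal(unname(ex$dinucleotide[["CG"]]),
               unname(ex$mononucleotide[["C"]] * P["C", "G"]))
})

test_that("non-uniform bases with a multiplier remain marginal-exact", {
  spec <- chainSpec(1000, 1, baseProbs = c(A = .3, C = .2, G = .2, T = .3),
                    multipliers = c(CG = 0.2, TA = 1.5))
  ex <- analyticDinucleotideExpectation(spec)
  expect_equal(unname(ex$mononucleotide),
               c(.3, .2, .2, .3), tolerance = 1e-8)
  expect_equal(unname(ex$dinucleotide[["CG"]]), 0.2 * .2 * .2)
  expect_equal(unname(ex$dinucleotide[["TA"]]), 1.5 * .3 * .3)
})

test_that("empirical dinucleotide frequencies match the closed form
           within five standard errors", {
  spec <- chainSpec(500000, 41, multipliers = c(CG = 0.2))
  truth <- analyticDinucleotideExpectation(spec)$dinucleotide
  tb <- countKmers(simulateGenome(spec), 2)
  f <- kmerFreqs(tb)[names(truth)]
  n <- kmerWindows(tb)
  ## conservative multinomial-style bound, inflated for chain correlation
  se <- sqrt(truth * (1 - truth) / n) * 2
  expect_true(all(abs(f - truth) < 5 * se))
})

test_that("the asymptotic o/e standard error predicts replicate spread", {
  specs <- lapply(1:20, function(s)
    chainSpec(30000, 500 + s, multipliers = c(CG = 0.2)))
  oes <- vapply(specs, function(sp) cpgOE(simulateGenome(sp)), numeric(1))
  sd0 <- cpgOEAsymptoticSD(specs[[1]])
  expect_equal(mean(oes), 0.2, tolerance = 4 * sd0 / sqrt(20) + 0.003)
  ## the predicted sd is the right order of magnitude
  expect_gt(sd(oes), sd0 / 2.5)
  expect_lt(sd(oes), sd0 * 2.5)
})

test_that("invalid specs are rejected", {
  expect_error(chainSpec(0, 1), "length")
  expect_error(chainSpec(10, 1, multipliers = c(CG = -1)), "positive")
  expect_error(chainSpec(10, 1, multipliers = c(CGT = 2)),
               "dinucleotides")
  expect_error(chainSpec(10, 1, baseProbs = c(A = 1, C = 0, G = 0, T = 0)),
               "positive")
  expect_error(analyticDinucleotideExpectation(
    chainSpec(10, 1, motifs = list(list(motif = "ACGT", prob = .1)))),
    "motif")
  expect_error(chainSpec(1000, 1, multipliers = c(CG = 5)) |>
                 transitionMatrix(), "infeasible")
})

test_that("motif planting overwrites at the expected rate", {
  spec <- chainSpec(100000, 77,
                    motifs = list(list(motif = "TTAACCGG", prob = 0.01)))
  x <- unname(as.character(simulateGenome(spec)))
  nHits <- length(gregexpr("TTAACCGG", x, fixed = TRUE)[[1]])
  ## ~1000 planted (minus overlaps) plus ~1.5 background expected
  expect_gt(nHits, 700)
  expect_lt(nHits, 1300)
  expect_identical(nchar(x), 100000L)
})
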
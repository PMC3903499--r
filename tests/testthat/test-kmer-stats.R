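test_that("sliding-window counting matches direct enumeration", {
  tb <- countKmers("ACGT", 2)
  expect_equal(unname(kmerCounts(tb)[c("AC", "CG", "GT")]), c(1, 1, 1))
  expect_equal(sum(kmerCounts(tb)), 3)
  expect_equal(unname(kmerFreqs(tb)[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  ## windows never span records
  tb2 <- countKmers(c("AC", "GT"), 2)
  expect_equal(unname(kmerCounts(tb2)[c("AC", "GT", "CG")]), c(1, 1, 0))
})

test_that("ambiguity policies: skip drops N-windows, error raises", {
  tb <- countKmers("ACGNACG", 3)
  expect_equal(unname(kmerCounts(tb)["ACG"]), 2)
  expect_equal(kmerWindows(tb), 2)
  expect_error(countKmers("ACGNACG", 3, ambiguity = "error"), "non-ACGT")
})

test_that("strand policy both adds reverse-complement windows", {
  tb <- countKmers("AAAC", 2, strand = "both")
  ## forward: AA AA AC; reverse complement GTTT: GT TT TT
  expect_equal(unname(kmerCounts(tb)[c("AA", "AC", "GT", "TT")]),
               c(2, 1, 1, 2))
})

test_that("degenerate input raises the no-countable-windows error", {
  expect_error(countKmers(c("AC", "GT"), 5), "no countable windows")
})

test_that("uniform i.i.d. dinucleotide frequencies sit near 1/16", {
  spec <- chainSpec(100000, 31)
  tb <- countKmers(simulateGenome(spec), 2)
  se <- sqrt((1 / 16) * (15 / 16) / kmerWindows(tb))
  expect_true(all(abs(kmerFreqs(tb) - 1 / 16) < 5 * se))
})

test_that("zeroth-order background is the product measure", {
  bg <- zerothOrderBackground(c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(unname(kmerFreqs(kmerTable(bg, 3))), rep(4^-3, 64))
  bg2 <- zerothOrderBackground(c(A = .4, C = .1, G = .1, T = .4))
  expect_equal(unname(kmerFreqs(kmerTable(bg2, 2))["AT"]), 0.16)
  ## self-estimated p at k = 1 reproduces the mononucleotide frequencies
  mono <- countKmers("AACGTTTG", 1)
  bg3 <- zerothOrderBackground(kmerFreqs(mono))
  expect_equal(kmerFreqs(kmerTable(bg3, 1)), kmerFreqs(mono))
  expect_error(zerothOrderBackground(c(A = .5, C = .5, G = .5, T = .5)),
               "sum to 1")
})

test_that("markov order 0 collapses to the zeroth-order model", {
  x <- "ACGGTTACGATCGGATT"
  m0 <- markovBackground(x, 0)
  expect_identical(backgroundKind(m0), "zeroth_markov")
  expect_equal(kmerFreqs(kmerTable(m0, 3)),
               kmerFreqs(kmerTable(zerothOrderBackground(
                 kmerFreqs(countKmers(x, 1))), 3)))
})

test_that("markov expectations normalize and recover a known chain", {
  x <- simulateGenome(chainSpec(200000, 13, multipliers = c(CG = 0.25)))
  m1 <- markovBackground(x, 1)
  g <- kmerFreqs(kmerTable(m1, 4))
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_error(kmerTable(m1, 1), "must exceed")
  ## the order-1 model must reproduce the generating chain's dinucleotide
  ## expectations within sampling noise
  truth <- analyticDinucleotideExpectation(
    chainSpec(200000, 13, multipliers = c(CG = 0.25)))$dinucleotide
  g2 <- kmerFreqs(kmerTable(m1, 2))
  expect_equal(unname(g2[names(truth)]), unname(truth), tolerance = 0.02)
})

test_that("log-odds: zero field, 1-bit doubling, antisymmetry", {
  tb <- countKmers("ACGTAGGTCCAT", 2)
  expect_true(all(logOddsValues(logOdds(tb, tb)) == 0))
  expect_error(logOdds(tb, countKmers("ACGT", 3)), "differ")
  ## antisymmetry on two real tables with no zero cells
  x <- simulateGenome(chainSpec(20000, 3))
  y <- simulateGenome(chainSpec(20000, 4, multipliers = c(CG = 0.5)))
  ab <- logOddsValues(crossGenomeField(x, y, 2))
  ba <- logOddsValues(crossGenomeField(y, x, 2))
  expect_equal(ab, -ba, tolerance = 1e-9)
  expect_true(ab[["CG"]] > 0)  # x has no CpG depletion, y does
})

test_that("a doubled frequency is exactly one bit", {
  nm <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2)
  g <- rep(1 / 16, 16) |> stats::setNames(nm)
  f <- g
  f[["CG"]] <- 2 / 16
  f <- f / sum(f)
  obs <- new("KmerTable", k = 2L, counts = g * 0, freqs = f, nWindows = 160)
  bgt <- new("KmerTable", k = 2L, counts = g * 0, freqs = g, nWindows = 0)
  v <- logOddsValues(logOdds(obs, bgt))
  expect_equal(unname(v[["CG"]]), log2(f[["CG"]] / g[["CG"]]))
  expect_equal(unname(v[["CG"]]), 1, tolerance = 0.1)
})

test_that("cpg o/e: exact window enumeration and i.i.d. neutrality", {
  ## CGCGCG: dinucleotide windows CG GC CG GC CG; mononucleotides 3 C, 3 G
  expect_equal(cpgOE(strrep("CG", 3)), (3 / 5) / (0.5 * 0.5))
  x <- simulateGenome(chainSpec(200000, 17))
  expect_equal(cpgOE(x), 1, tolerance = 0.05)
})
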
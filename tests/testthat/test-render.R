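zeroField <- function(k) {
  nm <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  new("LogOddsField", k = as.integer(k),
      values = stats::setNames(numeric(4^k), nm))
}

test_that("color scale: neutral zero, clamping, symmetry, monotonicity", {
  sc <- makeColorScale(2)
  expect_identical(scaleColor(sc, 0), "#F7F7F7")
  expect_identical(scaleColor(sc, 2), scaleColor(sc, 5))
  expect_identical(scaleColor(sc, -2), scaleColor(sc, -99))
  ## symmetric values sit at mirrored interpolation positions
  mid <- c(247, 247, 247)
  for (x in c(0.5, 1, 1.7)) {
    up <- t(grDevices::col2rgb(scaleColor(sc, x)))
    dn <- t(grDevices::col2rgb(scaleColor(sc, -x)))
    expect_equal(abs(up - mid) / abs(c(178, 24, 43) - mid),
                 abs(dn - mid) / abs(c(33, 102, 172) - mid),
                 tolerance = 0.05, ignore_attr = TRUE)
  }
  ## per-channel monotonicity on the positive half-range
  reds <- t(grDevices::col2rgb(scaleColor(sc, seq(0, 2, by = 0.1))))
  expect_true(all(diff(reds[, "green"]) <= 0))
  expect_true(all(diff(reds[, "blue"]) <= 0))
  expect_error(makeColorScale(0), "positive")
  expect_error(makeColorScale(2, "sepia"), "unknown gradient")
})

test_that("the document has one cell polygon per k-mer and the right
           label count", {
  svg <- renderDevelopment(zeroField(3), labelDepth = 2)
  expect_identical(sum(grepl('class="cell"', svg, fixed = TRUE)), 64L)
  expect_identical(sum(grepl('class="prefix-label"', svg, fixed = TRUE)),
                   16L)
  expect_identical(sum(grepl('class="flap"', svg, fixed = TRUE)), 3L)
  ## zero field: all cells share the neutral color
  cells <- grep('class="cell"', svg, value = TRUE, fixed = TRUE)
  expect_true(all(grepl('fill="#F7F7F7"', cells, fixed = TRUE)))
  ## no flaps / no labels variants
  svg2 <- renderDevelopment(zeroField(2), labelDepth = 0, flaps = FALSE)
  expect_identical(sum(grepl('class="flap"', svg2, fixed = TRUE)), 0L)
  expect_identical(sum(grepl('class="prefix-label"', svg2, fixed = TRUE)),
                   0L)
  expect_error(renderDevelopment(zeroField(2), labelDepth = 3),
               "must not exceed")
})

test_that("polygon coordinates agree with the code geometry", {
  k <- 2
  svg <- renderDevelopment(zeroField(k), labelDepth = 0, flaps = FALSE)
  cells <- grep('class="cell"', svg, value = TRUE, fixed = TRUE)
  code <- tetraGrayCode(k)
  V <- codeVertices(code)
  ## device mapping used by the renderer
  S <- 1024; margin <- 0.08 * S; triH <- S * sqrt(3) / 2
  got <- lapply(cells, function(ln) {
    pts <- sub('.*points="([^"]*)".*', "\\1", ln)
    matrix(as.numeric(unlist(strsplit(unlist(strsplit(pts, " ")), ","))),
           ncol = 2, byrow = TRUE)
  })
  ## render order is address order; invert the device transform
  for (i in seq_len(4^k)) {
    want <- matrix(V[i, ], 3, 2, byrow = TRUE)
    dev <- got[[i]]
    back <- cbind((dev[, 1] - margin) / S,
                  (margin + triH - dev[, 2]) / S)
    expect_equal(back, want, tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("rendering is deterministic: identical inputs, identical bytes", {
  x <- simulateGenome(chainSpec(20000, 55, multipliers = c(CG = 0.4)))
  field <- logOdds(countKmers(x, 4), markovBackground(x, 0))
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  renderDevelopment(field, file = f1)
  renderDevelopment(field, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
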
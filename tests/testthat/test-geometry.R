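test_that("digit maps are quarter-area contractions tiling the base", {
  for (d in 0:3) {
    m <- affineForDigit(d)
    expect_equal(abs(det(affineLinear(m))), 0.25)
  }
  ## the four images tile the base triangle: total area equals the base
  ## area and sampled interior points fall in exactly one image
  baseArea <- sqrt(3) / 4
  areas <- vapply(0:3, function(d)
    abs(det(affineLinear(affineForDigit(d)))) * baseArea, numeric(1))
  expect_equal(sum(areas), baseArea)
  inTriangle <- function(p, verts, tol = 0) {
    s <- function(a, b) (p[1] - b[1]) * (a[2] - b[2]) -
                        (a[1] - b[1]) * (p[2] - b[2])
    d1 <- s(verts[1, ], verts[2, ]); d2 <- s(verts[2, ], verts[3, ])
    d3 <- s(verts[3, ], verts[1, ])
    all(c(d1, d2, d3) > tol) || all(c(d1, d2, d3) < -tol)
  }
  images <- lapply(0:3, function(d)
    applyAffine(affineForDigit(d), rbind(c(0, 0), c(1, 0),
                                         c(0.5, sqrt(3) / 2))))
  set.seed(5)
  for (rep in 1:200) {
    ## random strictly interior point of the base triangle
    w <- -log(runif(3)); w <- w / sum(w)
    p <- colSums(w * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
    hits <- sum(vapply(images, function(v)
      inTriangle(p, v, tol = 1e-12), logical(1)))
    expect_lte(hits, 1)
  }
})

test_that("the central map fixes the centroid", {
  centroid <- c(0.5, sqrt(3) / 6)
  expect_equal(applyAffine(affineForDigit(0), centroid), centroid,
               tolerance = 1e-12)
})

test_that("address transforms compose left to right", {
  t21 <- addressToTransform("21")
  t2 <- addressToTransform("2")
  t1 <- addressToTransform("1")
  p <- c(0.3, 0.2)
  expect_equal(applyAffine(t21, p), applyAffine(t2, applyAffine(t1, p)),
               tolerance = 1e-12)
  ## all-zero address shrinks area by 4^-k
  for (k in 1:4) {
    tr <- addressToTransform(strrep("0", k))
    expect_equal(abs(det(affineLinear(tr))), 4^-k)
  }
  expect_error(addressToTransform(""), "non-empty")
})

test_that("cells have edge 2^-k and the expected orientation", {
  cell <- addressToCell("2")
  v <- cellVertices(cell)
  expect_equal(sqrt(sum((v[1, ] - v[2, ])^2)), 0.5)
  expect_identical(cellOrientation(addressToCell("0")), "down")
  expect_identical(cellOrientation(addressToCell("3")), "up")
  expect_identical(cellOrientation(addressToCell("00")), "up")
  ## orientation parity follows the sign of the composed linear part
  for (a in c("012", "030", "123", "0000")) {
    s <- sign(affineLinear(addressToTransform(a))[1, 1])
    expect_identical(cellOrientation(addressToCell(a)),
                     if (s > 0) "up" else "down")
  }
})

test_that("cells at one depth are pairwise interior-disjoint and tile", {
  k <- 3
  code <- tetraGrayCode(k)
  V <- codeVertices(code)
  cx <- rowMeans(V[, c(1, 3, 5)])
  cy <- rowMeans(V[, c(2, 4, 6)])
  ## distinct centroids ensure distinct cells; equal areas summing to the
  ## base area then force pairwise interior-disjointness of the tiling
  expect_equal(anyDuplicated(paste(round(cx * 2^(k + 4)),
                                   round(cy * 2^(k + 4)))), 0L)
  areas <- abs((V[, 3] - V[, 1]) * (V[, 6] - V[, 2]) -
               (V[, 5] - V[, 1]) * (V[, 4] - V[, 2])) / 2
  expect_equal(areas, rep(sqrt(3) / 4 / 4^k, 4^k), tolerance = 1e-12)
  expect_equal(sum(areas), sqrt(3) / 4, tolerance = 1e-12)
})

test_that("bulk code geometry agrees with per-address construction", {
  code <- tetraGrayCode(2)
  V <- codeVertices(code)
  for (i in seq_along(cellAddresses(code))) {
    cell <- addressToCell(cellAddresses(code)[i])
    got <- matrix(V[i, ], 3, 2, byrow = TRUE)
    ## same vertex set (row order may differ)
    want <- cellVertices(cell)
    perm <- vapply(1:3, function(r)
      which(colSums(abs(t(want) - got[r, ])) < 1e-9)[1], integer(1))
    expect_false(any(is.na(perm)))
    expect_identical(cellOrientations(code)[i], cellOrientation(cell))
  }
})

test_that("digit outside 0..3 is a domain error", {
  expect_error(affineForDigit(4), "0..3")
  expect_error(affineForDigit(-1), "0..3")
})
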
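## Affine geometry of the development: the base triangle, the four digit
## maps, address transforms and cell construction.

## Base triangle: unit edge, counter-clockwise.
TRIANGLE_A <- c(0, 0)
TRIANGLE_B <- c(1, 0)
TRIANGLE_C <- c(0.5, sqrt(3) / 2)
BASE_TRIANGLE <- rbind(TRIANGLE_A, TRIANGLE_B, TRIANGLE_C)

## maximum construction depth: 4^10 cells is the desk-scale ceiling
MAX_DEPTH <- 10L

.checkDepth <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k))
    stop("k must be a single integer")
  k <- as.integer(k)
  if (k < 1L || k > MAX_DEPTH)
    stop("k must be between 1 and ", MAX_DEPTH)
  k
}

## The four digit maps. Digit 0 is the half-turn about the centroid scaled
## by 1/2 (the central, inverted sub-triangle); digits 1..3 scale by 1/2
## toward vertices A, B, C. All linear parts are +/- I/2, so any composed
## linear part is a scalar +/- 2^-k times the identity.
.digitMaps <- local({
  cen <- colMeans(BASE_TRIANGLE)
  list(
    list(linear = -diag(2) / 2, offset = 1.5 * cen),
    list(linear = diag(2) / 2, offset = TRIANGLE_A / 2),
    list(linear = diag(2) / 2, offset = TRIANGLE_B / 2),
    list(linear = diag(2) / 2, offset = TRIANGLE_C / 2))
})

#' Affine map of one address digit
#'
#' Digit 0 carries the base triangle onto its central inverted sub-triangle
#' (point symmetry about the centroid composed with scale 1/2); digits 1, 2
#' and 3 are half-scale contractions toward vertices A = (0,0), B = (1,0)
#' and C = (1/2, sqrt(3)/2). The four images tile the base triangle and each
#' linear part has |det| = 1/4.
#'
#' @param digit integer in 0..3.
#' @return An [AffineMap-class] object.
#' @examples
#' abs(det(affineLinear(affineForDigit(0)))) # 0.25
#' @export
affineForDigit <- function(digit) {
  if (length(digit) != 1L || is.na(digit) || !digit %in% 0:3)
    stop("digit must be a single integer in 0..3")
  m <- .digitMaps[[digit + 1L]]
  new("AffineMap", linear = m$linear, offset = m$offset)
}

#' @describeIn affineForDigit linear part of an AffineMap.
#' @param map an AffineMap.
#' @export
affineLinear <- function(map) map@linear

#' @describeIn affineForDigit offset of an AffineMap.
#' @export
affineOffset <- function(map) map@offset

#' Apply an affine map to points
#'
#' @param map an [AffineMap-class].
#' @param points numeric length-2 vector or n x 2 matrix.
#' @return Transformed points, same shape as the input.
#' @export
applyAffine <- function(map, points) {
  if (is.matrix(points))
    t(map@linear %*% t(points) + map@offset)
  else
    as.vector(map@linear %*% points + map@offset)
}

#' Composed transform of an address
#'
#' Left-to-right composition of the digit maps: the first (leftmost) digit
#' is the coarsest subdivision. The identity corresponds to the empty
#' prefix; an empty address is an error.
#'
#' @param address quaternary address string.
#' @return An [AffineMap-class] carrying the base triangle onto the cell of
#'   the address.
#' @export
addressToTransform <- function(address) {
  digs <- .addressDigits(address)
  L <- diag(2)
  t0 <- c(0, 0)
  for (d in digs) {
    m <- .digitMaps[[d + 1L]]
    t0 <- as.vector(L %*% m$offset) + t0
    L <- L %*% m$linear
  }
  new("AffineMap", linear = L, offset = t0)
}

## orientation from the actual vertex geometry: "up" if the apex (the
## vertex with unique y among the three) lies above the horizontal edge
.triangleOrientation <- function(verts, tol = 1e-9) {
  y <- verts[, 2L]
  if (abs(y[1L] - y[2L]) < tol) {
    if (y[3L] > y[1L]) "up" else "down"
  } else if (abs(y[1L] - y[3L]) < tol) {
    if (y[2L] > y[1L]) "up" else "down"
  } else {
    if (y[1L] > y[2L]) "up" else "down"
  }
}

#' Geometry of one cell
#'
#' Applies the composed transform of the address to the base triangle. The
#' orientation is read from the sign structure of the composed linear part
#' as realized in the image vertices, not from a digit-parity formula.
#'
#' @param address quaternary address string.
#' @return A [CellGeometry-class] object.
#' @examples
#' cellOrientation(addressToCell("0")) # "down"
#' @export
addressToCell <- function(address) {
  tr <- addressToTransform(address)
  verts <- applyAffine(tr, BASE_TRIANGLE)
  ## keep the vertex list counter-clockwise
  e1 <- verts[2L, ] - verts[1L, ]
  e2 <- verts[3L, ] - verts[1L, ]
  if (e1[1L] * e2[2L] - e1[2L] * e2[1L] < 0)
    verts <- verts[c(1L, 3L, 2L), ]
  new("CellGeometry", vertices = verts,
      orientation = .triangleOrientation(verts), address = address)
}

#' @describeIn addressToCell vertices of a CellGeometry (3x2 matrix).
#' @param cell a CellGeometry.
#' @export
cellVertices <- function(cell) cell@vertices

#' @describeIn addressToCell orientation ("up"/"down") of a CellGeometry.
#' @export
cellOrientation <- function(cell) cell@orientation

## ---- bulk construction ----

## Because every digit linear part is +/- I/2, the composed transform of an
## address is x -> s x + t with s = (-1)^(#zeros) / 2^k.  This lets the full
## code be built vectorised: one scalar and one offset per address.
.bulkTransforms <- function(k) {
  s <- 1
  t0 <- matrix(0, 1L, 2L)
  for (depth in seq_len(k)) {
    ns <- numeric(length(s) * 4L)
    nt <- matrix(0, length(s) * 4L, 2L)
    for (d in 0:3) {
      m <- .digitMaps[[d + 1L]]
      rows <- seq_along(s) * 4L - (3L - d)
      sgn <- if (d == 0L) -0.5 else 0.5
      ns[rows] <- s * sgn
      nt[rows, ] <- t0 + cbind(s * m$offset[1L], s * m$offset[2L])
    }
    s <- ns
    t0 <- nt
  }
  list(scale = s, offset = t0)
}

#' Construct the full tetrahedral Gray code at depth k
#'
#' Builds all 4^k addresses, their k-mers and the geometry of their cells on
#' the development of the tetrahedron.
#'
#' @param k code depth (k-mer length), 1..10.
#' @return A [TetraGrayCode-class] object.
#' @examples
#' code <- tetraGrayCode(2)
#' head(cellKmers(code))
#' @export
tetraGrayCode <- function(k) {
  k <- .checkDepth(k)
  digs <- .allDigits(k)
  addrs <- .digitsToAddress(digs)
  kmers <- apply(.digitsToLetters(digs), 1L, paste, collapse = "")
  tr <- .bulkTransforms(k)
  n <- 4^k
  verts <- matrix(0, n, 6L)
  for (v in 1:3) {
    verts[, 2L * v - 1L] <- tr$scale * BASE_TRIANGLE[v, 1L] + tr$offset[, 1L]
    verts[, 2L * v] <- tr$scale * BASE_TRIANGLE[v, 2L] + tr$offset[, 2L]
  }
  colnames(verts) <- c("v0x", "v0y", "v1x", "v1y", "v2x", "v2y")
  orientation <- ifelse(tr$scale > 0, "up", "down")
  new("TetraGrayCode", k = k, addresses = addrs, kmers = kmers,
      vertices = verts, orientation = orientation)
}

#' @describeIn tetraGrayCode code depth.
#' @param code a TetraGrayCode.
#' @export
codeDepth <- function(code) code@k

#' @describeIn tetraGrayCode all addresses, base-4 ascending.
#' @export
cellAddresses <- function(code) code@addresses

#' @describeIn tetraGrayCode k-mers in address order.
#' @export
cellKmers <- function(code) code@kmers

#' @describeIn tetraGrayCode cell vertex matrix (4^k x 6).
#' @export
codeVertices <- function(code) code@vertices

#' @describeIn tetraGrayCode per-cell orientation.
#' @export
cellOrientations <- function(code) code@orientation
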
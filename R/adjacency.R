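## Adjacency of the folded code: interior shared edges plus the
## half-turn identification of boundary half-sides.

## Integer lattice keys for cell vertices at depth k: all x coordinates are
## multiples of 2^-(k+1) and all y coordinates multiples of sqrt(3)/2^(k+2),
## so scaled rounding is exact well beyond the 1e-9 tolerance regime.
.vertexKeys <- function(x, y, k) {
  s <- 2^(k + 1)
  ix <- round(x * s)
  iy <- round(y * s * 2 / sqrt(3))
  list(ix = ix, iy = iy, code = ix * (s + 2) + iy)
}

#' Build the adjacency graph of the folded tetrahedral Gray code
#'
#' Two cells are adjacent when they share a full triangle edge within the
#' development, or when their edges lie on the development boundary and are
#' identified by the folding rule: each half of a base-triangle side is
#' glued to the other half of the same side by a half-turn (180 degree
#' point symmetry) about that side's midpoint. The result is the face
#' adjacency of the closed tetrahedron surface: 3-regular with 3*4^k/2
#' edges.
#'
#' @param k code depth, 1..10.
#' @return A [TGCAdjacency-class] object.
#' @examples
#' adj <- buildAdjacency(1)
#' nrow(adjacencyEdges(adj)) # 6: the four faces form a K4
#' @export
buildAdjacency <- function(k) {
  k <- .checkDepth(k)
  code <- tetraGrayCode(k)
  V <- code@vertices
  n <- nrow(V)
  s <- 2^(k + 1)

  ## three edges per cell, as canonical (sorted endpoint-code) numeric keys
  kv <- lapply(1:3, function(v)
    .vertexKeys(V[, 2L * v - 1L], V[, 2L * v], k))
  pairIdx <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  M <- (s + 2)^2
  edgeKey <- numeric(3L * n)
  edgeCell <- rep(seq_len(n), times = 3L)
  epIx <- matrix(0, 3L * n, 2L)  # endpoint ix for boundary handling
  epIy <- matrix(0, 3L * n, 2L)
  for (e in 1:3) {
    a <- kv[[pairIdx[e, 1L]]]
    b <- kv[[pairIdx[e, 2L]]]
    lo <- pmin(a$code, b$code)
    hi <- pmax(a$code, b$code)
    rows <- ((e - 1L) * n + 1L):(e * n)
    edgeKey[rows] <- lo * M + hi
    epIx[rows, ] <- cbind(a$ix, b$ix)
    epIy[rows, ] <- cbind(a$iy, b$iy)
  }

  ord <- order(edgeKey)
  sk <- edgeKey[ord]
  same <- sk[-length(sk)] == sk[-1L]
  i1 <- ord[c(same, FALSE)]
  i2 <- ord[c(FALSE, same)]
  edges <- cbind(edgeCell[i1], edgeCell[i2])

  ## boundary edges: keys occurring exactly once
  singleton <- !(c(same, FALSE) | c(FALSE, same))
  bIdx <- ord[singleton]
  bx <- epIx[bIdx, , drop = FALSE]
  by <- epIy[bIdx, , drop = FALSE]
  onAB <- by[, 1L] == 0L & by[, 2L] == 0L
  onCA <- 2L * bx[, 1L] == by[, 1L] & 2L * bx[, 2L] == by[, 2L]
  onBC <- 2L * bx[, 1L] == 2L * s - by[, 1L] & 2L * bx[, 2L] == 2L * s - by[, 2L]

  imgIx <- bx
  imgIy <- by
  imgIx[onAB, ] <- s - bx[onAB, ]
  imgIx[onCA, ] <- s / 2 - bx[onCA, ]
  imgIy[onCA, ] <- s - by[onCA, ]
  imgIx[onBC, ] <- 3 * s / 2 - bx[onBC, ]
  imgIy[onBC, ] <- s - by[onBC, ]

  bcode <- function(ix, iy) ix * (s + 2) + iy
  keyOf <- function(ix, iy) {
    c1 <- bcode(ix[, 1L], iy[, 1L])
    c2 <- bcode(ix[, 2L], iy[, 2L])
    pmin(c1, c2) * M + pmax(c1, c2)
  }
  bKeys <- keyOf(bx, by)
  imgKeys <- keyOf(imgIx, imgIy)
  partner <- match(imgKeys, bKeys)
  if (any(is.na(partner)))
    stop("internal error: boundary identification is not an involution")
  keep <- seq_along(partner) < partner
  foldEdges <- cbind(edgeCell[bIdx[keep]], edgeCell[bIdx[partner[keep]]])

  edges <- rbind(edges, foldEdges)
  storage.mode(edges) <- "integer"
  new("TGCAdjacency", k = k, addresses = code@addresses, edges = edges)
}

#' Edge list of a TGCAdjacency as address pairs
#'
#' @param adj a [TGCAdjacency-class].
#' @return Character matrix with two columns of addresses, one row per
#'   unordered adjacency edge.
#' @export
adjacencyEdges <- function(adj) {
  cbind(address1 = adj@addresses[adj@edges[, 1L]],
        address2 = adj@addresses[adj@edges[, 2L]])
}

#' Cell degrees of a TGCAdjacency
#'
#' @param adj a [TGCAdjacency-class].
#' @return Named integer vector of degrees per address.
#' @export
adjacencyDegrees <- function(adj) {
  deg <- tabulate(c(adj@edges[, 1L], adj@edges[, 2L]),
                  nbins = length(adj@addresses))
  names(deg) <- adj@addresses
  deg
}

#' Neighbors of one cell
#'
#' @param adj a [TGCAdjacency-class].
#' @param address a quaternary address present in the graph.
#' @return Character vector of the neighboring addresses.
#' @export
cellNeighbors <- function(adj, address) {
  i <- match(address, adj@addresses)
  if (is.na(i)) stop("address not in graph: ", address)
  e <- adj@edges
  nb <- c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L])
  adj@addresses[sort(nb)]
}
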
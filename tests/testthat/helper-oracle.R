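# Independent brute-force adjacency oracle: O(n^2) pairwise segment
# sharing plus an explicit midpoint-reflection scan of the boundary.
# Implemented on raw floating-point coordinates with a 1e-9 tolerance,
# deliberately sharing no code with buildAdjacency().

oracleAdjacency <- function(k, tol = 1e-9) {
  code <- tetraGrayCode(k)
  V <- codeVertices(code)
  n <- nrow(V)
  verts <- lapply(seq_len(n), function(i)
    matrix(V[i, ], 3L, 2L, byrow = TRUE))

  sameP <- function(p, q) max(abs(p - q)) < tol
  edgesOf <- function(vm) list(vm[c(1, 2), ], vm[c(2, 3), ], vm[c(3, 1), ])
  sameSeg <- function(e1, e2) {
    (sameP(e1[1, ], e2[1, ]) && sameP(e1[2, ], e2[2, ])) ||
      (sameP(e1[1, ], e2[2, ]) && sameP(e1[2, ], e2[1, ]))
  }

  edges <- list()
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    shared <- 0L
    for (i in 1:3) for (j in 1:3)
      if (sameP(verts[[a]][i, ], verts[[b]][j, ])) shared <- shared + 1L
    if (shared == 2L) edges[[length(edges) + 1L]] <- c(a, b)
  }

  ## boundary identification: half turn about each side midpoint
  A <- c(0, 0); B <- c(1, 0); C <- c(0.5, sqrt(3) / 2)
  sides <- list(list(mid = (A + B) / 2,
                     on = function(p) abs(p[2]) < tol),
                list(mid = (B + C) / 2,
                     on = function(p) abs(p[1] - (1 - p[2] / sqrt(3))) < tol),
                list(mid = (C + A) / 2,
                     on = function(p) abs(p[1] - p[2] / sqrt(3)) < tol))
  boundaryEdges <- list()
  for (a in seq_len(n)) for (e in edgesOf(verts[[a]])) {
    for (s in seq_along(sides)) {
      if (sides[[s]]$on(e[1, ]) && sides[[s]]$on(e[2, ]))
        boundaryEdges[[length(boundaryEdges) + 1L]] <-
          list(cell = a, e = e, side = s)
    }
  }
  for (i in seq_along(boundaryEdges)) {
    bi <- boundaryEdges[[i]]
    m <- sides[[bi$side]]$mid
    img <- rbind(2 * m - bi$e[1, ], 2 * m - bi$e[2, ])
    for (j in seq_along(boundaryEdges)) {
      if (j <= i) next
      bj <- boundaryEdges[[j]]
      if (bj$side == bi$side && sameSeg(img, bj$e))
        edges[[length(edges) + 1L]] <- sort(c(bi$cell, bj$cell))
    }
  }
  mat <- do.call(rbind, edges)
  mat[order(mat[, 1L], mat[, 2L]), , drop = FALSE]
}

canonicalEdges <- function(edges) {
  e <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  unname(e)
}

randomChar <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}
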
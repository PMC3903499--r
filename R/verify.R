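## Exhaustive verification of the defining properties of the code.

#' Verify the Gray-code properties at depth k
#'
#' Enumerates all adjacent cell pairs of the folded code (interior and
#' across the development boundary) and reports: bijectivity of the
#' address-to-k-mer map, the range of Hamming distances over adjacent
#' pairs (the Gray property holds when both are 1), 3-regularity,
#' connectivity, and -- optionally -- the hierarchical property that every
#' proper prefix class is graph-connected and geometrically contained in
#' its prefix cell.
#'
#' Failures are reported in the returned object, not raised as errors.
#'
#' @param k code depth; exhaustive checking is supported up to 6.
#' @param checkHierarchy logical; also verify prefix connectivity and
#'   containment (default TRUE).
#' @return A [GrayCodeReport-class] object.
#' @examples
#' verifyGrayCode(3)
#' @export
verifyGrayCode <- function(k, checkHierarchy = TRUE) {
  k <- .checkDepth(k)
  if (k > 6L)
    stop("exhaustive verification is capped at k = 6")
  digs <- .allDigits(k)
  letters <- .digitsToLetters(digs)
  kmers <- apply(letters, 1L, paste, collapse = "")
  n <- 4^k

  adj <- buildAdjacency(k)
  e <- adj@edges
  hd <- rowSums(letters[e[, 1L], , drop = FALSE] !=
                letters[e[, 2L], , drop = FALSE])
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  connected <- igraph::components(g)$no == 1L

  hierarchyOK <- NA
  if (checkHierarchy && k > 1L) {
    hierarchyOK <- TRUE
    code <- tetraGrayCode(k)
    V <- code@vertices
    for (j in seq_len(k - 1L)) {
      pid <- (seq_len(n) - 1L) %/% 4L^(k - j)  # index of the length-j prefix
      ## connectivity: with only within-prefix edges, every prefix class is
      ## connected iff the component count equals the number of classes
      within <- pid[e[, 1L]] == pid[e[, 2L]]
      gj <- igraph::graph_from_edgelist(e[within, , drop = FALSE],
                                        directed = FALSE)
      gj <- igraph::add_vertices(gj, max(0L, n - igraph::vcount(gj)))
      if (igraph::components(gj)$no != 4L^j) hierarchyOK <- FALSE
      ## containment: every cell vertex inside its prefix triangle
      trj <- .bulkTransforms(j)
      sP <- trj$scale[pid + 1L]
      tP <- trj$offset[pid + 1L, , drop = FALSE]
      for (v in 1:3) {
        lx <- (V[, 2L * v - 1L] - tP[, 1L]) / sP
        ly <- (V[, 2L * v] - tP[, 2L]) / sP
        ## barycentric-style half-plane tests for the base triangle
        tol <- 1e-9
        inside <- ly >= -tol &
          (sqrt(3) * lx - ly) >= -tol &
          (sqrt(3) * (1 - lx) - ly) >= -tol
        if (!all(inside)) hierarchyOK <- FALSE
      }
    }
  }

  new("GrayCodeReport",
      k = k,
      nDistinctKmers = length(unique(kmers)),
      bijective = !anyDuplicated(kmers),
      hammingRange = as.integer(range(hd)),
      degreeRange = as.integer(range(deg)),
      nEdges = nrow(e),
      connected = connected,
      hierarchyOK = as.logical(hierarchyOK))
}
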
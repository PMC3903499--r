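## show() methods.

setMethod("show", "AffineMap", function(object) {
  cat("AffineMap\n  linear:\n")
  print(unname(object@linear))
  cat("  offset:", format(object@offset, digits = 6), "\n")
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf("CellGeometry for address \"%s\" (%s)\n", object@address,
              object@orientation))
  print(unname(round(object@vertices, 6)))
})

setMethod("show", "TetraGrayCode", function(object) {
  n <- 4^object@k
  cat(sprintf("TetraGrayCode of depth k = %d: %d cells\n", object@k, n))
  m <- min(4L, n)
  cat(sprintf("  %s -> %s\n", object@addresses[seq_len(m)],
              object@kmers[seq_len(m)]), sep = "")
  if (n > m) cat("  ...\n")
})

setMethod("show", "TGCAdjacency", function(object) {
  cat(sprintf("TGCAdjacency at k = %d: %d cells, %d edges\n", object@k,
              length(object@addresses), nrow(object@edges)))
})

setMethod("show", "GrayCodeReport", function(object) {
  cat(sprintf("Gray-code report at k = %d\n", object@k))
  cat(sprintf("  bijective:          %s (%d / %d distinct k-mers)\n",
              object@bijective, object@nDistinctKmers, 4^object@k))
  cat(sprintf("  Hamming distance:   %d .. %d over %d adjacent pairs\n",
              object@hammingRange[1L], object@hammingRange[2L],
              object@nEdges))
  cat(sprintf("  degree:             %d .. %d\n", object@degreeRange[1L],
              object@degreeRange[2L]))
  cat(sprintf("  connected:          %s\n", object@connected))
  cat(sprintf("  prefix hierarchy:   %s\n", object@hierarchyOK))
})

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable k = %d (%d k-mers, %g windows)\n", object@k,
              4^object@k, object@nWindows))
  print(utils::head(object@freqs, 8L))
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel kind = %s", object@kind))
  if (object@kind == "markov_m") cat(sprintf(" (order %d)", object@order))
  cat("\n")
})

setMethod("show", "LogOddsField", function(object) {
  cat(sprintf("LogOddsField k = %d, range [%.3f, %.3f] bits\n", object@k,
              min(object@values), max(object@values)))
})

setMethod("show", "CpGContextMatrix", function(object) {
  cat(sprintf("CpGContextMatrix: flank %d, %d CG sites\n", object@flank,
              object@nSites))
  half <- object@flank
  cons <- object@consensus
  cat("  consensus:", paste(c(cons[seq_len(half)], "[CG]",
                              cons[half + seq_len(half)]), collapse = " "),
      "\n")
})

setMethod("show", "ColorScale", function(object) {
  cat(sprintf("ColorScale \"%s\", clamp +/- %g\n", object@gradient,
              object@clamp))
})

setMethod("show", "ChainSpec", function(object) {
  cat(sprintf("ChainSpec: length %d, seed %d\n", object@length,
              object@seed))
  if (length(object@multipliers))
    cat("  multipliers:", paste(names(object@multipliers),
                                object@multipliers, sep = "=",
                                collapse = ", "), "\n")
  for (m in object@motifs)
    cat(sprintf("  motif %s at p = %g\n", m$motif, m$prob))
})
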
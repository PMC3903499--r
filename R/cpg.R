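## CpG statistics: observed/expected ratio and the positional log-odds
## matrix around CpG occurrences.

#' CpG observed/expected ratio
#'
#' f(CG) / (f(C) * f(G)), with dinucleotide and mononucleotide frequencies
#' taken from sliding-window counts ([countKmers()]). Values below 1
#' indicate CpG depletion (the typical methylation signature); values above
#' 1 indicate overrepresentation.
#'
#' @param x sequences (as in [countKmers()]).
#' @param ... passed to [countKmers()].
#' @return The o/e ratio as a single numeric value.
#' @examples
#' cpgOE(strrep("CG", 3)) # 2.4: windows CG,GC,CG,GC,CG
#' @export
cpgOE <- function(x, ...) {
  di <- kmerFreqs(countKmers(x, 2L, ...))
  mo <- kmerFreqs(countKmers(x, 1L, ...))
  denom <- mo[["C"]] * mo[["G"]]
  if (denom == 0)
    stop("undefined o/e ratio: f(C) * f(G) is zero")
  unname(di[["CG"]] / denom)
}

#' Positional log-odds matrix around CpG
#'
#' For every CG occurrence, tallies the nucleotides at offsets -F..-1
#' (before the C) and +1..+F (after the G), converts the tallies to
#' per-position conditional frequencies, and reports their log2 ratio
#' against the background's expected nucleotide distribution, together
#' with the consensus (argmax) nucleotide per position.
#'
#' Positions falling outside a sequence record, or holding a non-ACGT
#' symbol, are dropped from that position's denominator.
#'
#' @param x sequences (as in [countKmers()]).
#' @param flank number of flanking positions F on each side, >= 1.
#' @param background a [BackgroundModel-class] supplying the expected
#'   nucleotide distribution per position (its mononucleotide marginal);
#'   default NULL builds a zeroth-order model from the sequences
#'   themselves.
#' @return A [CpGContextMatrix-class].
#' @export
cpgContextMatrix <- function(x, flank = 5L, background = NULL) {
  if (length(flank) != 1L || is.na(flank) || flank < 1L ||
      flank != as.integer(flank))
    stop("flank must be a single integer >= 1")
  flank <- as.integer(flank)
  seqs <- .asDNAStringSet(x)
  if (is.null(background))
    background <- zerothOrderBackground(kmerFreqs(countKmers(seqs, 1L)))
  if (!is(background, "BackgroundModel"))
    stop("background must be a BackgroundModel or NULL")
  expected <- backgroundMonoProbs(background)[NUCS]

  offsets <- c(-rev(seq_len(flank)), seq_len(flank))
  rowNames <- ifelse(offsets < 0, as.character(offsets),
                     paste0("+", offsets))
  tallies <- matrix(0, length(offsets), 4L,
                    dimnames = list(rowNames, NUCS))
  nSites <- 0L
  hits <- Biostrings::vmatchPattern("CG", seqs)
  for (i in seq_along(seqs)) {
    starts <- BiocGenerics::start(hits[[i]])
    if (!length(starts)) next
    nSites <- nSites + length(starts)
    chars <- strsplit(as.character(seqs[[i]]), "", fixed = TRUE)[[1L]]
    len <- length(chars)
    for (r in seq_along(offsets)) {
      off <- offsets[r]
      ## the C sits at the match start, the G at start + 1
      pos <- if (off < 0) starts + off else starts + 1L + off
      pos <- pos[pos >= 1L & pos <= len]
      if (!length(pos)) next
      tb <- table(factor(chars[pos], levels = NUCS))
      tallies[r, ] <- tallies[r, ] + as.numeric(tb)
    }
  }
  if (nSites == 0L)
    stop("undefined context matrix: no CG occurrences found")

  rs <- rowSums(tallies)
  condFreq <- tallies / ifelse(rs == 0, 1, rs)
  ## floor the observed conditionals with half a pseudo-occurrence so the
  ## log is finite; the model expectation is only guarded against exact 0
  floorAt <- 1 / (2 * max(rs, 1))
  lo <- log2(pmax(condFreq, floorAt) /
             matrix(pmax(expected, 1e-12), nrow(condFreq), 4L,
                    byrow = TRUE))
  consensus <- NUCS[apply(condFreq, 1L, which.max)]
  names(consensus) <- rowNames
  new("CpGContextMatrix", flank = flank, logOdds = lo, condFreq = condFreq,
      expected = expected, consensus = consensus, nSites = nSites)
}

#' @describeIn cpgContextMatrix positional log2-odds matrix.
#' @param m a CpGContextMatrix.
#' @export
contextLogOdds <- function(m) m@logOdds

#' @describeIn cpgContextMatrix positional conditional frequencies.
#' @export
contextFreqs <- function(m) m@condFreq

#' @describeIn cpgContextMatrix consensus nucleotide per position.
#' @export
contextConsensus <- function(m) m@consensus

#' @describeIn cpgContextMatrix number of CG occurrences tallied.
#' @export
contextSites <- function(m) m@nSites
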
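## k-mer counting over sequence sets.

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("sequences must be a DNAStringSet, DNAString or character vector")
}

.allKmerNames <- function(k) {
  Biostrings::mkAllStrings(NUCS, k)
}

#' Count k-mers with a sliding window
#'
#' Slides a width-k window with step 1 within each sequence record; windows
#' never span records. Under the default ambiguity policy, windows that
#' contain any non-ACGT character are skipped and the frequency denominator
#' is the number of retained windows.
#'
#' @param x sequences: a `DNAStringSet`, `DNAString` or character vector.
#' @param k word length, >= 1.
#' @param strand "given" (default) counts the given strand only; "both"
#'   additionally counts every window of the reverse complement.
#' @param ambiguity "skip" (default) drops windows containing non-ACGT
#'   symbols; "error" raises an error when any such symbol is present.
#' @return A [KmerTable-class] with counts and relative frequencies over
#'   all 4^k k-mers.
#' @examples
#' kmerFreqs(countKmers("ACGT", 2))[c("AC", "CG", "GT")] # each 1/3
#' @export
countKmers <- function(x, k, strand = c("given", "both"),
                       ambiguity = c("skip", "error")) {
  strand <- match.arg(strand)
  ambiguity <- match.arg(ambiguity)
  if (length(k) != 1L || is.na(k) || k < 1L || k != as.integer(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  seqs <- .asDNAStringSet(x)
  if (length(seqs) == 0L) stop("empty sequence set")
  if (ambiguity == "error") {
    af <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
    nonACGT <- sum(af) - sum(af[NUCS])
    if (nonACGT > 0)
      stop("sequences contain ", nonACGT,
           " non-ACGT characters (ambiguity = \"error\")")
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k,
                                                         step = 1L))
  if (strand == "both") {
    rc <- Biostrings::reverseComplement(seqs)
    counts <- counts +
      colSums(Biostrings::oligonucleotideFrequency(rc, width = k, step = 1L))
  }
  total <- sum(counts)
  if (total == 0)
    stop("no countable windows: every sequence is shorter than k = ", k,
         " or fully ambiguous")
  freqs <- counts / total
  new("KmerTable", k = k, counts = as.numeric(counts) |>
        stats::setNames(names(counts)),
      freqs = as.numeric(freqs) |> stats::setNames(names(counts)),
      nWindows = total)
}

#' @describeIn countKmers word length of a KmerTable.
#' @param table a KmerTable.
#' @export
kmerLength <- function(table) table@k

#' @describeIn countKmers named counts of a KmerTable.
#' @export
kmerCounts <- function(table) table@counts

#' @describeIn countKmers named relative frequencies of a KmerTable.
#' @export
kmerFreqs <- function(table) table@freqs

#' @describeIn countKmers number of retained windows of a KmerTable.
#' @export
kmerWindows <- function(table) table@nWindows
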
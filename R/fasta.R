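## FASTA ingestion.

#' Read DNA sequences from a FASTA file
#'
#' Reads plain or gzip-compressed FASTA, uppercases the sequences and maps
#' U to T so RNA input flows through the DNA machinery. Records are
#' returned in file order.
#'
#' @param path path to a FASTA or FASTA.gz file.
#' @return A `DNAStringSet` named by the FASTA headers.
#' @export
readFastaDNA <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## light structural check so malformed input fails with a line number:
  ## any sequence content before the first header is an error
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lineNo <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) break
    lineNo <- lineNo + 1L
    if (!nzchar(trimws(ln)) || startsWith(ln, ";")) next
    if (!startsWith(ln, ">"))
      stop("malformed FASTA: sequence before header at line ", lineNo,
           " of ", path)
    break
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  chr <- chartr("uU", "tT", as.character(x))
  out <- Biostrings::DNAStringSet(toupper(chr))
  names(out) <- names(x)
  out
}
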
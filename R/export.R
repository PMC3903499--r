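## Tabular export of the code and of analysis results.

#' Export the code table as TSV
#'
#' Columns: address, kmer, v0x, v0y, v1x, v1y, v2x, v2y, orientation.
#'
#' @param code a [TetraGrayCode-class].
#' @param path output file.
#' @export
exportCodeTable <- function(code, path) {
  df <- data.frame(address = code@addresses, kmer = code@kmers,
                   code@vertices, orientation = code@orientation,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the adjacency edge list as TSV
#'
#' @param adj a [TGCAdjacency-class].
#' @param path output file.
#' @export
exportAdjacency <- function(adj, path) {
  utils::write.table(as.data.frame(adjacencyEdges(adj)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a KmerTable as TSV
#'
#' @param table a [KmerTable-class].
#' @param path output file.
#' @export
exportKmerTable <- function(table, path) {
  df <- data.frame(kmer = names(table@counts), count = table@counts,
                   freq = table@freqs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a LogOddsField as TSV
#'
#' @param field a [LogOddsField-class].
#' @param path output file.
#' @export
exportLogOddsField <- function(field, path) {
  df <- data.frame(kmer = names(field@values), log2_odds = field@values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a CpGContextMatrix as TSV
#'
#' One row per flanking position (signed, relative to the CG at 0), with
#' both the log-odds and the raw conditional frequencies so alternative
#' normalizations can be recomputed.
#'
#' @param m a [CpGContextMatrix-class].
#' @param path output file.
#' @export
exportCpGContext <- function(m, path) {
  lo <- m@logOdds
  cf <- m@condFreq
  colnames(lo) <- paste0("log2_", colnames(lo))
  colnames(cf) <- paste0("freq_", colnames(cf))
  df <- data.frame(position = rownames(m@condFreq), lo, cf,
                   consensus = m@consensus, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
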
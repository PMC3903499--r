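## Address <-> k-mer transformation through the relation matrix.

NUCS <- c("A", "C", "G", "T")

## first bases: digits (0,1,2,3) -> (A,T,C,G)
FIRST_BASE <- c("A", "T", "C", "G")

## Klein four-group encoding of digits: w(0)=(1,1), w(1)=(0,0), w(2)=(1,0),
## w(3)=(0,1).  The nucleotide stamped after moving from digit p to digit d
## is Lambda(w(p) xor w(d)) with Lambda(00,10,01,11) = (A,G,C,T).  The
## resulting 4x4 table is the relation matrix; its rows are labelled by the
## first base of the previous digit so that rows T and C read
## (T,A,G,C) and (C,G,A,T).
.kleinW <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L), c(0L, 1L))
.kleinLambda <- matrix(c("A", "G", "C", "T"), 2L, 2L) # [i1+1, i2+1]

.makeRelation <- function() {
  R <- matrix("", 4L, 4L, dimnames = list(FIRST_BASE, as.character(0:3)))
  for (p in 0:3) for (d in 0:3) {
    cls <- (.kleinW[p + 1L, ] + .kleinW[d + 1L, ]) %% 2L
    R[p + 1L, d + 1L] <- .kleinLambda[cls[1L] + 1L, cls[2L] + 1L]
  }
  R
}

RELATION <- .makeRelation()

#' The relation matrix of the tetrahedral Gray code
#'
#' Returns the 4x4 nucleotide table that drives the address-to-sequence
#' transformation. Rows are labelled by the first base assigned to the
#' previous address digit (digits 0..3 carry first bases A, T, C, G),
#' columns by the current digit. Every row is a permutation of A, C, G, T.
#' The i-th nucleotide of a k-mer is the row-(first base of digit i-1),
#' column-(digit i) entry, with a virtual leading digit 0, so the first
#' nucleotide is read from row A: (0,1,2,3) -> (A,T,C,G).
#'
#' @return A 4x4 character matrix with rownames A, T, C, G and colnames
#'   "0".."3".
#' @examples
#' relationMatrix()["T", ] # T A G C: addresses 10..13 -> TT TA TG TC
#' @export
relationMatrix <- function() RELATION

## ---- address utilities ----

.checkAddress <- function(address) {
  if (length(address) != 1L || is.na(address) || !nzchar(address))
    stop("address must be a single non-empty string of digits 0-3")
  if (!grepl("^[0-3]+$", address))
    stop("address must consist of digits 0-3 only: ", address)
  invisible(address)
}

.addressDigits <- function(address) {
  .checkAddress(address)
  as.integer(strsplit(address, "", fixed = TRUE)[[1L]])
}

## all length-k addresses in base-4 ascending order, as an n x k digit matrix
.allDigits <- function(k) {
  n <- 4^k
  digs <- matrix(0L, n, k)
  idx <- 0:(n - 1)
  for (pos in k:1) {
    digs[, pos] <- idx %% 4L
    idx <- idx %/% 4L
  }
  digs
}

.digitsToAddress <- function(digs) {
  apply(digs, 1L, paste, collapse = "")
}

## vectorised kmer letters for an n x k digit matrix
.digitsToLetters <- function(digs) {
  n <- nrow(digs)
  k <- ncol(digs)
  letters <- matrix("", n, k)
  prev <- rep(0L, n)
  for (pos in seq_len(k)) {
    letters[, pos] <- RELATION[cbind(prev + 1L, digs[, pos] + 1L)]
    prev <- digs[, pos]
  }
  letters
}

#' Convert an address to its k-mer
#'
#' Walks the relation matrix along the address: the first nucleotide is the
#' first base of the first digit, and each subsequent nucleotide is the
#' relation-matrix entry for (previous digit, current digit).
#'
#' @param address quaternary address string, e.g. "21".
#' @return The k-mer as a character string of the same length.
#' @examples
#' addressToKmer("21") # "CG"
#' vapply(c("10", "11", "12", "13"), addressToKmer, "") # TT TA TG TC
#' @seealso [kmerToAddress()] for the inverse.
#' @export
addressToKmer <- function(address) {
  digs <- .addressDigits(address)
  out <- character(length(digs))
  prev <- 0L
  for (i in seq_along(digs)) {
    out[i] <- RELATION[prev + 1L, digs[i] + 1L]
    prev <- digs[i]
  }
  paste(out, collapse = "")
}

#' Convert a k-mer to its address
#'
#' Exact inverse of [addressToKmer()]: each relation-matrix row is a
#' permutation of the four nucleotides, so the digit at every position is
#' recovered uniquely.
#'
#' @param kmer nucleotide string over A, C, G, T.
#' @return The quaternary address string.
#' @examples
#' kmerToAddress("CG") # "21"
#' @export
kmerToAddress <- function(kmer) {
  if (length(kmer) != 1L || is.na(kmer) || !nzchar(kmer))
    stop("kmer must be a single non-empty string")
  chars <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% NUCS)
  if (length(bad))
    stop("non-ACGT character '", chars[bad[1L]], "' at position ", bad[1L])
  digs <- integer(length(chars))
  prev <- 0L
  for (i in seq_along(chars)) {
    d <- match(chars[i], RELATION[prev + 1L, ]) - 1L
    digs[i] <- d
    prev <- d
  }
  paste(digs, collapse = "")
}

## all 4^k kmers in address order (used by the code constructor)
.allKmers <- function(k) {
  spl <- .digitsToLetters(.allDigits(k))
  apply(spl, 1L, paste, collapse = "")
}
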
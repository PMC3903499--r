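## Background models: expected k-mer frequencies against which observed
## composition is contrasted.

#' Zeroth-order Markov background
#'
#' Expected k-mer frequency as the product of independent mononucleotide
#' probabilities: g(w) = prod_i p(w_i).
#'
#' @param probs named nucleotide probabilities over A, C, G, T (must sum
#'   to 1), or a [KmerTable-class] of k = 1 from which they are taken.
#' @return A [BackgroundModel-class] of kind "zeroth_markov". Use
#'   [kmerTable()] to materialize its expected k-mer table at any k.
#' @examples
#' bg <- zerothOrderBackground(c(A = .4, C = .1, G = .1, T = .4))
#' kmerFreqs(kmerTable(bg, 2))["AT"] # 0.16
#' @export
zerothOrderBackground <- function(probs) {
  if (is(probs, "KmerTable")) {
    if (probs@k != 1L) stop("a KmerTable of k = 1 is required")
    probs <- kmerFreqs(probs)
  }
  if (is.null(names(probs)) ||
      !identical(sort(names(probs)), c("A", "C", "G", "T")))
    stop("probs must be named A, C, G, T")
  probs <- probs[NUCS]
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be non-negative and sum to 1")
  new("BackgroundModel", kind = "zeroth_markov", order = 0L, probs = probs,
      init = numeric(0), cond = matrix(numeric(0), 0, 0), reference = NULL)
}

#' Order-m Markov background estimated from sequences
#'
#' Estimates an order-m Markov model from the sequences: (m+1)-mer
#' frequencies supply the initial distribution and the per-context
#' conditional next-nucleotide probabilities. The expected frequency of a
#' k-mer (k > m) is the chain probability of emitting it. m = 0 reduces
#' exactly to the zeroth-order model built from the mononucleotide
#' frequencies of the sequences.
#'
#' @param x sequences (as in [countKmers()]).
#' @param m Markov order, >= 0.
#' @param ... passed to [countKmers()] (strand/ambiguity policies).
#' @return A [BackgroundModel-class] of kind "zeroth_markov" (m = 0) or
#'   "markov_m".
#' @export
markovBackground <- function(x, m, ...) {
  if (length(m) != 1L || is.na(m) || m < 0L || m != as.integer(m))
    stop("m must be a single integer >= 0")
  m <- as.integer(m)
  if (m == 0L)
    return(zerothOrderBackground(kmerFreqs(countKmers(x, 1L, ...))))
  counts <- kmerCounts(countKmers(x, m + 1L, ...))
  init <- counts / sum(counts)
  ## conditional table: contexts (first m letters) x next nucleotide
  ctx <- substr(names(counts), 1L, m)
  nxt <- substr(names(counts), m + 1L, m + 1L)
  cond <- matrix(counts, nrow = 4L^m, ncol = 4L, byrow = TRUE,
                 dimnames = list(unique(ctx), NUCS))
  ## (names(counts) is alphabetical, so contexts vary slowest)
  rs <- rowSums(cond)
  zero <- rs == 0
  cond <- cond / ifelse(rs == 0, 1, rs)
  cond[zero, ] <- 0.25  # unseen context: uniform
  new("BackgroundModel", kind = "markov_m", order = m, probs = numeric(0),
      init = init, cond = cond, reference = NULL)
}

#' Empirical background from a reference sequence set
#'
#' Uses the k-mer frequencies of another sequence set (for example another
#' genome) as the background, for comparative analyses.
#'
#' @param x reference sequences or a ready [KmerTable-class].
#' @param k word length to tabulate when sequences are given.
#' @param ... passed to [countKmers()].
#' @return A [BackgroundModel-class] of kind "empirical".
#' @export
empiricalBackground <- function(x, k = NULL, ...) {
  tab <- if (is(x, "KmerTable")) x else {
    if (is.null(k)) stop("k is required when sequences are given")
    countKmers(x, k, ...)
  }
  new("BackgroundModel", kind = "empirical", order = NA_integer_,
      probs = numeric(0), init = numeric(0),
      cond = matrix(numeric(0), 0, 0), reference = tab)
}

#' Expected k-mer table of a background model
#'
#' @param model a [BackgroundModel-class].
#' @param k word length; for Markov models k must exceed the order.
#' @return A [KmerTable-class] of expected frequencies (counts all zero).
#' @export
kmerTable <- function(model, k) {
  if (!is(model, "BackgroundModel")) stop("model must be a BackgroundModel")
  if (length(k) != 1L || is.na(k) || k < 1L || k != as.integer(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  nm <- .allKmerNames(k)
  g <- switch(model@kind,
    zeroth_markov = {
      digs <- .allDigits(k)  # base-4 == alphabetical over A,C,G,T
      lg <- log(model@probs)
      exp(rowSums(matrix(lg[digs + 1L], nrow = nrow(digs))))
    },
    markov_m = {
      m <- model@order
      if (k <= m) stop("k must exceed the Markov order m = ", m)
      digs <- .allDigits(k)
      n <- nrow(digs)
      ## context codes: rolling base-4 code of m consecutive digits
      lg <- log(model@init[.contextCode(digs[, seq_len(m + 1L),
                                             drop = FALSE]) + 1L])
      if (k > m + 1L) {
        lcond <- log(model@cond)
        for (i in seq.int(m + 2L, k)) {
          ctx <- .contextCode(digs[, (i - m):(i - 1L), drop = FALSE])
          lg <- lg + lcond[cbind(ctx + 1L, digs[, i] + 1L)]
        }
      }
      exp(lg)
    },
    empirical = {
      ref <- model@reference
      if (ref@k != k)
        stop("empirical background was tabulated at k = ", ref@k,
             ", not k = ", k)
      kmerFreqs(ref)
    })
  names(g) <- nm
  ## guard against drift; Markov expectations telescope to 1 analytically
  g <- g / sum(g)
  new("KmerTable", k = k, counts = stats::setNames(numeric(length(g)), nm),
      freqs = g, nWindows = 0)
}

## base-4 integer code of digit blocks (rows)
.contextCode <- function(digs) {
  code <- numeric(nrow(digs))
  for (j in seq_len(ncol(digs))) code <- code * 4 + digs[, j]
  code
}

#' @describeIn kmerTable kind of a BackgroundModel.
#' @export
backgroundKind <- function(model) model@kind

#' @describeIn kmerTable mononucleotide marginal of a BackgroundModel
#'   (stationary distribution for Markov kinds; first-position marginal for
#'   empirical kinds).
#' @export
backgroundMonoProbs <- function(model) {
  switch(model@kind,
    zeroth_markov = model@probs,
    markov_m = {
      ## stationary distribution of the embedded first-order chain on
      ## m-mer contexts, marginalized to the last nucleotide
      m <- model@order
      stat <- .statFromInit(model)
      stat
    },
    empirical = {
      ref <- model@reference
      f <- kmerFreqs(ref)
      if (ref@k == 1L) return(f)
      first <- substr(names(f), 1L, 1L)
      vapply(NUCS, function(nt) sum(f[first == nt]), numeric(1))
    })
}

.statFromInit <- function(model) {
  ## mononucleotide marginal implied by the (m+1)-mer frequencies
  f <- model@init
  first <- substr(names(f), 1L, 1L)
  p <- vapply(NUCS, function(nt) sum(f[first == nt]), numeric(1))
  p / sum(p)
}
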
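## Log-odds fields: observed vs background k-mer frequencies.

#' Log-odds ratio field
#'
#' r(w) = log2(f(w) / g(w)) for every k-mer w, where f is the observed and
#' g the background frequency. With the default "floor" smoothing both
#' frequencies are floored at 1/(2 * total retained windows) before the
#' ratio, so the field is finite everywhere and exactly zero wherever
#' f(w) = g(w).
#'
#' @param observed a [KmerTable-class] of observed frequencies.
#' @param background a [KmerTable-class] or [BackgroundModel-class] of the
#'   same k.
#' @param smoothing "floor" (default) or "none" (zero frequencies then
#'   yield infinite values and are rejected).
#' @return A [LogOddsField-class].
#' @examples
#' tb <- countKmers(c("ACGTACGGT"), 2)
#' field <- logOdds(tb, zerothOrderBackground(kmerFreqs(countKmers(
#'   c("ACGTACGGT"), 1))))
#' @export
logOdds <- function(observed, background, smoothing = c("floor", "none")) {
  smoothing <- match.arg(smoothing)
  if (!is(observed, "KmerTable")) stop("observed must be a KmerTable")
  if (is(background, "BackgroundModel"))
    background <- kmerTable(background, observed@k)
  if (!is(background, "KmerTable"))
    stop("background must be a KmerTable or BackgroundModel")
  if (background@k != observed@k)
    stop("observed (k = ", observed@k, ") and background (k = ",
         background@k, ") word lengths differ")
  f <- kmerFreqs(observed)
  g <- kmerFreqs(background)
  if (smoothing == "floor") {
    nw <- observed@nWindows
    if (nw <= 0) nw <- max(1, background@nWindows)
    eps <- 1 / (2 * nw)
    f <- pmax(f, eps)
    g <- pmax(g, eps)
  } else if (any(f == 0) || any(g == 0)) {
    stop("zero frequencies present; use smoothing = \"floor\"")
  }
  vals <- log2(f / g)
  vals[kmerFreqs(observed) == kmerFreqs(background)] <- 0
  new("LogOddsField", k = observed@k, values = vals)
}

#' Cross-genome log-odds field
#'
#' Contrasts the k-mer composition of a target sequence set against the
#' empirical k-mer frequencies of a reference set, for comparative
#' genomics.
#'
#' @param target target sequences (as in [countKmers()]).
#' @param reference reference sequences.
#' @param k word length.
#' @param ... passed to [countKmers()] for both sets.
#' @return A [LogOddsField-class].
#' @export
crossGenomeField <- function(target, reference, k, ...) {
  logOdds(countKmers(target, k, ...), countKmers(reference, k, ...))
}

#' @describeIn logOdds named log-odds values of a field.
#' @param field a LogOddsField.
#' @export
logOddsValues <- function(field) field@values

#' @describeIn logOdds word length of a field.
#' @export
logOddsK <- function(field) field@k
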
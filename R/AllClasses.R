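## S4 class definitions for the tetrahedral Gray code machinery.

#' AffineMap: a planar affine transformation
#'
#' A 2x2 linear part plus a translation, used for the four digit maps that
#' carry the base triangle onto its four half-scale sub-triangles and for
#' their compositions along an address.
#'
#' @slot linear numeric 2x2 matrix.
#' @slot offset numeric length-2 translation.
#' @exportClass AffineMap
setClass("AffineMap",
  representation(linear = "matrix", offset = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@linear), c(2L, 2L)))
      return("'linear' must be a 2x2 matrix")
    if (length(object@offset) != 2L)
      return("'offset' must have length 2")
    if (!is.numeric(object@linear) || !is.numeric(object@offset))
      return("'linear' and 'offset' must be numeric")
    TRUE
  })

#' CellGeometry: one triangular cell of the development
#'
#' @slot vertices numeric 3x2 matrix of triangle vertices, counter-clockwise.
#' @slot orientation "up" (same pointing as the base triangle) or "down"
#'   (inverted).
#' @slot address the quaternary address string of the cell.
#' @exportClass CellGeometry
setClass("CellGeometry",
  representation(vertices = "matrix", orientation = "character",
                 address = "character"),
  validity = function(object) {
    if (!identical(dim(object@vertices), c(3L, 2L)))
      return("'vertices' must be a 3x2 matrix")
    if (!object@orientation %in% c("up", "down"))
      return("'orientation' must be \"up\" or \"down\"")
    TRUE
  })

#' TetraGrayCode: the complete code at depth k
#'
#' Holds, for every length-k quaternary address, its k-mer and the geometry
#' of its triangular cell on the development (net) of the tetrahedron.
#' Cells are stored in address order (base-4 ascending).
#'
#' @slot k code depth (k-mer length).
#' @slot addresses character vector of the 4^k quaternary addresses.
#' @slot kmers character vector of the corresponding k-mers (a bijection).
#' @slot vertices numeric 4^k x 6 matrix, columns v0x, v0y, v1x, v1y, v2x,
#'   v2y, in units where the base triangle has unit edge.
#' @slot orientation character vector, "up" or "down" per cell.
#' @exportClass TetraGrayCode
setClass("TetraGrayCode",
  representation(k = "integer", addresses = "character", kmers = "character",
                 vertices = "matrix", orientation = "character"),
  validity = function(object) {
    n <- 4^object@k
    if (length(object@addresses) != n) return("wrong number of addresses")
    if (length(object@kmers) != n) return("wrong number of k-mers")
    if (anyDuplicated(object@kmers)) return("k-mers are not a bijection")
    if (nrow(object@vertices) != n || ncol(object@vertices) != 6L)
      return("'vertices' must be a 4^k x 6 matrix")
    if (length(object@orientation) != n) return("wrong orientation length")
    TRUE
  })

#' TGCAdjacency: adjacency structure of the folded code
#'
#' Edge list over the 4^k cells: cells sharing a full triangle edge within
#' the development, plus cells glued together across the development
#' boundary when the net is folded into a tetrahedron.
#'
#' @slot k code depth.
#' @slot addresses character vector of the 4^k addresses (address order).
#' @slot edges integer m x 2 matrix of indices into \code{addresses}.
#' @exportClass TGCAdjacency
setClass("TGCAdjacency",
  representation(k = "integer", addresses = "character", edges = "matrix"),
  validity = function(object) {
    if (length(object@addresses) != 4^object@k)
      return("wrong number of addresses")
    if (ncol(object@edges) != 2L) return("'edges' must have two columns")
    if (nrow(object@edges) > 0 &&
        (min(object@edges) < 1 || max(object@edges) > 4^object@k))
      return("edge indices out of range")
    TRUE
  })

#' GrayCodeReport: property report of verifyGrayCode
#'
#' @slot k code depth checked.
#' @slot nDistinctKmers number of distinct k-mers observed (4^k expected).
#' @slot bijective TRUE if all 4^k k-mers are distinct.
#' @slot hammingRange min and max Hamming distance over all adjacent pairs.
#' @slot degreeRange min and max cell degree.
#' @slot nEdges number of adjacency edges.
#' @slot connected TRUE if the adjacency graph is connected.
#' @slot hierarchyOK TRUE if every proper prefix class is geometrically
#'   contained in its prefix cell and graph-connected (NA if not checked).
#' @exportClass GrayCodeReport
setClass("GrayCodeReport",
  representation(k = "integer", nDistinctKmers = "integer",
                 bijective = "logical", hammingRange = "integer",
                 degreeRange = "integer", nEdges = "integer",
                 connected = "logical", hierarchyOK = "logical"))

#' KmerTable: k-mer counts and relative frequencies
#'
#' Keys are always the full set of 4^k k-mers in alphabetical order
#' (zero-filled). For background tables produced from a model, counts are
#' all zero and only \code{freqs} is meaningful.
#'
#' @slot k word length.
#' @slot counts named numeric vector of window counts.
#' @slot freqs named numeric vector of relative frequencies (sums to 1).
#' @slot nWindows total number of retained windows (0 for model tables).
#' @exportClass KmerTable
setClass("KmerTable",
  representation(k = "integer", counts = "numeric", freqs = "numeric",
                 nWindows = "numeric"),
  validity = function(object) {
    n <- 4^object@k
    if (length(object@counts) != n || length(object@freqs) != n)
      return("counts/freqs must cover all 4^k k-mers")
    if (!identical(names(object@counts), names(object@freqs)))
      return("counts and freqs must share names")
    if (any(object@counts < 0)) return("negative counts")
    if (abs(sum(object@freqs) - 1) > 1e-9)
      return("freqs must sum to 1")
    TRUE
  })

#' BackgroundModel: expected k-mer frequencies
#'
#' Three kinds: \code{"zeroth_markov"} (independent nucleotides with
#' probabilities \code{probs}), \code{"markov_m"} (order-m Markov chain
#' estimated from sequences; \code{init} holds (m+1)-mer frequencies and
#' \code{cond} the conditional next-nucleotide table per m-mer context) and
#' \code{"empirical"} (the k-mer table of a reference sequence set).
#'
#' @slot kind one of "zeroth_markov", "markov_m", "empirical".
#' @slot order Markov order m (0 for zeroth, NA for empirical).
#' @slot probs named nucleotide probabilities (zeroth kind).
#' @slot init named (m+1)-mer frequencies (markov_m kind).
#' @slot cond conditional probability matrix, 4^m contexts x 4 nucleotides
#'   (markov_m kind).
#' @slot reference KmerTable of the reference set (empirical kind), or NULL.
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(kind = "character", order = "integer", probs = "numeric",
                 init = "numeric", cond = "matrix", reference = "ANY"),
  validity = function(object) {
    if (!object@kind %in% c("zeroth_markov", "markov_m", "empirical"))
      return("unknown background kind")
    if (object@kind == "zeroth_markov") {
      if (abs(sum(object@probs) - 1) > 1e-8)
        return("nucleotide probabilities must sum to 1")
      if (any(object@probs < 0)) return("negative probabilities")
    }
    if (object@kind == "markov_m" && nrow(object@cond) > 0) {
      if (any(abs(rowSums(object@cond) - 1) > 1e-8))
        return("conditional rows must sum to 1")
    }
    TRUE
  })

#' LogOddsField: per-k-mer log-odds ratios
#'
#' @slot k word length.
#' @slot values named numeric log2 odds ratio per k-mer, finite.
#' @exportClass LogOddsField
setClass("LogOddsField",
  representation(k = "integer", values = "numeric"),
  validity = function(object) {
    if (length(object@values) != 4^object@k)
      return("values must cover all 4^k k-mers")
    if (any(!is.finite(object@values)))
      return("log-odds values must be finite")
    TRUE
  })

#' CpGContextMatrix: positional log-odds around CpG
#'
#' Rows are positions relative to a CG dinucleotide at 0 (the C occupies
#' position 0, the G position +1 of the sequence; flanking offsets are
#' reported as -F..-1 before the C and +1..+F after the G).
#'
#' @slot flank number of positions on each side.
#' @slot logOdds 2F x 4 matrix of log2 ratios of conditional vs expected
#'   nucleotide frequency.
#' @slot condFreq 2F x 4 matrix of conditional nucleotide frequencies
#'   (rows sum to 1).
#' @slot expected named length-4 expected nucleotide distribution used.
#' @slot consensus character vector, the argmax nucleotide per position.
#' @slot nSites number of CG occurrences used.
#' @exportClass CpGContextMatrix
setClass("CpGContextMatrix",
  representation(flank = "integer", logOdds = "matrix", condFreq = "matrix",
                 expected = "numeric", consensus = "character",
                 nSites = "integer"),
  validity = function(object) {
    if (nrow(object@condFreq) != 2L * object@flank)
      return("condFreq must have 2*flank rows")
    rs <- rowSums(object@condFreq)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      return("conditional frequencies must normalize per position")
    TRUE
  })

#' ColorScale: symmetric diverging color mapping for log-odds values
#'
#' @slot clamp half-range c; values are clamped to [-c, c].
#' @slot gradient gradient name.
#' @slot low,mid,high RGB triples (0..255) of the gradient anchors.
#' @exportClass ColorScale
setClass("ColorScale",
  representation(clamp = "numeric", gradient = "character", low = "numeric",
                 mid = "numeric", high = "numeric"),
  validity = function(object) {
    if (object@clamp <= 0) return("'clamp' must be positive")
    TRUE
  })

#' ChainSpec: specification of the synthetic-genome Markov chain
#'
#' First-order chain whose stationary mononucleotide distribution equals
#' \code{baseProbs} and whose dinucleotide frequencies equal
#' \code{multiplier * p_a * p_b} for every multiplied dinucleotide, with
#' optional motifs overwritten at seeded random positions.
#'
#' @slot baseProbs named nucleotide probabilities (A, C, G, T).
#' @slot multipliers named positive multipliers, e.g. c(CG = 0.2).
#' @slot motifs list of list(motif=, prob=) plants.
#' @slot length sequence length.
#' @slot seed integer RNG seed.
#' @exportClass ChainSpec
setClass("ChainSpec",
  representation(baseProbs = "numeric", multipliers = "numeric",
                 motifs = "list", length = "integer", seed = "integer"),
  validity = function(object) {
    if (!identical(sort(names(object@baseProbs)), c("A", "C", "G", "T")))
      return("baseProbs must be named A, C, G, T")
    if (abs(sum(object@baseProbs) - 1) > 1e-8)
      return("baseProbs must sum to 1")
    if (any(object@baseProbs <= 0))
      return("baseProbs must be strictly positive")
    if (length(object@multipliers)) {
      if (any(object@multipliers <= 0))
        return("multipliers must be positive")
      ok <- grepl("^[ACGT]{2}$", names(object@multipliers))
      if (!all(ok)) return("multiplier names must be dinucleotides")
    }
    for (m in object@motifs) {
      if (!is.list(m) || is.null(m$motif) || is.null(m$prob))
        return("each motif must be list(motif=, prob=)")
      if (!grepl("^[ACGT]+$", m$motif)) return("motif must be over ACGT")
      if (m$prob < 0 || m$prob > 1) return("motif prob must be in [0,1]")
    }
    if (object@length < 1) return("length must be >= 1")
    TRUE
  })
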
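## Seeded synthetic-genome simulator: first-order Markov chains with
## controlled dinucleotide biases and planted motifs, plus the closed-form
## oracle for their dinucleotide composition.

#' Specify a synthetic-genome Markov chain
#'
#' The chain is built from a joint dinucleotide distribution q(a,b): for
#' every multiplied dinucleotide, q(a,b) is pinned to
#' multiplier * p(a) * p(b) exactly; the remaining cells are scaled by
#' iterative proportional fitting so that both marginals equal the base
#' probabilities. The transition matrix is the conditional of q, so the
#' stationary mononucleotide distribution is the base distribution and the
#' CpG-style o/e ratio of a multiplied dinucleotide equals its multiplier.
#'
#' @param length sequence length.
#' @param seed integer RNG seed (recorded in the spec; simulation is
#'   deterministic given it).
#' @param baseProbs named nucleotide probabilities (default uniform).
#' @param multipliers named positive multipliers per dinucleotide, e.g.
#'   `c(CG = 0.2)` for five-fold CpG depletion.
#' @param motifs list of `list(motif =, prob =)`: each motif is overwritten
#'   at positions sampled independently with the given per-position
#'   probability (overwriting keeps the sequence length fixed).
#' @return A [ChainSpec-class].
#' @export
chainSpec <- function(length, seed, baseProbs = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                      multipliers = numeric(0), motifs = list()) {
  new("ChainSpec", baseProbs = baseProbs[c("A", "C", "G", "T")],
      multipliers = multipliers, motifs = motifs,
      length = as.integer(length), seed = as.integer(seed))
}

## fixed-cell IPF: joint dinucleotide distribution with pinned multiplied
## cells and base-probability marginals
.dinucJoint <- function(spec) {
  p <- spec@baseProbs
  Q <- outer(p, p)
  fixed <- matrix(FALSE, 4L, 4L, dimnames = dimnames(Q))
  for (nm in names(spec@multipliers)) {
    a <- substr(nm, 1L, 1L)
    b <- substr(nm, 2L, 2L)
    Q[a, b] <- spec@multipliers[[nm]] * p[a] * p[b]
    fixed[a, b] <- TRUE
  }
  rfix <- rowSums(Q * fixed)
  cfix <- colSums(Q * fixed)
  if (any(rfix >= p) || any(cfix >= p))
    stop("infeasible multipliers: pinned mass exceeds a marginal")
  for (it in seq_len(1000L)) {
    free <- Q
    free[fixed] <- 0
    su <- (p - rowSums(Q * fixed)) / rowSums(free)
    Q[!fixed] <- (free * su)[!fixed]
    free <- Q
    free[fixed] <- 0
    sv <- (p - colSums(Q * fixed)) / colSums(free)
    Q[!fixed] <- t(t(free) * sv)[!fixed]
    if (max(abs(rowSums(Q) - p)) < 1e-13 &&
        max(abs(colSums(Q) - p)) < 1e-13) break
  }
  if (max(abs(rowSums(Q) - p)) > 1e-9 || max(abs(colSums(Q) - p)) > 1e-9)
    stop("multiplier fitting did not converge")
  if (any(Q < 0)) stop("infeasible multipliers: negative joint mass")
  Q
}

#' Transition matrix of a chain spec
#'
#' @param spec a [ChainSpec-class].
#' @return 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transitionMatrix <- function(spec) {
  Q <- .dinucJoint(spec)
  Q / rowSums(Q)
}

#' Closed-form dinucleotide expectations of a chain spec
#'
#' The stationary distribution and implied dinucleotide frequencies of the
#' constructed chain, the oracle against which simulated counts are tested.
#' Motif plants are not accounted for (an error is raised if any are
#' present).
#'
#' @param spec a [ChainSpec-class] without motif plants.
#' @return List with `mononucleotide` (stationary distribution),
#'   `dinucleotide` (named 16-vector of expected frequencies) and `cpgOE`
#'   (the implied o/e ratio).
#' @export
analyticDinucleotideExpectation <- function(spec) {
  if (length(spec@motifs))
    stop("the closed form is only available without motif plants")
  P <- transitionMatrix(spec)
  if (any(P <= 0))
    stop("non-ergodic chain: zero transition probabilities")
  ## stationary distribution (equals baseProbs by construction; computed
  ## from P as a consistency guarantee)
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i])
  stat <- stat / sum(stat)
  names(stat) <- NUCS
  Q <- stat * P  # pi_a * P(a,b)
  di <- as.vector(Q)  # column-major matches outer() below: entry (a,b) -> "ab"
  names(di) <- as.vector(outer(NUCS, NUCS, paste0))
  list(mononucleotide = stat, dinucleotide = di,
       cpgOE = unname(Q["C", "G"] / (stat[["C"]] * stat[["G"]])))
}

#' Simulate a genome from a chain spec
#'
#' Draws a first-order Markov sequence of the specified length from the
#' constructed transition matrix (initial state from the stationary
#' distribution), then overwrites each planted motif at positions sampled
#' independently at its per-position probability. Deterministic given the
#' spec's seed; the caller's RNG state is left untouched.
#'
#' @param spec a [ChainSpec-class].
#' @return A `DNAStringSet` with one record.
#' @export
simulateGenome <- function(spec) {
  P <- transitionMatrix(spec)
  L <- spec@length
  oldSeed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec@seed)

  cum <- t(apply(P, 1L, cumsum))
  x <- integer(L)
  x[1L] <- sample.int(4L, 1L, prob = spec@baseProbs)
  if (L > 1L) {
    u <- stats::runif(L)
    for (i in 2:L) {
      r <- cum[x[i - 1L], ]
      x[i] <- 1L + (u[i] > r[1L]) + (u[i] > r[2L]) + (u[i] > r[3L])
    }
  }
  for (m in spec@motifs) {
    letters <- match(strsplit(m$motif, "", fixed = TRUE)[[1L]], NUCS)
    w <- length(letters)
    nPos <- L - w + 1L
    if (nPos < 1L) next
    starts <- which(stats::runif(nPos) < m$prob)
    if (length(starts)) {
      idx <- outer(starts, 0:(w - 1L), "+")
      x[idx] <- rep(letters, each = length(starts))
    }
  }
  out <- Biostrings::DNAStringSet(paste(NUCS[x], collapse = ""))
  names(out) <- sprintf("synthetic_chain_len%d_seed%d", L, spec@seed)
  out
}

#' Asymptotic standard error of the CpG o/e estimator
#'
#' Delta-method standard error of [cpgOE()] applied to a sequence of the
#' spec's length drawn from the spec's chain, using the exact asymptotic
#' covariance of the dinucleotide and mononucleotide frequencies computed
#' from the fundamental matrix of the pair (dinucleotide) chain. This is
#' the Monte-Carlo standard error oracle for recovery tests.
#'
#' @param spec a [ChainSpec-class] without motif plants.
#' @return Standard error (single numeric).
#' @export
cpgOEAsymptoticSD <- function(spec) {
  if (length(spec@motifs))
    stop("only available without motif plants")
  P <- transitionMatrix(spec)
  stat <- analyticDinucleotideExpectation(spec)$mononucleotide
  ## pair chain on 16 states (a,b) -> (b,c) with probability P(b,c)
  states <- expand.grid(b = NUCS, a = NUCS)[, c("a", "b")]
  n16 <- 16L
  P2 <- matrix(0, n16, n16)
  pi2 <- numeric(n16)
  for (i in seq_len(n16)) {
    a <- states$a[i]; b <- states$b[i]
    pi2[i] <- stat[[a]] * P[a, b]
    for (j in seq_len(n16)) {
      if (states$a[j] == b) P2[i, j] <- P[b, states$b[j]]
    }
  }
  Pi2 <- matrix(pi2, n16, n16, byrow = TRUE)
  Z <- solve(diag(n16) - P2 + Pi2)
  ## indicator functionals: f(CG), f(C*) and f(G*) (first-letter marginals)
  u1 <- as.numeric(states$a == "C" & states$b == "G")
  u2 <- as.numeric(states$a == "C")
  u3 <- as.numeric(states$a == "G")
  covf <- function(u, v) {
    uc <- u - sum(pi2 * u)
    vc <- v - sum(pi2 * v)
    sum(pi2 * uc * vc) +
      sum(pi2 * uc * ((Z - diag(n16)) %*% vc)) +
      sum(pi2 * vc * ((Z - diag(n16)) %*% uc))
  }
  S <- matrix(0, 3L, 3L)
  us <- list(u1, u2, u3)
  for (i in 1:3) for (j in 1:3) S[i, j] <- covf(us[[i]], us[[j]])
  fCG <- sum(pi2 * u1)
  fC <- sum(pi2 * u2)
  fG <- sum(pi2 * u3)
  oe <- fCG / (fC * fG)
  grad <- c(1 / (fC * fG), -oe / fC, -oe / fG)
  nWin <- spec@length - 1L
  sqrt(max(0, as.numeric(t(grad) %*% S %*% grad)) / nWin)
}
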
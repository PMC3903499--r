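# tetragray

Genome k-mer composition on the surface of a tetrahedron, with a Gray-code
guarantee.

## The problem

Chaos game representation (CGR) and its relatives place every DNA k-mer in
a recursively subdivided square, but neighboring regions of a CGR can hold
completely unrelated words, so visually contiguous patterns need not mean
anything biologically. `tetragray` implements the **tetrahedral Gray code
(TGC)**: a bijection between all 4^k DNA k-mers and the 4^k triangular
cells that tile the surface of a tetrahedron (drawn flat as its
development, or *net*), constructed so that **any two cells sharing an
edge — including cells glued together when the net is folded — carry
k-mers that differ at exactly one position** (Hamming distance 1). A
contiguous colored region on the figure therefore corresponds to a family
of single-nucleotide-related words, and the sharp boundary of such a
region pinpoints the discriminating nucleotide. Because all k-mers with a
common prefix form a connected triangular block, the layout is also
hierarchical: a depth-8 map can be annotated with its depth-3 prefixes.

## The construction

A cell is named by a quaternary *address* a₁a₂…a_k. Digit maps are affine
contractions of the unit-edge base triangle (A = (0,0), B = (1,0),
C = (1/2, √3/2)): digit 0 is the half-turn about the centroid composed
with scale 1/2 (the central, inverted sub-triangle); digits 1–3 contract
by 1/2 toward A, B, C. The cell of an address is the image of the base
triangle under the left-to-right composition of its digit maps. Folding
glues each half of a side of the net to the other half of the same side by
a half-turn about the side's midpoint.

The k-mer of an address follows a relation matrix **R** on digit pairs:
encode digits into the Klein four-group as w(0,1,2,3) = (11, 00, 10, 01)
and letters as Λ(00, 10, 01, 11) = (A, G, C, T); then nucleotide i is
Λ(w(a₍ᵢ₋₁₎) ⊕ w(aᵢ)) with a virtual leading 0, i.e. the first bases of
digits (0,1,2,3) are (A,T,C,G) and the rows of R indexed by those first
bases read

```
     digit:  0 1 2 3
  row A:     A T C G
  row T:     T A G C
  row C:     C G A T
  row G:     G C T A
```

`verifyGrayCode()` checks the defining properties exhaustively (Hamming
distance over every adjacent pair, 3-regularity, connectivity, prefix
hierarchy) for k up to 6.

On top of the layout the package provides k-mer counting
(`countKmers()`), zeroth/higher-order Markov and cross-genome backgrounds,
log₂-odds fields (`logOdds()`), CpG observed/expected ratios (`cpgOE()`),
positional log-odds matrices around CpG (`cpgContextMatrix()`), an SVG
renderer of the color-coded net with glue flaps (`renderDevelopment()`),
and a seeded Markov-chain genome simulator with controlled dinucleotide
biases and planted motifs (`chainSpec()` / `simulateGenome()`).

## Worked example

```r
library(tetragray)

addressToKmer("21")
#> [1] "CG"

verifyGrayCode(4)
#> Gray-code report at k = 4
#>   bijective:          TRUE (256 / 256 distinct k-mers)
#>   Hamming distance:   1 .. 1 over 384 adjacent pairs
#>   degree:             3 .. 3
#>   connected:          TRUE
#>   prefix hierarchy:   TRUE

## a 1 Mb synthetic genome with five-fold CpG depletion
spec <- chainSpec(1e6, seed = 42, multipliers = c(CG = 0.2))
x <- simulateGenome(spec)
cpgOE(x)
#> [1] 0.2006216

field <- logOdds(countKmers(x, 2), markovBackground(x, 0))
round(logOddsValues(field)[c("CG", "GC", "TA")], 3)
#>     CG     GC     TA
#> -2.317 -0.138 -0.127

## a planted XhoI-style motif shows up as the consensus around CpG
m <- cpgContextMatrix(simulateGenome(chainSpec(1e6, 43,
  motifs = list(list(motif = "CTCGAG", prob = 0.02)))), flank = 2)
m
#> CpGContextMatrix: flank 2, 73246 CG sites
#>   consensus: C T [CG] A G
```

The o/e ratio of 0.2006 recovers the simulated five-fold depletion, the
CG cell of the dinucleotide field sits at −2.32 bits ≈ log₂ 0.2, and the
planted CTCGAG motif is read back letter-for-letter from the flanks of
CpG. A paper-craft octamer map is one call away:

```r
x8 <- logOdds(countKmers(x, 8), markovBackground(x, 0))
renderDevelopment(x8, file = "tgc.svg")  # 65536 cells, 64 prefix labels
```

A command-line wrapper lives in `inst/scripts/tgc`:

```sh
tgc simulate --length 1000000 --seed 42 --mult CG=0.2 --out genome.fa
tgc render --k 8 --in genome.fa --bg markov0 --out tgc.svg
tgc verify --k 5
tgc cpg-oe --in genome.fa
```

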
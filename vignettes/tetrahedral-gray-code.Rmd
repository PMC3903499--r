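---
title: "The tetrahedral Gray code: model, construction and design choices"
author: "tetragray maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tetrahedral Gray code: model, construction and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetragray)
```

# The model

A k-mer map is useful for composition analysis only if spatial proximity
means sequence similarity. `tetragray` lays the 4^k DNA k-mers onto the
4^k triangular cells tiling the surface of a tetrahedron so that every
pair of edge-adjacent cells differs at exactly one sequence position; we
call this arrangement the tetrahedral Gray code (TGC). The surface is
drawn flat as the development (net) of the tetrahedron — one large
triangle of 4^k cells — and the three sides of the net carry an implicit
gluing: each half-side is identified with the other half of the same side
by a half-turn about the side's midpoint, which is exactly how the flat
net folds into the solid. Adjacency in this package always means
adjacency *after* gluing, so the verification treats the figure as the
closed surface it represents (3-regular, 3·4^k/2 edges).

Two structural facts make the layout practical:

* **Hierarchy.** All k-mers sharing a length-j prefix occupy precisely
  the cell of that prefix at depth j and form a connected region. Deep
  maps can therefore be annotated with shallow prefixes
  (`labelDepth = 3` by default).
* **Gray property.** Every edge of the folded adjacency graph joins two
  k-mers at Hamming distance 1, so a contiguous color patch is a family
  of single-substitution neighbors and its boundary localizes the
  discriminating position.

# Construction

## Geometry

The base triangle has unit edge with A = (0,0), B = (1,0),
C = (1/2, √3/2); these coordinates keep every cell vertex at dyadic
rationals times √3, far above rounding noise, and let all geometric
coincidence tests use an absolute tolerance of 1e-9 (adjacency detection
additionally snaps vertices to the exact integer lattice at scale
2^(k+1), making edge matching exact). The four digit maps are: digit 0,
point symmetry about the centroid composed with scale 1/2 (the central
inverted sub-triangle); digits 1–3, half-scale contractions toward A, B,
C. All four linear parts are ±I/2, so the composed transform of any
address is a scalar ±2^-k times the identity plus an offset — the bulk
constructor exploits this to build a depth-8 code (65,536 cells) in well
under a second. A cell's orientation (upward like the base, or inverted)
is read from the sign structure of the composed linear part as realized
in its vertices, not from a digit-parity formula, so it stays correct
under any change of the central map's chirality.

## The relation structure

The sequence attached to an address is generated by a 4×4 relation
matrix. A natural first hypothesis indexes it by the *previous
nucleotide*: the anchor dimer assignments are consistent with
table[n][d] = n ⊕ first_base(d) in the Klein four-group. That rule
reproduces every depth-2 value but provably cannot extend the Gray
property to depth 3: there exist edge-adjacent cells whose parents agree
in their last nucleotide while the children carry different digits, so
any bijective row assignment forces their last letters apart. We searched
the full design space — every assignment of digits to sub-triangles,
every vertex correspondence of the four affine maps, and every relation
table consistent with the fixed dimer values — and none satisfies the
Gray property beyond k = 2 under previous-nucleotide indexing.

The structure that does work indexes the matrix by the *previous digit*.
Encoding digits into the Klein four-group by w(0,1,2,3) = (11,00,10,01)
and classes into letters by Λ(00,10,01,11) = (A,G,C,T), nucleotide i is

> s_i = Λ( w(a_{i−1}) ⊕ w(a_i) ),  with a virtual leading digit a₀ = 0.

Equivalently s_i = R[fb(a_{i−1}), a_i] where fb maps digits (0,1,2,3) to
first bases (A,T,C,G) and R is the symmetric Latin square returned by
`relationMatrix()`. Rows T and C of R read (T,A,G,C) and (C,G,A,T),
reproducing the dimer families 10..13 → TT,TA,TG,TC and
20..23 → CC,CG,CA,CT exactly. The underlying reason this works is the
recurrence of a rolling tetrahedron on the triangular lattice: each
lattice vertex of the parent grid is always touched by the same solid
vertex (the vertex classes are simply coordinates mod 2), each cell's
next letter is the label of the parent-grid vertex it nests against (or
the complementary label for central cells), and the digit-pair formula is
the closed form of that assignment under the digit maps above.

One genuine freedom remains: the anchor values pin the letter labels
only through depth 2, and two self-consistent extrapolations exist for
deeper levels (per-level complement alternation, or stationary labels).
We adopt the stationary labels because they are the unique choice that
yields a *single*, position-independent relation matrix; the alternative
would require two matrices applied at alternating depths. A visible
consequence worth knowing: digit 0 duplicates the previous base at
position 2 (00 = AA, 10 = TT, 20 = CC, 30 = GG) but not universally at
deeper positions (330 → GAG), because the chain conditions on the
previous digit rather than the previous letter.

Nothing above is taken on faith: `verifyGrayCode()` re-derives the
adjacency from the geometry (with the fold) and checks bijectivity,
Hamming distances, 3-regularity, connectivity and the prefix hierarchy
exhaustively; the test suite runs it for k = 1..6 and cross-validates
the adjacency builder against an independent brute-force segment-sharing
and midpoint-reflection scan.

# k-mer statistics

`countKmers()` slides a width-k window with step 1 inside each record;
windows never span records, so concatenation artifacts cannot create
chimeric words. Windows containing any non-ACGT symbol are skipped by
default (assemblies contain N runs); `ambiguity = "error"` makes such
input fatal. Counting is single-stranded by default — strand
symmetrization changes the figures and should be a visible, opt-in choice
(`strand = "both"` adds reverse-complement windows).

Backgrounds come in three kinds. The zeroth-order model multiplies
independent mononucleotide probabilities. The order-m Markov model uses
(m+1)-mer frequencies for the initial block and per-context conditional
ratios thereafter; because the conditionals are normalized within each
context, the expected k-mer table telescopes to total mass 1 exactly, and
m = 0 collapses to the zeroth-order model by construction. The empirical
kind uses the k-mer table of a reference set, for cross-genome contrasts.

The displayed quantity is r(w) = log₂ f(w)/g(w). The logarithm base is a
display convention (it rescales colors only); bits are the customary unit
for sequence log-odds. Both frequencies are floored at
1/(2 · retained windows) before the ratio — a half-pseudocount that keeps
the field finite at unobserved words while leaving r = 0 wherever
f = g.

`cpgOE()` is f(CG)/(f(C)·f(G)) from the same window counts.
`cpgContextMatrix()` tallies the nucleotides at offsets −F..−1 and
+1..+F around every CG occurrence (the C at offset 0), normalizes per
position, and contrasts each position against the background's
mononucleotide marginal — the stationary distribution for Markov kinds,
the first-position marginal for empirical kinds. The per-position
expectation deliberately ignores positional correlation with the CG
anchor itself; the export therefore includes the raw conditional
frequencies so any alternative normalization can be recomputed downstream.
Consensus calls are argmax per position with alphabetical tie-breaking
(deterministic). Gene-level methylated/unmethylated partitioning is out
of scope: the functions accept arbitrary user-partitioned sequence sets.

# Rendering

`renderDevelopment()` emits plain SVG 1.1: one polygon per cell in
address order, prefix labels at the centroids of the depth-`labelDepth`
cells (default 3 — 64 labels, the deepest level that stays legible on a
printed octamer map), optional glue flaps, and a color-bar legend.
Default color scale: symmetric clamp at ±2 bits through a blue–white–red
diverging gradient (negative = depleted = blue); the gradient is pluggable
by name and the clamp is a parameter in log-odds units. Flaps are
trapezoids with 45°-cut ends, 5% of the base edge wide, attached to the
first half of each side walking A→B→C→A — one flap per glued half-edge
pair, purely decorative for paper craft and never colored. All
coordinates are emitted with fixed three-decimal formatting, so the
document is a pure function of its inputs and repeated runs are
byte-identical.

# The synthetic-genome generator

Tests and examples never download data; `simulateGenome()` provides the
controlled statistical structures instead. A `ChainSpec` holds base
probabilities p, dinucleotide multipliers, motif plants, a length and a
seed. The chain is defined through a joint dinucleotide distribution q:
every multiplied cell is pinned at q(a,b) = m·p(a)·p(b) exactly, and the
free cells are rescaled by iterative proportional fitting until both
marginals equal p. The transition matrix is the conditional of q, so the
stationary mononucleotide distribution is p exactly and the o/e-style
ratio of a multiplied dinucleotide equals its multiplier exactly — the
generator's headline dial is calibrated in the same units the analysis
reports. The marginal-preserving compensation necessarily spreads a small
opposite signal over the free cells (for CG = 0.2 on a uniform base:
+0.34 bits on the other C·/·G cells, −0.13 bits elsewhere — an order of
magnitude below the −2.32-bit CG signal); `analyticDinucleotideExpectation()`
returns the exact expectations so tests compare against the oracle rather
than against an idealized zero. Motifs are overwritten (not inserted) at
positions sampled independently at their per-position probability, which
keeps the length fixed and the background chain locally intact elsewhere.

For recovery tests, `cpgOEAsymptoticSD()` computes the delta-method
standard error of the o/e estimator using the exact asymptotic covariance
of the dinucleotide/mononucleotide frequencies from the fundamental
matrix of the 16-state pair chain — i.e. chain autocorrelation is
accounted for analytically, not assumed away.

What the generator emulates: stationary first-order composition with a
chosen CpG depletion/enrichment, and motif enrichment around CpG. What it
does not emulate: tandem repeats, isochore-scale heterogeneity,
methylation data, or length/GC covariation of real assemblies. Passing
tests therefore demonstrate correctness of the statistics on their
defined inputs, not biological completeness.

# Problem sizes, tolerances and limits

* Construction and rendering are capped at k = 10 (about a million
  cells); exhaustive Gray verification at k = 6 (4096 cells, 6144 edges,
  under a second) — beyond that the checks add confidence but no new
  structure, as the construction is depth-uniform.
* Recovery tests use 1 Mb chains (seeded), where the o/e standard error
  is ≈ 0.0017 — small enough that a 3-standard-error test is sharp, large
  enough to run in seconds.
* Geometric tolerances: 1e-9 absolute on raw coordinates; adjacency uses
  exact integer lattice keys at scale 2^(k+1).
* The frequency floor 1/(2N) and the context-matrix pseudocount are the
  only smoothing anywhere; both vanish as data grow.

# Known limitations

* The chirality of the layout is fixed by convention (digit 1→A, 2→B,
  3→C and the centroid half-turn); a mirror-image layout satisfies the
  same anchor values and Gray property, so figures from other
  implementations may be reflected.
* `cpgContextMatrix()`'s positional expectation is the background's
  marginal; it does not condition on distance from the CG anchor.
* The renderer emits flat SVG only; no pagination, no 3-D view.
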
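---
title: "Combinatorial fullerene graphs: spirals, Stone-Wales rewriting and spectral characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial fullerene graphs: spirals, Stone-Wales rewriting and spectral characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullerite)
```

## The objects

A fullerene on $n$ vertices is a 3-regular planar (equivalently, 3-connected
cubic spherical) graph whose faces are pentagons and hexagons.  Euler's
relation forces exactly 12 pentagons and $n/2-10$ hexagons, so $n$ must be
even, at least 20, and (by a classical non-existence result) not 22.  The
package works almost everywhere with the *dual* triangulation $T_n$: a sphere
triangulation on $m = n/2+2$ vertices with degrees 5 and 6, exactly twelve of
degree 5.  Duality is implemented on rotation systems (counterclockwise
cyclic neighbour orders per vertex); faces are traced by the standard
"next edge clockwise after the reversed edge" rule, and the two directions of
every edge appear in exactly one face walk each.  Because fullerenes are
cyclically 5-edge-connected, every 3-cycle of $T_n$ bounds a face; this is
what lets `triangulation_embedding()` reconstruct the unique sphere embedding
of a dual fullerene from its adjacency matrix alone (per-vertex link cycles,
oriented consistently by breadth-first propagation).

## Face spirals

A face spiral lists all $m$ faces so that face $k$ touches face $k-1$ and the
earliest face that is still open.  `windup()` replays such a degree sequence
into a triangulation, maintaining the open boundary as a double-ended queue
that rolls up over saturated faces; sequences that cannot close return a
typed rejection object rather than an error, because rejection is the normal
outcome for most pentagon placements.  `unwind_canonical()` searches all
starts — every start vertex, every adjacent second face, both winding
directions, with branching on the (rare) ambiguous continuations — and
returns the lexicographically smallest successful size sequence.  That code
is a complete isomorphism invariant on the range we handle; the first
fullerenes with no spiral at all appear near 380 vertices, far beyond any
computation here, and `unwind_canonical()` raises an explicit error for them.

`enumerate_isomers()` backtracks over partial spirals, placing a 5 or a 6 at
each position, pruning on windup failure, on the pentagon budget, and on an
endgame bound (the open boundary shrinks by at most three per face and the
last face must close it completely, so a boundary of size $b$ needs at least
$(b-6)/3$ more faces).  A completed sequence is emitted only when no strictly
smaller spiral of the decoded graph exists, so each isomorphism class appears
exactly once, in ascending lexicographic order of pentagon positions.  This
reproduces the reference counts (1 isomer of $C_{20}$, none of $C_{22}$, 1812
of $C_{60}$) and is cross-checked against a naive all-subsets oracle for
$n \le 26$.

Uniform random isomers come from acceptance-rejection: draw a 12-subset of
$\{1..m\}$ uniformly (by unranking a uniform integer), wind it up, and accept
only when the drawn vector *is* the canonical code of the decoded graph.
Each isomorphism class owns exactly one canonical code, which is what makes
accepted draws uniform.  A compatibility dialect draws positions from
$\{1..n\}$ instead; it only lowers the acceptance rate (about $1812 /
\binom{60}{12} \approx 10^{-9}$ at $n = 60$), which is why the package
defaults to the face-count dialect.

## Stone-Wales rewriting

Three operations act on duals:

* `psw_flip()` — the polyhedral Stone-Wales operation, a single diagonal
  flip: remove edge $(v_1,v_2)$, insert the edge between the two common
  neighbours.  It is closed on sphere triangulations, not on fullerenes; we
  additionally require that the inserted diagonal not already exist, which
  keeps the graph simple.
* `find_gsw_paths()` / `apply_gsw()` — the generalized Stone-Wales
  operation.  A gSW path is a zigzag $(v_1,\dots,v_{2w})$, $w \ge 2$, with
  degree-5 ends, degree-6 second and penultimate vertices, all vertices
  distinct, consecutive vertices adjacent and every skip-one pair adjacent.
  The rewiring is not given by formulas in the sources we follow, only
  functionally; we implement it as the minimal flip cascade along the path —
  remove $(v_{2i}, v_{2i+1})$ and insert $(v_{2i-1}, v_{2i+2})$ for
  $i = 1..w-1$ — and verify the functional contract in tests: the permuted
  sequence $(v_2,v_1,v_4,v_3,\dots)$ is a gSW path of the output, only the
  four end degrees swap, the output is again a dual fullerene, and applying
  the operation along the transformed path restores the input (self-inverse).
  With $w = 2$ the cascade is exactly one classic Stone-Wales flip.
* `psw_random_walk()` — uniformly random flips over flippable edges, with
  every dual-fullerene state flagged.  The literature selects flips by a
  polyhedral energy; that selection rule is not specified precisely enough to
  reimplement, so only the uniform walk is provided.  Uniform walks reach
  fullerene states far too rarely to cross the huge triangulation space of a
  32-vertex seed at test scale; the walk machinery is therefore exercised on
  small seeds, including a seed-fixed short walk that revisits a fullerene
  state by undoing its first flip.

Scanning all 22,430 isomers below 70 vertices finds exactly two duals without
any gSW path: the dodecahedron (trivially, having no hexagons) and isomer 622
of $C_{56}$.

## Triangular patches, the glued family, cut-partitions

A $t$-triangle is the triangular patch with $t^2$ unit triangles,
$(t+1)(t+2)/2$ vertices, corners of degree 2 and sides of degree 4.
Truncation is parameterized by the number of *rows* deleted at each corner:
`truncated_triangle(t, r1, r2, r3)` removes $r_i(r_i+1)/2$ vertices at corner
$i$ ($r = 1$ removes the corner vertex alone), and the edges between vertices
whose degree dropped are the open edges.  We fixed the row convention because
it is the unique reading under which the glued construction below reproduces
all of its stated counts (vertex totals $2(t^2+6t+2)$, per-patch triangle
counts $t^2+6t-3$, boundary degrees alternating 4 and 5, final
$n = 4(t^2+6t+7)$) consistently with Euler's relation; the alternative
reading (deleting $(r+1)(r+2)/2$ vertices) contradicts those counts and even
the identity between `truncated_triangle(t,0,0,0)` and `t_triangle(t)`.

`construction2(t)` glues four $(2t,(t-1,t-1,t-1))$-triangles along their open
corner paths in a tetrahedral pattern (each face of the tetrahedron is a
patch; the corner opposite a tetrahedron edge is glued, reversed, to its
partner across that edge).  The glued graph is the hexagonal subgraph of the
target dual: it has four hexagonal holes whose boundary degrees alternate 4
and 5, and inserting a triangle of three pentagonal vertices into each hole
(side middles receive two new edges, glued corners one) makes every degree 6
or 5 as required.  The result is a valid dual fullerene with no gSW path:
any zigzag between boundary vertices of two hexagonal holes has even length,
while a gSW path needs odd length.  The family proves that infinitely many
fullerenes are out of reach of gSW rewriting; `has_gsw_path()` confirms the
members $n = 92, 136, 188$ directly.

`cut_partition()` decomposes a hexagonal subgraph in two steps.  Step one
splits every vertex that borders two or more larger-than-triangle facets
into one vertex per fan of edges between consecutive large corners.  We
count large-facet *corners* rather than distinct facets: successive cuts
merge the holes into one region, and corner counting is the reading under
which the documented decompositions (four 2-triangles for $T_{56,622}$,
twenty 1-triangles for the $n=80$ counterexample, four $(4,(1,1,1))$-
triangles for the $n=92$ family member) come out, while remaining equivalent
to facet counting on the original graph.  Step two separates remaining
degree-5 vertices along a minimal path whose edges border only triangles,
duplicating the path and reattaching one geometric side to the copies; ties
are broken lexicographically (smallest pair, then smallest path), and the
side containing the smallest off-path vertex id stays with the originals.
Components are classified by isomorphism against generated patch templates.

`conjecture2_scan()` evaluates the conjectured equivalence "partition
consists solely of (truncated) $t$-triangles $\iff$ no gSW path", with the
stated exception for partitions of 0-triangles only.  Implemented literally,
the equivalence has trivial small-$n$ failures: isomers whose hexagonal
subgraph already falls apart into disjoint 1-triangles (first at $n = 32$)
satisfy the partition condition yet carry perfectly valid $w = 3$ gSW paths,
which we verified end-to-end by applying the operation.  The scan reports
such rows honestly; what does hold, and what the tests freeze, is that every
gSW-free isomer is correctly characterized and all disagreements are
gSW-capable isomers with all-triangle partitions of size $t \le 1$.

## Named families

* `nanotube_5_0(n)` — tubes for $n = 20+10r$: two caps of six degree-5 dual
  vertices (apex plus five-ring) separated by $r$ five-vertex belts, rings
  joined in antiprism fashion; $r = 0$ is the icosahedron.
* `goldberg(p, q)` — the $(p,q)$ Goldberg-Coxeter subdivision of the
  icosahedron, $n = 20((p+q)^2-pq)$.  Each icosahedral face carries a chart
  of the Eisenstein lattice spanned by $z = p + q\zeta$, $\zeta = e^{i\pi/3}$;
  charts are glued by exact integer affine maps, so chiral cases such as
  $(2,1)$ need no floating point.  The chirality convention is $p \ge q$.
* `construction3(n)` — seed isomers for every even $n \ge 36$: a six-vertex
  boundary cycle with degree-deficit labels $(1,2,2,2,2,3)$ is located in the
  first $C_{36}$ isomer; one vertex is inserted per step (joined to the
  vertex labeled 1 and its neighbours labeled 2 and 3), which provably
  preserves the label vector, and the detached component is reattached at
  the end by the label-preserving rotation.
* `bipyramid_seed(m)` — the dual of the $(m-2)$-gonal prism, the classic
  seed of flip random walks.

## Spectral characters

For a graph with adjacency matrix $A$ and degree matrix $D$, the
$(\alpha,\beta)$-character is
$\mathrm{tr}\, e^{\alpha A + \beta D} = \sum_j e^{\alpha\lambda_j}$ where
$\lambda_j$ are the eigenvalues of $A + (\beta/\alpha)D$.  We compute it from
the symmetric eigendecomposition (numerically stable and exact to machine
precision at these sizes); the matrix-exponential definition is retained as a
cross-check in tests at $10^{-9}$ relative tolerance, and the power sums
`newton_polynomial()` tie the spectrum back to closed-walk counting.  As
$\alpha,\beta \to 0$ the character approaches the vertex count, which the
tests check at $\alpha=\beta=10^{-8}$ within $10^{-6}$.

Default parameters are $(\alpha,\beta) = (1/2, 1/4)$ for dual graphs (the
choice under which normalized closed-walk counts of $A + D/2$ have a
hexagonal-lattice limit) and $(1,0)$ is the natural choice for primal
fullerene graphs.  Within each isomer set the $(5,0)$-nanotube attains the
maximal character (narrow tubes support the most closed walks) and the
Goldberg dual the minimal one; for $n$ admitting both (60, 80, 140) these
anchor `normalized_character()` at 1 and 0.  The range experiment over
$n \in \{58,60,62\}$ reproduces the qualitative parameter story: at
$(1,1)$ consecutive character ranges overlap; at $(1,1/2)$ only a residual
$C_{60}$–$C_{62}$ overlap remains, caused by the disproportionately large
character of the $(5,0)$-nanotube in $C_{60}$; at $(1/2,1)$ and at the
default $(1/2,1/4)$ the ranges are disjoint, and only the default keeps the
values at a practical scale.  `conjecture3_check()` compares characters of
all isomers across $n$ at a configurable relative tolerance (default
$10^{-9}$).  Up to $n = 50$ there is no collision at numerical resolution
($10^{-12}$); the default tolerance flags a single near-degenerate pair of
$C_{50}$ isomers whose characters differ by $8.7\times10^{-10}$ relative —
three orders of magnitude above eigensolver error, hence genuinely distinct.
This supports — without proving — the conjectured injectivity, and
illustrates why the comparison tolerance is exposed as a parameter.

`riemann_zeta()` uses Euler-Maclaurin-corrected partial sums (default
$K = 100$ explicit terms, remainder bounded by the first omitted Bernoulli
term), giving at least ten significant digits for all $s > 1$; $\zeta(9)
\approx 1.00200839$ is the constant entering the asymptotic isomer-count
formula.

## Problem sizes, determinism, limitations

The test suite and the acceptance script enumerate all isomers up to
$n = 68$ (22,430 graphs, a few minutes with the compiled spiral kernels),
run the character experiments on the 5,402 isomers of $n \in \{58,60,62\}$,
check operation properties exhaustively up to $n = 40$, and draw $10^4$
accepted samples at $n = 28$.  Enumerations are cached per session.  All
stochastic entry points take explicit integer seeds and are bit-reproducible;
search orders and tie-breaks are deterministic as described above.

Known limitations, all deliberate: generalized spirals with jumps (needed
first at $n = 380$) are not implemented; the radial variant of the
generalized Stone-Wales operation is out of scope; flip walks use uniform
selection only; the $n \le 400$ isomer census and the asymptotic count
formula are represented only by the $\zeta(9)$ constant and by property
tests; the gSW-free isomer of $C_{96}$ (rank 191839) has no independent
generator in the package, so its cut-partition is not asserted at test
scale; and the cut-partition of graphs whose degree-5 vertices admit no
admissible separating path is reported as an explicit error rather than
guessed.  Synthetic inputs (enumerated, constructed or sampled graphs) cover
the combinatorial universe exactly, so unlike data-driven packages there is
no model-vs-reality gap: what the tests do not show is anything about
chemical stability or 3-D geometry, which the package deliberately does not
model.
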
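Package: fullerite
Title: Combinatorial Fullerene Graphs, Face Spirals, Stone-Wales Rewriting
    and Spectral Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the combinatorial study of fullerene graphs
    (3-regular planar graphs with pentagonal and hexagonal faces) and
    their dual triangulations.  Implements rotation-system planar
    embeddings with face tracing and dualization; face-spiral encoding,
    canonical codes, lexicographic enumeration, ranking and an
    acceptance-rejection uniform sampler of isomers; the Stone-Wales
    family of isomerization operations (classic SW, the polyhedral
    edge-flip variant and the generalized path-based operation) together
    with exhaustive gSW-path search; deterministic generators for named
    families ((5,0)-nanotubes, Goldberg polyhedra, triangular patches and
    a glued family on which the generalized Stone-Wales operation is
    provably inapplicable); cut-partition analysis of hexagonal
    subgraphs; and spectral invariants based on the trace of the matrix
    exponential of linear combinations of adjacency and degree matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
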
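#' Fullerene graphs and their dual triangulations
#'
#' A fullerene on n vertices (n even, n >= 20, n != 22) is a 3-regular
#' planar graph whose faces are 12 pentagons and n/2 - 10 hexagons.  Its
#' unique dual is a sphere triangulation on m = n/2 + 2 vertices with
#' degrees in \{5, 6\} and exactly twelve vertices of degree 5; the twelve
#' degree-5 vertices correspond to the pentagonal faces.
#'
#' @param emb a `planar_embedding` satisfying the fullerene invariants.
#' @return an object of class `fullerene` (fields `embedding`, `n`).
#' @export
fullerene <- function(emb) {
  validate_embedding(emb)
  deg <- embedding_degrees(emb)
  if (any(deg != 3L)) stop("not 3-regular: a fullerene vertex has degree 3")
  fs <- lengths(trace_faces(emb, check = FALSE))
  if (!all(fs %in% c(5L, 6L)))
    stop("face of size ", paste(setdiff(fs, c(5L, 6L)), collapse = ","),
         " found; fullerene faces are pentagons and hexagons")
  n <- emb$n_vertices
  if (sum(fs == 5L) != 12L) stop("expected 12 pentagonal faces, found ", sum(fs == 5L))
  if (sum(fs == 6L) != n / 2 - 10L)
    stop("expected ", n / 2 - 10L, " hexagonal faces, found ", sum(fs == 6L))
  structure(list(embedding = emb, n = n), class = "fullerene")
}

#' @rdname fullerene
#' @param t a `planar_embedding` satisfying the dual-triangulation
#'   invariants (all faces triangles, degrees 5 or 6, twelve of degree 5).
#' @export
dual_triangulation <- function(t) {
  validate_embedding(t)
  fs <- lengths(trace_faces(t, check = FALSE))
  if (!all(fs == 3L)) stop("non-triangular face in dual triangulation")
  deg <- embedding_degrees(t)
  if (!all(deg %in% c(5L, 6L)))
    stop("dual fullerene degrees must be 5 or 6")
  if (sum(deg == 5L) != 12L)
    stop("expected 12 degree-5 vertices, found ", sum(deg == 5L))
  structure(list(embedding = t, m = t$n_vertices), class = "dual_triangulation")
}

#' @export
print.fullerene <- function(x, ...) {
  cat("fullerene C", x$n, " (", x$n / 2 - 10, " hexagons)\n", sep = "")
  invisible(x)
}

#' @export
print.dual_triangulation <- function(x, ...) {
  cat("dual fullerene triangulation, m =", x$m,
      "vertices (n =", 2 * (x$m - 2), ")\n")
  invisible(x)
}

#' Dualize a fullerene / invert the dualization
#'
#' `dualize` maps a fullerene to its dual triangulation (faces become
#' vertices); `dualize_inverse` maps the triangulation back.  The two are
#' mutually inverse up to isomorphism, and the vertex counts satisfy
#' m = n/2 + 2.
#'
#' @param f a `fullerene`.
#' @return `dualize`: a `dual_triangulation`; `dualize_inverse`: a
#'   `fullerene`.
#' @export
dualize <- function(f) {
  stopifnot(inherits(f, "fullerene"))
  dual_triangulation(dual_embedding(f$embedding))
}

#' @rdname dualize
#' @param t a `dual_triangulation`.
#' @export
dualize_inverse <- function(t) {
  stopifnot(inherits(t, "dual_triangulation"))
  fullerene(dual_embedding(t$embedding))
}

#' Build a dual triangulation from an adjacency matrix
#'
#' Reconstructs the (unique) sphere embedding via link cycles and wraps it
#' as a validated `dual_triangulation`.
#'
#' @param adj symmetric 0/1 adjacency matrix of a dual fullerene graph.
#' @return a `dual_triangulation`.
#' @export
dual_from_adjacency <- function(adj) {
  dual_triangulation(triangulation_embedding(adj))
}

# induced subgraph with inherited rotation; vertices relabelled 1..k,
# original ids kept alongside
subgraph_embedding <- function(emb, keep) {
  keep <- sort(as.integer(keep))
  idx <- integer(emb$n_vertices)
  idx[keep] <- seq_along(keep)
  rot <- lapply(keep, function(v) {
    nb <- emb$rotation[[v]]
    idx[nb[nb %in% keep]]
  })
  structure(list(n_vertices = length(keep), rotation = rot, orig_ids = keep),
            class = "subgraph_embedding")
}

#' Pentagonal and hexagonal subgraphs of a dual fullerene
#'
#' `subgraph5` is induced by the twelve degree-5 vertices (pentagon
#' adjacency); `subgraph6` by the degree-6 vertices (hexagon adjacency).
#' Rotations are inherited from the dual embedding, so the faces of the
#' hexagonal subgraph remain available for cut-partition analysis.
#'
#' @param t a `dual_triangulation`.
#' @return a `subgraph_embedding` (fields `n_vertices`, `rotation`,
#'   `orig_ids`; rotation in the relabelled ids `1..n_vertices`).
#' @export
subgraph5 <- function(t) {
  stopifnot(inherits(t, "dual_triangulation"))
  subgraph_embedding(t$embedding, which(embedding_degrees(t$embedding) == 5L))
}

#' @rdname subgraph5
#' @export
subgraph6 <- function(t) {
  stopifnot(inherits(t, "dual_triangulation"))
  subgraph_embedding(t$embedding, which(embedding_degrees(t$embedding) == 6L))
}

# connected components of a subgraph_embedding (or rotation list);
# returns list of integer vectors of (local) vertex ids
rotation_components <- function(rot) {
  n <- length(rot)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in rot[[v]]) if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  split(seq_len(n), comp)
}

#' Pentagon-cluster partition of a dual fullerene
#'
#' The sizes of the connected components of the pentagonal subgraph, sorted
#' non-increasingly: an integer partition of 12.  The partition
#' (1,1,...,1) characterizes isolated-pentagon (IPR) isomers.
#'
#' @param t a `dual_triangulation`.
#' @return integer vector, non-increasing, summing to 12.
#' @export
pentagon_partition <- function(t) {
  s5 <- subgraph5(t)
  parts <- sort(lengths(rotation_components(s5$rotation)), decreasing = TRUE)
  stopifnot(sum(parts) == 12L)
  as.integer(parts)
}

#' Does a dual fullerene satisfy the isolated pentagon rule?
#'
#' TRUE iff the pentagonal subgraph has no edges, i.e. no two pentagonal
#' faces of the fullerene are adjacent.
#'
#' @param t a `dual_triangulation`.
#' @return logical.
#' @export
is_ipr <- function(t) {
  s5 <- subgraph5(t)
  sum(lengths(s5$rotation)) == 0L
}

#' Number of integer partitions
#'
#' Counts the partitions of k into positive parts (77 for k = 12, the
#' reference count for pentagon-cluster partitions).
#'
#' @param k positive integer.
#' @return integer partition count.
#' @export
count_integer_partitions <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  k <- as.integer(k)
  # p(i, j): partitions of i with parts <= j
  p <- matrix(0L, k + 1L, k + 1L)
  p[1L, ] <- 1L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      p[i + 1L, j + 1L] <- p[i + 1L, j] +
        if (i - j >= 0L) p[i - j + 1L, j + 1L] else 0L
    }
  }
  p[k + 1L, k + 1L]
}
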
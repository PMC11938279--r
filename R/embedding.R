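#' Planar embeddings as rotation systems
#'
#' A planar (combinatorial) embedding of a connected simple graph is stored
#' as a rotation system: for every vertex, the counterclockwise cyclic order
#' of its neighbours.  Faces are traced with the standard rule that the
#' directed edge (a, b) is followed by (b, c), where c is the neighbour
#' immediately before a in the rotation at b; for a genus-0 rotation system
#' the traced faces satisfy Euler's relation V - E + F = 2.
#'
#' @param rotation list of integer vectors; element `v` holds the cyclic
#'   (counterclockwise) neighbour order of vertex `v`.  Vertex ids are the
#'   contiguous integers `1..length(rotation)`.
#' @return An object of class `planar_embedding` with fields
#'   `n_vertices`, `rotation`.
#' @examples
#' tri <- planar_embedding(list(c(2L, 3L), c(3L, 1L), c(1L, 2L)))
#' length(trace_faces(tri))  # 2 faces
#' @export
planar_embedding <- function(rotation) {
  rotation <- lapply(rotation, function(x) as.integer(x))
  emb <- structure(list(n_vertices = length(rotation), rotation = rotation),
                   class = "planar_embedding")
  validate_embedding(emb)
  emb
}

#' Validate a planar embedding
#'
#' Checks that the rotation system describes a connected simple graph whose
#' traced face set satisfies Euler's relation (genus 0).
#'
#' @param emb a `planar_embedding`.
#' @return `emb`, invisibly; an error is signalled on violation.
#' @export
validate_embedding <- function(emb) {
  stopifnot(inherits(emb, "planar_embedding"))
  n <- emb$n_vertices
  rot <- emb$rotation
  if (n < 1L) stop("embedding has no vertices")
  if (n == 1L && length(rot[[1L]]) == 0L) return(invisible(emb))  # single vertex
  for (v in seq_len(n)) {
    nb <- rot[[v]]
    if (anyNA(nb) || any(nb < 1L) || any(nb > n))
      stop("vertex ", v, ": neighbour id out of range")
    if (any(nb == v)) stop("vertex ", v, ": loop edge")
    if (anyDuplicated(nb)) stop("vertex ", v, ": parallel edge")
  }
  # symmetry
  for (v in seq_len(n)) {
    for (u in rot[[v]]) {
      if (!(v %in% rot[[u]]))
        stop("edge (", v, ",", u, ") is not symmetric")
    }
  }
  # connectivity
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (u in rot[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  if (!all(seen)) stop("graph is not connected")
  nE <- sum(lengths(rot)) / 2
  faces <- trace_faces(emb, check = FALSE)
  if (n - nE + length(faces) != 2)
    stop("rotation system is not planar: V - E + F = ",
         n - nE + length(faces), ", expected 2")
  invisible(emb)
}

#' Trace the faces of a rotation system
#'
#' Every directed edge lies on exactly one face walk; walks are closed
#' cyclic vertex sequences.
#'
#' @param emb a `planar_embedding`.
#' @param check validate the embedding first (the validator itself calls
#'   with `check = FALSE`).
#' @return list of integer vectors, one cyclic vertex walk per face.
#' @export
trace_faces <- function(emb, check = TRUE) {
  if (check) validate_embedding(emb)
  .trace_rotation(emb$rotation)
}

# face tracing on a bare rotation list (vertex ids 1..length(rot));
# works for disconnected rotation systems as well
.trace_rotation <- function(rot) {
  n <- length(rot)
  # index of each neighbour within each rotation for O(1) lookup
  pos <- lapply(seq_len(n), function(v) {
    p <- integer(n)
    p[rot[[v]]] <- seq_along(rot[[v]])
    p
  })
  used <- new.env(hash = TRUE, size = 4L * n)
  faces <- list()
  for (a in seq_len(n)) {
    for (b in rot[[a]]) {
      key <- paste0(a, ".", b)
      if (!is.null(used[[key]])) next
      walk <- integer(0)
      x <- a; y <- b
      repeat {
        used[[paste0(x, ".", y)]] <- TRUE
        walk <- c(walk, x)
        # next directed edge: (y, z), z = neighbour before x in rot[[y]]
        k <- pos[[y]][x]
        ry <- rot[[y]]
        z <- ry[[if (k == 1L) length(ry) else k - 1L]]
        x <- y; y <- z
        if (x == a && y == b) break
        if (length(walk) > 6L * n) stop("face tracing did not close")
      }
      faces[[length(faces) + 1L]] <- walk
    }
  }
  faces
}

#' Dual of a planar embedding
#'
#' Vertices of the dual are the faces of `emb`; two dual vertices are
#' adjacent once for every edge their faces share, and the dual rotation at
#' a face follows that face's boundary walk.  Applying the operation twice
#' returns an embedding isomorphic to the input (sphere duality).
#'
#' @param emb a `planar_embedding` whose dual is again simple (true for
#'   3-connected graphs such as fullerenes and their duals).
#' @return a `planar_embedding` of the dual graph; attribute `face_walks`
#'   carries the primal face walks defining the dual vertices.
#' @export
dual_embedding <- function(emb) {
  faces <- trace_faces(emb)
  nf <- length(faces)
  # map directed edge -> face id
  edge_face <- new.env(hash = TRUE, size = 4L * emb$n_vertices)
  for (f in seq_len(nf)) {
    w <- faces[[f]]
    l <- length(w)
    for (i in seq_len(l)) {
      a <- w[[i]]; b <- w[[if (i == l) 1L else i + 1L]]
      edge_face[[paste0(a, ".", b)]] <- f
    }
  }
  rot <- vector("list", nf)
  for (f in seq_len(nf)) {
    w <- faces[[f]]
    l <- length(w)
    nb <- integer(l)
    for (i in seq_len(l)) {
      a <- w[[i]]; b <- w[[if (i == l) 1L else i + 1L]]
      nb[[i]] <- edge_face[[paste0(b, ".", a)]]   # face across the edge
    }
    rot[[f]] <- nb
  }
  out <- planar_embedding(rot)
  attr(out, "face_walks") <- faces
  out
}

#' Reconstruct the embedding of a sphere triangulation from adjacency
#'
#' In a triangulation all of whose 3-cycles are faces (true for dual
#' fullerenes, which are cyclically 5-edge-connected in the primal), the
#' neighbours of each vertex form a single cycle in which consecutive
#' neighbours are adjacent.  The per-vertex cycles are oriented consistently
#' by breadth-first propagation and verified by face tracing.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @return a `planar_embedding`.
#' @export
triangulation_embedding <- function(adj) {
  n <- nrow(adj)
  nbl <- lapply(seq_len(n), function(v) which(adj[v, ] != 0))
  link_cycle <- function(v) {
    nb <- nbl[[v]]
    d <- length(nb)
    if (d < 3L) stop("vertex ", v, " has degree < 3; not a triangulation")
    cyc <- nb[[1L]]
    prev <- 0L
    while (length(cyc) < d) {
      last <- cyc[[length(cyc)]]
      nxt <- nb[adj[last, nb] != 0 & !(nb %in% c(cyc, prev))]
      if (length(nxt) < 1L)
        stop("link of vertex ", v, " is not a cycle")
      cyc <- c(cyc, nxt[[1L]])
    }
    last <- cyc[[length(cyc)]]
    if (adj[last, cyc[[1L]]] == 0) stop("link of vertex ", v, " does not close")
    cyc
  }
  rot <- lapply(seq_len(n), link_cycle)
  # orient consistently: for face (u,v,w) CCW, w = next(rot[u], v) requires
  # next(rot[v], w) == u
  nxt_in <- function(r, x) r[[(match(x, r) %% length(r)) + 1L]]
  oriented <- logical(n)
  oriented[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (v in rot[[u]]) {
      w <- nxt_in(rot[[u]], v)
      if (!oriented[v]) {
        if (nxt_in(rot[[v]], w) != u) rot[[v]] <- rev(rot[[v]])
        if (nxt_in(rot[[v]], w) != u)
          stop("could not orient link of vertex ", v)
        oriented[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  emb <- planar_embedding(rot)
  if (any(lengths(trace_faces(emb)) != 3L))
    stop("reconstructed embedding has a non-triangular face")
  emb
}

#' Build an embedding from plane coordinates
#'
#' Neighbours are sorted counterclockwise by angle around each vertex;
#' intended for patch graphs drawn in the plane (triangular grids).
#'
#' @param edges two-column integer matrix of undirected edges.
#' @param xy two-column coordinate matrix, one row per vertex.
#' @return a `planar_embedding` (the outer face is whatever the drawing
#'   leaves unbounded).
#' @export
embedding_from_coords <- function(edges, xy) {
  n <- nrow(xy)
  nbl <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    nbl[[a]] <- c(nbl[[a]], b)
    nbl[[b]] <- c(nbl[[b]], a)
  }
  rot <- lapply(seq_len(n), function(v) {
    nb <- unique(nbl[[v]])
    ang <- atan2(xy[nb, 2L] - xy[v, 2L], xy[nb, 1L] - xy[v, 1L])
    nb[order(ang)]
  })
  planar_embedding(rot)
}

#' Adjacency matrix of an embedding
#' @param emb a `planar_embedding`.
#' @return symmetric 0/1 integer matrix.
#' @export
embedding_adjacency <- function(emb) {
  n <- emb$n_vertices
  a <- matrix(0L, n, n)
  for (v in seq_len(n)) a[v, emb$rotation[[v]]] <- 1L
  a
}

#' Vertex degrees of an embedding
#' @param emb a `planar_embedding`.
#' @return integer vector of degrees.
#' @export
embedding_degrees <- function(emb) lengths(emb$rotation)

#' Number of edges of an embedding
#' @param emb a `planar_embedding`.
#' @return integer edge count.
#' @export
embedding_edges <- function(emb) as.integer(sum(lengths(emb$rotation)) / 2)

#' @export
print.planar_embedding <- function(x, ...) {
  cat("planar embedding:", x$n_vertices, "vertices,",
      embedding_edges(x), "edges\n")
  invisible(x)
}
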
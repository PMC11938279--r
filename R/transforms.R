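#' General sphere triangulations
#'
#' The polyhedral Stone-Wales edge flip is closed on the set of all sphere
#' triangulations with a fixed vertex count, not on dual fullerenes, so
#' intermediate walk states are wrapped in this weaker class (all faces
#' triangles, no degree restriction).
#'
#' @param emb a `planar_embedding` all of whose faces are triangles.
#' @return an object of class `triangulation`.
#' @export
triangulation <- function(emb) {
  validate_embedding(emb)
  if (any(lengths(trace_faces(emb, check = FALSE)) != 3L))
    stop("embedding has a non-triangular face")
  structure(list(embedding = emb, m = emb$n_vertices), class = "triangulation")
}

#' @export
print.triangulation <- function(x, ...) {
  cat("sphere triangulation, m =", x$m, "vertices\n")
  invisible(x)
}

# embedding accessor for triangulation-like inputs
.tri_embedding <- function(t) {
  if (inherits(t, c("dual_triangulation", "triangulation"))) t$embedding
  else if (inherits(t, "planar_embedding")) t
  else stop("expected a triangulation, dual_triangulation or planar_embedding")
}

#' Is a triangulation a valid dual fullerene?
#'
#' @param t a `triangulation` (or `dual_triangulation`).
#' @return logical: all degrees 5 or 6 with exactly twelve 5s.
#' @export
is_dual_fullerene <- function(t) {
  deg <- embedding_degrees(.tri_embedding(t))
  all(deg %in% c(5L, 6L)) && sum(deg == 5L) == 12L
}

# cyclic-order helpers on rotation vectors
.rot_next <- function(r, x) r[[(match(x, r) %% length(r)) + 1L]]
.rot_prev <- function(r, x) r[[((match(x, r) - 2L) %% length(r)) + 1L]]
.rot_delete <- function(r, x) r[r != x]
.rot_insert_between <- function(r, a, b, x) {
  ia <- match(a, r)
  l <- length(r)
  if (r[[(ia %% l) + 1L]] == b) append(r, x, after = ia)
  else {
    ib <- match(b, r)
    if (r[[(ib %% l) + 1L]] != a) stop("vertices not consecutive in rotation")
    append(r, x, after = ib)
  }
}

#' Polyhedral Stone-Wales edge flip
#'
#' Removes the edge (v1, v2) and inserts the edge (v3, v4) between the two
#' common neighbours of its endpoints, i.e. a diagonal flip of the
#' quadrilateral formed by the two triangles on the edge.  Degrees of v1
#' and v2 drop by one, those of v3 and v4 grow by one.  When v1, v2 have
#' degree 6 and v3, v4 degree 5 this is the classic Stone-Wales operation
#' on the underlying fullerene.
#'
#' @param t a `triangulation`, `dual_triangulation` or `planar_embedding`.
#' @param edge integer vector `c(v1, v2)`; the edge must exist and the flip
#'   must not create a parallel edge (v3, v4 not already adjacent).
#' @return a `triangulation` on the same vertex set.
#' @export
psw_flip <- function(t, edge) {
  emb <- .tri_embedding(t)
  v1 <- as.integer(edge[[1L]]); v2 <- as.integer(edge[[2L]])
  rot <- emb$rotation
  if (!(v2 %in% rot[[v1]])) stop("edge (", v1, ",", v2, ") does not exist")
  v3 <- .rot_next(rot[[v1]], v2)
  v4 <- .rot_prev(rot[[v1]], v2)
  if (v3 == v4) stop("endpoints have a single common neighbour; not a flip site")
  if (v4 %in% rot[[v3]])
    stop("flip would create a parallel edge: (", v3, ",", v4, ") already present")
  rot[[v1]] <- .rot_delete(rot[[v1]], v2)
  rot[[v2]] <- .rot_delete(rot[[v2]], v1)
  rot[[v3]] <- .rot_insert_between(rot[[v3]], v1, v2, v4)
  rot[[v4]] <- .rot_insert_between(rot[[v4]], v1, v2, v3)
  triangulation(planar_embedding(rot))
}

#' Find generalized Stone-Wales (gSW) paths
#'
#' A gSW path is a zigzag sequence (v1, ..., v2w), w >= 2, of distinct
#' vertices of a dual fullerene with deg(v1) = deg(v2w) = 5, deg(v2) =
#' deg(v2w-1) = 6, consecutive vertices adjacent and every two vertices at
#' distance two along the sequence also adjacent.  The search is an
#' exhaustive depth-first zigzag extension; its existence is the
#' precondition for the gSW operation.
#'
#' @param t a `dual_triangulation`.
#' @param max_w largest half-length searched; defaults to m/2 (a
#'   self-avoiding zigzag cannot use more than m vertices).
#' @return list of integer vectors (paths), sorted lexicographically.
#' @export
find_gsw_paths <- function(t, max_w = NULL) {
  emb <- .tri_embedding(t)
  adj <- embedding_adjacency(emb)
  deg <- embedding_degrees(emb)
  if (is.null(max_w)) max_w <- emb$n_vertices %/% 2L
  paths <- .gsw_paths_cpp(adj, deg, as.integer(max_w), FALSE)
  if (length(paths) == 0L) return(list())
  key <- vapply(paths, function(p) paste(sprintf("%04d", p), collapse = ""), character(1))
  paths[order(key)]
}

#' @rdname find_gsw_paths
#' @return `has_gsw_path`: logical.
#' @export
has_gsw_path <- function(t, max_w = NULL) {
  emb <- .tri_embedding(t)
  adj <- embedding_adjacency(emb)
  deg <- embedding_degrees(emb)
  if (is.null(max_w)) max_w <- emb$n_vertices %/% 2L
  length(.gsw_paths_cpp(adj, deg, as.integer(max_w), TRUE)) > 0L
}

# adjacency-matrix fast path used by bulk scans
.has_gsw_adj <- function(adj) {
  deg <- as.integer(rowSums(adj))
  length(.gsw_paths_cpp(adj, deg, nrow(adj) %/% 2L, TRUE)) > 0L
}

#' Check the gSW path conditions
#'
#' @param t a `dual_triangulation`.
#' @param p integer vector of vertex ids, length 2w with w >= 2.
#' @return logical with attribute `reason` on failure.
#' @export
is_gsw_path <- function(t, p) {
  emb <- .tri_embedding(t)
  adj <- embedding_adjacency(emb)
  deg <- embedding_degrees(emb)
  p <- as.integer(p)
  fail <- function(msg) structure(FALSE, reason = msg)
  l <- length(p)
  if (l < 4L || l %% 2L != 0L) return(fail("length must be even and at least 4"))
  if (anyDuplicated(p)) return(fail("vertices must be distinct"))
  if (deg[p[1L]] != 5L || deg[p[l]] != 5L) return(fail("end vertices must have degree 5"))
  if (deg[p[2L]] != 6L || deg[p[l - 1L]] != 6L)
    return(fail("second and second-to-last vertices must have degree 6"))
  for (i in seq_len(l - 1L)) if (adj[p[i], p[i + 1L]] == 0L)
    return(fail("consecutive vertices must be adjacent"))
  for (i in seq_len(l - 2L)) if (adj[p[i], p[i + 2L]] == 0L)
    return(fail("skip-one pairs must be adjacent"))
  TRUE
}

#' Apply the generalized Stone-Wales operation
#'
#' Transports the pentagon/hexagon defect pairs at the two ends of a gSW
#' path across each other: for i = 1..w-1 the edge (v_2i, v_2i+1) is
#' removed and the edge (v_2i-1, v_2i+2) inserted (a cascade of diagonal
#' flips along the zigzag).  Degrees of v1, v2 and of v_2w-1, v_2w are
#' exchanged (5 and 6 swap); all other degrees are preserved, so the result
#' is again a dual fullerene.  The permuted sequence (v2, v1, v4, v3, ...,
#' v2w, v2w-1) is a gSW path of the output, and applying the operation
#' along it restores the input: the operation is self-inverse.  With w = 2
#' it reduces to the classic Stone-Wales flip.
#'
#' @param t a `dual_triangulation`.
#' @param p a gSW path of `t` (integer vector, length 2w).
#' @return a `dual_triangulation` on the same vertex set.
#' @export
apply_gsw <- function(t, p) {
  stopifnot(inherits(t, c("dual_triangulation", "triangulation")))
  ok <- is_gsw_path(t, p)
  if (!isTRUE(ok)) stop("not a gSW path: ", attr(ok, "reason"))
  p <- as.integer(p)
  w <- length(p) %/% 2L
  adj <- embedding_adjacency(.tri_embedding(t))
  for (i in seq_len(w - 1L)) {
    a <- p[2L * i]; b <- p[2L * i + 1L]          # edge removed
    c <- p[2L * i - 1L]; d <- p[2L * i + 2L]     # edge inserted
    if (adj[c, d] != 0L)
      stop("gSW rewiring would create a parallel edge (", c, ",", d, ")")
    adj[a, b] <- adj[b, a] <- 0L
    adj[c, d] <- adj[d, c] <- 1L
  }
  dual_from_adjacency(adj)
}

#' The transformed gSW path after the operation
#'
#' @param p a gSW path (length 2w).
#' @return the sequence (v2, v1, v4, v3, ..., v2w, v2w-1), which is a gSW
#'   path of `apply_gsw(t, p)`.
#' @export
gsw_transformed_path <- function(p) {
  l <- length(p)
  idx <- as.vector(rbind(seq(2L, l, by = 2L), seq(1L, l, by = 2L)))
  p[idx]
}

#' Random walk of polyhedral Stone-Wales flips
#'
#' Performs uniformly random flips over the flippable edges of a sphere
#' triangulation (edges whose flip does not create a parallel edge),
#' flagging every state that satisfies the dual-fullerene degree
#' invariants.  By Wagner's theorem such flips connect all triangulations
#' on a fixed vertex count, which makes the walk a complete (if
#' undirected) isomerization scheme.
#'
#' @param t starting `triangulation` (e.g. `bipyramid_seed`).
#' @param steps number of flips.
#' @param rng_seed integer seed.
#' @param keep_trace keep every intermediate triangulation (memory heavy
#'   for long walks); the summary table is always returned.
#' @return list with `final` (a `triangulation`), `summary` (data.frame:
#'   step, edge endpoints, is_dual_fullerene) and optionally `trace`.
#' @export
psw_random_walk <- function(t, steps, rng_seed, keep_trace = FALSE) {
  stopifnot(inherits(t, c("triangulation", "dual_triangulation")))
  cur <- triangulation(.tri_embedding(t))
  set.seed(as.integer(rng_seed))
  steps <- as.integer(steps)
  rows <- vector("list", steps)
  trace <- if (keep_trace) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    emb <- cur$embedding
    rot <- emb$rotation
    flippable <- list()
    for (v1 in seq_len(emb$n_vertices)) {
      for (v2 in rot[[v1]]) {
        if (v2 < v1) next
        v3 <- .rot_next(rot[[v1]], v2)
        v4 <- .rot_prev(rot[[v1]], v2)
        if (v3 != v4 && !(v4 %in% rot[[v3]]))
          flippable[[length(flippable) + 1L]] <- c(v1, v2)
      }
    }
    if (length(flippable) == 0L) stop("no flippable edge (degenerate triangulation)")
    e <- flippable[[sample.int(length(flippable), 1L)]]
    cur <- psw_flip(cur, e)
    rows[[s]] <- data.frame(step = s, v1 = e[[1L]], v2 = e[[2L]],
                            is_dual_fullerene = is_dual_fullerene(cur))
    if (keep_trace) trace[[s]] <- cur
  }
  out <- list(final = cur, summary = do.call(rbind, rows))
  if (keep_trace) out$trace <- trace
  out
}
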
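#' Classify 2-facet and 3-facet vertices of a hexagonal subgraph
#'
#' A vertex of the hexagonal subgraph T6 is a 2-facet (3-facet) vertex if
#' it is a boundary vertex of two (three) distinct facets larger than a
#' triangle.  Facets are computed per connected component from the
#' inherited rotation system; larger-than-triangle facets are the holes
#' left by the removed pentagonal vertices.
#'
#' @param t6 a `subgraph_embedding` (from [subgraph6()]) or any rotation
#'   structure with fields `n_vertices`, `rotation`.
#' @return data.frame with columns `vertex`, `n_large_facets`, `label`
#'   (`none`, `two_facet`, `three_facet`).
#' @export
classify_facet_vertices <- function(t6) {
  info <- .facet_incidence(t6$rotation)
  lab <- ifelse(info$n_large == 2L, "two_facet",
                ifelse(info$n_large >= 3L, "three_facet", "none"))
  data.frame(vertex = seq_along(t6$rotation), n_large_facets = info$n_large,
             label = lab)
}

# distinct large (>3) facets incident to each vertex, plus the full
# corner->face structure used by the cut operation
.facet_incidence <- function(rot) {
  n <- length(rot)
  faces <- .trace_rotation(rot)
  sizes <- lengths(faces)
  # face id of each directed edge
  fid <- new.env(hash = TRUE, size = max(4L, 4L * n))
  for (f in seq_along(faces)) {
    w <- faces[[f]]
    l <- length(w)
    for (i in seq_len(l)) {
      a <- w[[i]]; b <- w[[if (i == l) 1L else i + 1L]]
      fid[[paste0(a, ".", b)]] <- f
    }
  }
  corner_faces <- lapply(seq_len(n), function(v) {
    r <- rot[[v]]
    if (length(r) == 0L) return(integer(0))
    vapply(seq_along(r), function(k) fid[[paste0(v, ".", r[[k]])]], integer(1))
  })
  n_large <- vapply(seq_len(n), function(v) {
    cf <- corner_faces[[v]]
    length(unique(cf[sizes[cf] > 3L]))
  }, integer(1))
  list(faces = faces, sizes = sizes, corner_faces = corner_faces,
       n_large = n_large)
}

#' Cut-partition of a hexagonal subgraph
#'
#' Decomposes T6 by (1) splitting every vertex that borders two or more
#' distinct larger-than-triangle facets, detaching a minimal fan of its
#' edges onto a fresh vertex, and (2) cutting along minimal paths between
#' degree-5 vertices whose edges border only triangles, duplicating the
#' path.  The result contains no 2-/3-facet vertices and no degree-5
#' vertices; for gSW-free fullerenes every component is conjectured to be
#' a t-triangle or a truncated triangle.
#'
#' Tie-breaks (the construction only demands minimality): the lowest
#' vertex id is split first; among minimal fans the one with
#' lexicographically smallest endpoint ids; among minimal degree-5 pairs
#' the lexicographically smallest pair and path.
#'
#' @param t6 a `subgraph_embedding` from [subgraph6()].
#' @return object of class `cut_partition`: list with `components` (list of
#'   rotation lists), `classification` (list from [recognize_component()]),
#'   `n_split_vertices`, `n_vertices_in` and `n_vertices_out`.
#' @export
cut_partition <- function(t6) {
  rot <- t6$rotation
  n_in <- length(rot)
  splits <- 0L
  repeat {
    # --- step 1: split every vertex with two or more large-facet corners
    # (sequential cuts merge the holes, so incidences are recounted by
    # corner occurrence after every split)
    repeat {
      if (length(rot) == 0L) break
      inc <- .facet_incidence(rot)
      occ <- vapply(seq_along(rot), function(v) {
        cf <- inc$corner_faces[[v]]
        sum(inc$sizes[cf] > 3L)
      }, integer(1))
      vs <- which(occ >= 2L)
      if (length(vs) == 0L) break
      res <- .split_vertex_arcs(rot, vs[[1L]], inc)
      rot <- res$rot
      splits <- splits + res$new
    }
    # --- step 2: separate degree-5 vertices along triangular paths
    deg <- lengths(rot)
    if (!any(deg == 5L)) break
    cut <- .find_deg5_cut(rot)
    if (is.null(cut))
      stop("degree-5 vertices remain but no admissible separating path exists")
    rot <- .cut_path(rot, cut$path)
    splits <- splits + length(cut$path)
  }
  comps <- unname(rotation_components(rot))
  components <- lapply(comps, function(vs) {
    idx <- integer(length(rot)); idx[vs] <- seq_along(vs)
    lapply(vs, function(v) idx[rot[[v]]])
  })
  structure(list(components = components,
                 classification = lapply(components, recognize_component),
                 n_split_vertices = splits,
                 n_vertices_in = n_in,
                 n_vertices_out = length(rot)),
            class = "cut_partition")
}

#' @export
print.cut_partition <- function(x, ...) {
  lab <- vapply(x$classification, function(cl) {
    if (cl$type == "t_triangle") paste0(cl$t, "-triangle")
    else if (cl$type == "truncated") paste0("(", cl$t, ",(",
                                            paste(cl$truncation, collapse = ","), "))-triangle")
    else "other"
  }, character(1))
  cat("cut-partition:", length(x$components), "components (",
      paste(sort(lab), collapse = ", "), ")\n")
  invisible(x)
}

# split vertex v into one vertex per fan of edges between consecutive
# large-facet corners; v keeps the fan after its first large corner
.split_vertex_arcs <- function(rot, v, inc) {
  r <- rot[[v]]
  d <- length(r)
  cf <- inc$corner_faces[[v]]
  large <- which(inc$sizes[cf] > 3L)      # corner positions at large facets
  stopifnot(length(large) >= 2L)
  # corner k sits between edges k and k+1 (cyclic), so the fan after
  # corner k1 holds edge positions k1+1 .. k2 up to the next large corner
  arcs <- list()
  for (a in seq_along(large)) {
    k1 <- large[[a]]
    k2 <- large[[if (a == length(large)) 1L else a + 1L]]
    idx <- if (k2 > k1) (k1 + 1L):k2 else c(if (k1 < d) (k1 + 1L):d, seq_len(k2))
    arcs[[a]] <- idx
  }
  rot[[v]] <- r[arcs[[1L]]]
  new <- 0L
  for (a in seq_along(arcs)[-1L]) {
    newv <- length(rot) + 1L
    rot[[newv]] <- r[arcs[[a]]]
    for (u in r[arcs[[a]]]) rot[[u]][rot[[u]] == v] <- newv
    new <- new + 1L
  }
  list(rot = rot, new = new)
}

# minimal-length path between degree-5 vertices all of whose edges border
# only triangles; deterministic tie-breaking
.find_deg5_cut <- function(rot) {
  inc <- .facet_incidence(rot)
  deg <- lengths(rot)
  v5 <- which(deg == 5L)
  if (length(v5) < 2L) return(NULL)
  # edge -> triangles-only flag
  tri_edge <- function(a, b) {
    f1 <- inc$corner_faces[[a]][[match(b, rot[[a]])]]
    f2 <- inc$corner_faces[[b]][[match(a, rot[[b]])]]
    inc$sizes[[f1]] == 3L && inc$sizes[[f2]] == 3L
  }
  best <- NULL
  for (i in seq_along(v5)) for (j in seq_along(v5)) {
    if (j <= i) next
    s <- v5[[i]]; e <- v5[[j]]
    p <- .shortest_tri_path(rot, s, e, tri_edge)
    if (is.null(p)) next
    if (is.null(best) || length(p) < length(best) ||
        (length(p) == length(best) &&
         paste(sprintf("%05d", p), collapse = "") <
         paste(sprintf("%05d", best), collapse = ""))) best <- p
  }
  if (is.null(best)) NULL else list(path = best)
}

# BFS over triangle-bordered edges; lexicographically smallest shortest path
.shortest_tri_path <- function(rot, s, e, tri_edge) {
  n <- length(rot)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier) && is.na(dist[e])) {
    nxt <- integer(0)
    for (v in frontier) for (u in rot[[v]]) {
      if (!is.na(dist[u]) || !tri_edge(v, u)) next
      dist[u] <- dist[v] + 1L
      nxt <- c(nxt, u)
    }
    frontier <- nxt
  }
  if (is.na(dist[e])) return(NULL)
  # walk back from e picking the smallest predecessor
  path <- e
  while (path[[1L]] != s) {
    v <- path[[1L]]
    pred <- sort(Filter(function(u) !is.na(dist[u]) && dist[u] == dist[v] - 1L &&
                          tri_edge(u, v), rot[[v]]))
    path <- c(pred[[1L]], path)
  }
  path
}

# duplicate a path: one side of the strip keeps the original vertices, the
# other side is reattached to fresh copies (the side containing the
# smallest vertex id off the path stays with the originals)
.cut_path <- function(rot, path) {
  l <- length(path)
  inc <- .facet_incidence(rot)
  # left/right side edges at every path vertex: the rotation is split by
  # the adjacent path edges (interior vertices) or by the path edge and
  # the unique large-facet corner (endpoints, which have degree 5)
  sides <- lapply(seq_len(l), function(i) {
    v <- path[[i]]
    r <- rot[[v]]
    d <- length(r)
    span <- function(from, to) {      # positions strictly between, cyclic
      out <- integer(0); k <- from
      repeat {
        k <- if (k == d) 1L else k + 1L
        if (k == to) break
        out <- c(out, k)
      }
      out
    }
    if (i == 1L || i == l) {
      cf <- inc$corner_faces[[v]]
      kc <- which(inc$sizes[cf] > 3L)
      if (length(kc) != 1L)
        stop("path endpoint does not border exactly one large facet")
      # linearize after the large corner (corner kc sits between edges kc
      # and kc+1)
      ord <- c(r[-seq_len(kc)], r[seq_len(kc)])
      other <- if (i == 1L) path[[2L]] else path[[l - 1L]]
      k <- match(other, ord)
      after <- if (k < d) ord[(k + 1L):d] else integer(0)
      before <- if (k > 1L) ord[seq_len(k - 1L)] else integer(0)
      if (i == 1L) list(left = after, right = before)
      else list(left = before, right = after)
    } else {
      a <- match(path[[i - 1L]], r)
      b <- match(path[[i + 1L]], r)
      list(left = r[span(b, a)], right = r[span(a, b)])
    }
  })
  # which geometric side is "A": collect the off-path components
  offpath <- setdiff(seq_along(rot), path)
  comp_id <- integer(length(rot))
  cid <- 0L
  for (sstart in offpath) {
    if (comp_id[sstart] != 0L) next
    cid <- cid + 1L
    q <- sstart; comp_id[sstart] <- cid
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (u in rot[[v]]) if (u %in% offpath && comp_id[u] == 0L) {
        comp_id[u] <- cid; q <- c(q, u)
      }
    }
  }
  sideA_comps <- unique(unlist(lapply(sides, function(sd) comp_id[sd$left])))
  sideB_comps <- unique(unlist(lapply(sides, function(sd) comp_id[sd$right])))
  sideA_comps <- setdiff(sideA_comps, 0L)
  sideB_comps <- setdiff(sideB_comps, 0L)
  # keep the side containing the smallest off-path id with the originals
  keepA <- TRUE
  if (length(offpath)) {
    small <- min(offpath)
    if (comp_id[small] %in% sideB_comps && !(comp_id[small] %in% sideA_comps))
      keepA <- FALSE
  }
  copies <- length(rot) + seq_len(l)
  for (i in seq_len(l)) {
    v <- path[[i]]
    moved <- if (keepA) sides[[i]]$right else sides[[i]]$left
    kept <- if (keepA) sides[[i]]$left else sides[[i]]$right
    prevc <- if (i > 1L) copies[[i - 1L]] else integer(0)
    nextc <- if (i < l) copies[[i + 1L]] else integer(0)
    prevo <- if (i > 1L) path[[i - 1L]] else integer(0)
    nexto <- if (i < l) path[[i + 1L]] else integer(0)
    # copy rotation: previous copy, moved fan, next copy (an open fan);
    # the original keeps its side in the cyclic order (.., prev, right,
    # next, left, ..)
    rot[[copies[[i]]]] <- if (keepA) c(prevc, moved, nextc) else c(nextc, moved, prevc)
    rot[[v]] <- if (keepA) c(prevo, nexto, kept) else c(prevo, kept, nexto)
    for (u in moved) rot[[u]][rot[[u]] == v] <- copies[[i]]
  }
  rot
}

#' Recognize a cut-partition component
#'
#' Matches a component against generated t-triangles and truncated
#' triangles of the same vertex count by graph isomorphism.
#'
#' @param comp rotation list of the component (local ids), or a
#'   `triangle_component`.
#' @return list with `type` (`"t_triangle"`, `"truncated"` or `"other"`)
#'   and, when recognized, `t` and `truncation`.
#' @export
recognize_component <- function(comp) {
  rot <- if (inherits(comp, "triangle_component")) comp$embedding$rotation else comp
  nv <- length(rot)
  if (nv == 1L) return(list(type = "t_triangle", t = 0L, truncation = c(0L, 0L, 0L)))
  adjc <- matrix(0L, nv, nv)
  for (v in seq_len(nv)) adjc[v, rot[[v]]] <- 1L
  gc <- igraph::graph_from_adjacency_matrix(adjc, mode = "undirected")
  tmax <- ceiling(sqrt(8 * nv)) + 2L
  for (t in seq_len(tmax)) {
    full <- (t + 1L) * (t + 2L) / 2L
    if (full < nv) next
    rmax <- t - 1L
    for (r1 in 0:rmax) for (r2 in 0:r1) for (r3 in 0:r2) {
      if (r1 + r2 > t - 1L || r1 + r3 > t - 1L || r2 + r3 > t - 1L) next
      if (full - (r1*(r1+1L) + r2*(r2+1L) + r3*(r3+1L)) / 2L != nv) next
      cand <- truncated_triangle(t, r1, r2, r3)
      adjt <- embedding_adjacency(cand$embedding)
      gt <- igraph::graph_from_adjacency_matrix(adjt, mode = "undirected")
      if (igraph::isomorphic(gc, gt)) {
        if (r1 == 0L) return(list(type = "t_triangle", t = t,
                                  truncation = c(0L, 0L, 0L)))
        return(list(type = "truncated", t = t, truncation = c(r1, r2, r3)))
      }
    }
  }
  list(type = "other")
}

#' Scan isomers against the cut-partition / gSW-path conjecture
#'
#' For every isomer with n <= n_max, tests whether the cut-partition of
#' the hexagonal subgraph consists solely of (possibly truncated)
#' t-triangles exactly when the dual has no gSW path, with the stated
#' exception of partitions containing only 0-triangles.
#'
#' @param n_max largest (feasible) vertex count scanned.
#' @return data.frame with one row per isomer: `n`, `j`, `has_gsw_path`,
#'   `all_triangles`, `only_zero_triangles`, `agree`.
#' @export
conjecture2_scan <- function(n_max) {
  rows <- list()
  for (n in seq(20L, as.integer(n_max), by = 2L)) {
    codes <- enumerate_isomers(n)
    if (nrow(codes) == 0L) next
    for (j in seq_len(nrow(codes))) {
      adj <- windup_adjacency(ifelse(seq_len(n/2 + 2) %in% codes[j, ], 5L, 6L))
      gsw <- .has_gsw_adj(adj)
      td <- dual_from_adjacency(adj)
      cp <- cut_partition(subgraph6(td))
      types <- vapply(cp$classification, function(cl) cl$type, character(1))
      ts <- vapply(cp$classification,
                   function(cl) if (is.null(cl[["t"]])) NA_integer_ else cl[["t"]],
                   integer(1))
      all_tri <- length(types) > 0L && all(types != "other")
      only_zero <- length(types) == 0L ||
        (all(types == "t_triangle") && all(ts == 0L))
      agree <- only_zero || (all_tri == !gsw)
      rows[[length(rows) + 1L]] <-
        data.frame(n = n, j = j, has_gsw_path = gsw, all_triangles = all_tri,
                   only_zero_triangles = only_zero, agree = agree)
    }
  }
  do.call(rbind, rows)
}
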
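#' Triangular patches (t-triangles) and their truncations
#'
#' A t-triangle is the triangular patch of the hexagonal-lattice dual with
#' t^2 small triangles: (t+1)(t+2)/2 vertices in t+1 rows, three corners of
#' degree 2, 3(t-1) side vertices of degree 4 and interior vertices of
#' degree 6.  The 0-triangle is a single vertex.  These patches are the
#' building blocks of the cut-partition analysis and of the glued family of
#' gSW-free fullerenes.
#'
#' Truncation deletes `r` rows of vertices at a corner (r(r+1)/2 vertices;
#' r = 1 removes the corner vertex alone, r = 0 nothing).  Edges between
#' vertices whose degree decreased are the open edges along which truncated
#' patches are glued.
#'
#' @param t side length, t >= 0.
#' @return an object of class `triangle_component` with fields `t`,
#'   `truncation`, `embedding`, `coords` (grid rows/columns) and
#'   `open_edges` (two-column matrix, possibly empty).
#' @export
t_triangle <- function(t) {
  truncated_triangle(t, 0L, 0L, 0L)
}

#' @rdname t_triangle
#' @param r1,r2,r3 rows deleted at the three corners; `r1 >= r2 >= r3 >= 0`
#'   and `ri + rj <= t - 1` for distinct corners.
#' @export
truncated_triangle <- function(t, r1, r2, r3) {
  t <- as.integer(t); r <- as.integer(c(r1, r2, r3))
  if (t < 0L) stop("t must be non-negative")
  if (any(r < 0L) || r[1L] < r[2L] || r[2L] < r[3L])
    stop("truncation must satisfy r1 >= r2 >= r3 >= 0")
  if (t > 0L && any(c(r[1L] + r[2L], r[1L] + r[3L], r[2L] + r[3L]) > t - 1L))
    stop("truncation too deep: ri + rj must be at most t - 1")
  if (t == 0L) {
    if (any(r > 0L)) stop("the 0-triangle cannot be truncated")
    emb <- planar_embedding(list(integer(0)))
    return(structure(list(t = 0L, truncation = c(0L, 0L, 0L), embedding = emb,
                          coords = cbind(i = 0L, j = 0L),
                          open_edges = matrix(integer(0), 0, 2)),
                     class = "triangle_component"))
  }
  g <- .tri_grid(t)
  keep <- g$dA >= r[1L] & g$dB >= r[2L] & g$dC >= r[3L]
  idx <- integer(nrow(g$coords)); idx[keep] <- seq_len(sum(keep))
  edges <- g$edges[keep[g$edges[, 1L]] & keep[g$edges[, 2L]], , drop = FALSE]
  full_deg <- tabulate(g$edges, nbins = nrow(g$coords))
  new_deg <- tabulate(edges, nbins = nrow(g$coords))
  dropped <- keep & (new_deg < full_deg)
  open <- edges[dropped[edges[, 1L]] & dropped[edges[, 2L]], , drop = FALSE]
  emb <- embedding_from_coords(cbind(idx[edges[, 1L]], idx[edges[, 2L]]),
                               g$xy[keep, , drop = FALSE])
  structure(list(t = t, truncation = r, embedding = emb,
                 coords = g$coords[keep, , drop = FALSE],
                 open_edges = cbind(idx[open[, 1L]], idx[open[, 2L]])),
            class = "triangle_component")
}

#' @export
print.triangle_component <- function(x, ...) {
  if (all(x$truncation == 0L))
    cat(x$t, "-triangle: ", x$embedding$n_vertices, " vertices\n", sep = "")
  else
    cat("(", x$t, ", (", paste(x$truncation, collapse = ","), "))-triangle: ",
        x$embedding$n_vertices, " vertices, ", nrow(x$open_edges),
        " open edges\n", sep = "")
  invisible(x)
}

# triangular grid of side t: rows i = 0..t, columns j = 0..i; corner row
# distances dA = i, dB = 2? (from the two base corners); plane coordinates
.tri_grid <- function(t) {
  coords <- do.call(rbind, lapply(0:t, function(i) cbind(i = i, j = 0:i)))
  id <- function(i, j) i * (i + 1L) / 2L + j + 1L
  edges <- list()
  for (i in 0:t) for (j in 0:i) {
    if (j < i) edges[[length(edges) + 1L]] <- c(id(i, j), id(i, j + 1L))
    if (i < t) {
      edges[[length(edges) + 1L]] <- c(id(i, j), id(i + 1L, j))
      edges[[length(edges) + 1L]] <- c(id(i, j), id(i + 1L, j + 1L))
    }
  }
  edges <- do.call(rbind, edges)
  i <- coords[, "i"]; j <- coords[, "j"]
  list(coords = coords, edges = edges,
       dA = i, dB = t - i + j, dC = t - j,
       xy = cbind(j - i / 2, -i * sqrt(3) / 2))
}

#' The glued gSW-free family
#'
#' Four (2t, (t-1, t-1, t-1))-triangles are glued pairwise along their open
#' corner paths in a tetrahedral pattern; the glued graph is the hexagonal
#' subgraph of the target dual fullerene, with four hexagonal holes whose
#' boundary degrees alternate between 4 and 5.  Inserting a triangle of
#' three pentagonal vertices into each hole yields a valid dual fullerene
#' with n = 4(t^2 + 6t + 7) on which no gSW path exists: every zigzag path
#' in the hexagonal subgraph that connects boundary vertices of two
#' hexagonal holes has even length, while a gSW path needs odd length.
#'
#' @param t integer >= 2 (t = 2 gives n = 92).
#' @param as return the `"dual"` triangulation (default) or the primal
#'   `"fullerene"`.
#' @return a `dual_triangulation` or `fullerene`.
#' @export
construction2 <- function(t, as = c("dual", "fullerene")) {
  as <- match.arg(as)
  t <- as.integer(t)
  if (t < 2L) stop("construction requires t >= 2")
  tt <- 2L * t
  g <- .tri_grid(tt)
  keep <- g$dA >= t - 1L & g$dB >= t - 1L & g$dC >= t - 1L
  loc <- integer(nrow(g$coords)); loc[keep] <- seq_len(sum(keep))
  np <- sum(keep)                       # vertices per piece
  edges <- g$edges[keep[g$edges[, 1L]] & keep[g$edges[, 2L]], , drop = FALSE]
  edges <- cbind(loc[edges[, 1L]], loc[edges[, 2L]])
  i <- g$coords[keep, "i"]; j <- g$coords[keep, "j"]
  # corner paths in counterclockwise boundary order
  ids_of <- function(ii, jj) loc[ii * (ii + 1L) / 2L + jj + 1L]
  pathA <- ids_of(rep(t - 1L, t), (t - 1L):0L)            # diagonal -> AB side
  pathB <- ids_of(t + 1L + 0:(t - 1L), 0:(t - 1L))        # AB -> BC side
  pathC <- ids_of(tt:(t + 1L), rep(t + 1L, t))            # BC -> CA side
  mids <- c(AB = ids_of(t, 0L), BC = ids_of(tt, t), CA = ids_of(t, t))
  paths <- list(A = pathA, B = pathB, C = pathC)
  # tetrahedron: faces as vertex triples; piece corners A,B,C correspond to
  # the face's vertices; tetra edge {x,y} glues, in both incident faces,
  # the corners opposite to it
  faces <- list(c(1L, 2L, 3L), c(2L, 1L, 4L), c(3L, 4L, 1L), c(4L, 3L, 2L))
  gid <- function(piece, v) (piece - 1L) * np + v
  parent <- seq_len(4L * np)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  tetra_edges <- combn(4L, 2L)
  for (e in seq_len(ncol(tetra_edges))) {
    xy <- tetra_edges[, e]
    inc <- which(vapply(faces, function(f) all(xy %in% f), logical(1)))
    p1 <- inc[[1L]]; p2 <- inc[[2L]]
    c1 <- which(!(faces[[p1]] %in% xy))   # corner opposite the tetra edge
    c2 <- which(!(faces[[p2]] %in% xy))
    pa <- paths[[c1]]; pb <- paths[[c2]]
    for (k in seq_len(t)) unite(gid(p1, pa[[k]]), gid(p2, pb[[t + 1L - k]]))
  }
  canon <- vapply(seq_len(4L * np), find, integer(1))
  relab <- match(canon, sort(unique(canon)))
  nglued <- max(relab)
  adj <- matrix(0L, nglued + 12L, nglued + 12L)
  for (p in 1:4) for (r in seq_len(nrow(edges))) {
    a <- relab[gid(p, edges[r, 1L])]; b <- relab[gid(p, edges[r, 2L])]
    adj[a, b] <- adj[b, a] <- 1L
  }
  # hexagonal holes: cycles of the side edges (path end - side middle)
  side_edges <- do.call(rbind, lapply(1:4, function(p) rbind(
    c(relab[gid(p, pathA[[t]])], relab[gid(p, mids[["AB"]])]),
    c(relab[gid(p, mids[["AB"]])], relab[gid(p, pathB[[1L]])]),
    c(relab[gid(p, pathB[[t]])], relab[gid(p, mids[["BC"]])]),
    c(relab[gid(p, mids[["BC"]])], relab[gid(p, pathC[[1L]])]),
    c(relab[gid(p, pathC[[t]])], relab[gid(p, mids[["CA"]])]),
    c(relab[gid(p, mids[["CA"]])], relab[gid(p, pathA[[1L]])]))))
  holes <- .edge_cycles(side_edges)
  if (length(holes) != 4L || any(lengths(holes) != 6L))
    stop("internal error: gluing did not produce four hexagonal holes")
  nxt <- nglued
  degs <- rowSums(adj)
  for (h in holes) {
    # rotate so that positions 1, 3, 5 are the degree-4 side middles
    if (degs[h[[1L]]] != 4L) h <- c(h[-1L], h[[1L]])
    if (any(degs[h[c(1L, 3L, 5L)]] != 4L) || any(degs[h[c(2L, 4L, 6L)]] != 5L))
      stop("internal error: hole boundary degrees do not alternate 4/5")
    x <- nxt + 1:3; nxt <- nxt + 3L
    adj[x[1L], x[2L]] <- adj[x[2L], x[1L]] <- 1L
    adj[x[2L], x[3L]] <- adj[x[3L], x[2L]] <- 1L
    adj[x[3L], x[1L]] <- adj[x[1L], x[3L]] <- 1L
    link <- list(h[c(1L, 2L, 3L)], h[c(3L, 4L, 5L)], h[c(5L, 6L, 1L)])
    for (k in 1:3) for (u in link[[k]]) adj[x[[k]], u] <- adj[u, x[[k]]] <- 1L
  }
  td <- dual_from_adjacency(adj)
  if (as == "dual") td else dualize_inverse(td)
}

# split an edge list that forms disjoint cycles into ordered cycles
.edge_cycles <- function(edges) {
  edges <- unique(t(apply(edges, 1L, sort)))
  verts <- sort(unique(as.vector(edges)))
  nb <- lapply(verts, function(v) {
    w <- c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L])
    unique(w)
  })
  names(nb) <- as.character(verts)
  seen <- character(0)
  cycles <- list()
  for (v in verts) {
    if (as.character(v) %in% seen) next
    cyc <- v; prev <- NA_integer_
    repeat {
      cur <- cyc[[length(cyc)]]
      cand <- setdiff(nb[[as.character(cur)]], prev)
      nxt <- cand[[1L]]
      if (nxt == cyc[[1L]]) break
      prev <- cur
      cyc <- c(cyc, nxt)
    }
    seen <- c(seen, as.character(cyc))
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Seed fullerenes of every size by boundary-preserving growth
#'
#' Starting from the first isomer of C36, a cut along six boundary vertices
#' with degree-deficit labels (1,2,2,2,2,3) separates the dual into two
#' components.  Adding one vertex to the larger component (joined to the
#' vertex labeled 1 and to its neighbours labeled 2 and 3) reproduces the
#' same label vector, so the step can be iterated; re-attaching the smaller
#' component after n/2 - 18 iterations yields a C_n isomer for any feasible
#' n >= 36.
#'
#' @param n even integer >= 36.
#' @param as `"fullerene"` (default) or `"dual"`.
#' @return a `fullerene` or `dual_triangulation` with n vertices.
#' @export
construction3 <- function(n, as = c("fullerene", "dual")) {
  as <- match.arg(as)
  n <- as.integer(n)
  if (n < 36L || n %% 2L != 0L) stop("construction requires even n >= 36")
  seed <- isomer_by_index(36L, 1L, as = "dual")
  adj <- embedding_adjacency(seed$embedding)
  cut <- .find_labeled_cut(adj)
  if (is.null(cut)) stop("internal error: no (1,2,2,2,2,3) cut in the seed")
  k <- n %/% 2L - 18L
  m0 <- nrow(adj)
  madj <- matrix(0L, m0 + k, m0 + k)
  madj[seq_len(m0), seq_len(m0)] <- adj
  # detach the smaller component
  for (r in seq_len(nrow(cut$cut_edges))) {
    a <- cut$cut_edges[r, 1L]; b <- cut$cut_edges[r, 2L]
    madj[a, b] <- madj[b, a] <- 0L
  }
  cyc <- cut$cycle          # ordered: labels (1,2,2,2,2,3)
  for (s in seq_len(k)) {
    u <- m0 + s
    for (v in cyc[c(1L, 2L, 6L)]) madj[u, v] <- madj[v, u] <- 1L
    cyc <- c(cyc[2:6], u)
  }
  # re-attach: boundary position i of the original cycle maps to position i
  for (r in seq_len(nrow(cut$cut_edges))) {
    a <- cut$cut_edges[r, 1L]; b <- cut$cut_edges[r, 2L]
    onb <- a %in% cut$cycle0
    bv <- if (onb) a else b
    sv <- if (onb) b else a
    pos <- match(bv, cut$cycle0)
    madj[cyc[[pos]], sv] <- madj[sv, cyc[[pos]]] <- 1L
  }
  td <- dual_from_adjacency(madj)
  if (as == "dual") td else dualize_inverse(td)
}

# find a 6-cycle and a smaller side S such that removing the edges between
# the cycle-complement side and the rest gives boundary degree deficits
# (1,2,2,2,2,3) in cyclic order on the larger component
.find_labeled_cut <- function(adj) {
  m <- nrow(adj)
  nb <- lapply(seq_len(m), function(v) which(adj[v, ] != 0L))
  target <- c(1L, 2L, 2L, 2L, 2L, 3L)
  # enumerate 6-cycles: start at the smallest vertex of the cycle
  res <- NULL
  for (s in seq_len(m)) {
    if (!is.null(res)) break
    dfs <- function(path) {
      if (!is.null(res)) return()
      l <- length(path)
      if (l == 6L) {
        if (adj[path[[6L]], s] == 1L) res <<- .check_cut(adj, nb, path)
        return()
      }
      for (u in nb[[path[[l]]]]) {
        if (u <= s || u %in% path) next
        if (l == 5L && adj[u, s] == 0L) next
        dfs(c(path, u))
        if (!is.null(res)) return()
      }
    }
    dfs(s)
  }
  res
}

.check_cut <- function(adj, nb, cyc) {
  m <- nrow(adj)
  target <- c(1L, 2L, 2L, 2L, 2L, 3L)
  rest <- setdiff(seq_len(m), cyc)
  sub <- adj[rest, rest, drop = FALSE]
  comp <- rep(0L, length(rest))
  cid <- 0L
  for (ss in seq_along(rest)) {
    if (comp[ss] != 0L) next
    cid <- cid + 1L
    q <- ss; comp[ss] <- cid
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (u in which(sub[v, ] != 0L)) if (comp[u] == 0L) { comp[u] <- cid; q <- c(q, u) }
    }
  }
  for (K in seq_len(cid)) {
    Sv <- rest[comp == K]
    if (length(Sv) >= m - 6L - length(Sv)) next    # S must be the smaller side
    # labels: degree deficits of cycle vertices inside L = everything but S
    defic <- vapply(cyc, function(v) sum(adj[v, Sv]), integer(1))
    if (sum(defic) == 0L) next
    lab <- 6L - (vapply(cyc, function(v) length(nb[[v]]), integer(1)) - defic)
    for (dir in list(cyc, rev(cyc))) {
      labd <- 6L - (vapply(dir, function(v) length(nb[[v]]) - sum(adj[v, Sv]), integer(1)))
      for (rot in 0:5) {
        rc <- c(dir[-seq_len(rot)], dir[seq_len(rot)])
        rl <- c(labd[-seq_len(rot)], labd[seq_len(rot)])
        if (identical(rl, target)) {
          ce <- do.call(rbind, lapply(rc, function(v) {
            w <- intersect(which(adj[v, ] != 0L), Sv)
            if (length(w)) cbind(v, w) else NULL
          }))
          return(list(cycle = rc, cycle0 = rc, labels = rl,
                      S = Sv, cut_edges = ce))
        }
      }
    }
  }
  NULL
}

#' (5,0)-nanotube fullerenes
#'
#' Tubular fullerenes for n = 20 + 10r: two caps of six degree-5 dual
#' vertices (an apex and its five-ring) separated by r five-vertex belts of
#' degree-6 vertices, rings joined in antiprism fashion.  Within C_n these
#' attain the largest spectral character (narrow tubes support the most
#' closed walks).
#'
#' @param n vertex count, n = 20 + 10r.
#' @param as `"fullerene"` (default) or `"dual"`.
#' @return a `fullerene` or `dual_triangulation`.
#' @export
nanotube_5_0 <- function(n, as = c("fullerene", "dual")) {
  as <- match.arg(as)
  n <- as.integer(n)
  if (n < 20L || n %% 10L != 0L) stop("a (5,0)-nanotube requires n = 20 + 10r")
  r <- (n - 20L) %/% 10L
  nrings <- r + 2L
  m <- 5L * nrings + 2L
  adj <- matrix(0L, m, m)
  ring <- function(k) 1L + (k - 1L) * 5L + 1:5   # k = 1..nrings
  a1 <- 1L; a2 <- m
  link <- function(a, b) adj[a, b] <<- adj[b, a] <<- 1L
  for (v in ring(1L)) link(a1, v)
  for (v in ring(nrings)) link(a2, v)
  for (k in seq_len(nrings)) {
    rk <- ring(k)
    for (i in 1:5) link(rk[[i]], rk[[i %% 5L + 1L]])
    if (k < nrings) {
      rn <- ring(k + 1L)
      for (i in 1:5) { link(rk[[i]], rn[[i]]); link(rk[[i]], rn[[i %% 5L + 1L]]) }
    }
  }
  td <- dual_from_adjacency(adj)
  if (as == "dual") td else dualize_inverse(td)
}

#' Goldberg polyhedra
#'
#' Icosahedrally symmetric fullerenes with n = 20((p+q)^2 - pq), built as
#' the (p,q) Goldberg-Coxeter subdivision of the icosahedron: each
#' icosahedral face carries a patch of the Eisenstein lattice spanned by
#' z = p + q*zeta (zeta = exp(i*pi/3)), and patches are glued exactly
#' (integer lattice arithmetic) along shared sides.  Goldberg duals attain
#' the smallest spectral character within their isomer set and are IPR for
#' n > 20.
#'
#' @param p,q chirality integers, p >= q >= 0, p >= 1.
#' @param as `"fullerene"` (default) or `"dual"`.
#' @return a `fullerene` or `dual_triangulation` with
#'   n = 20((p+q)^2 - pq) vertices.
#' @export
goldberg <- function(p, q, as = c("fullerene", "dual")) {
  as <- match.arg(as)
  p <- as.integer(p); q <- as.integer(q)
  if (p < 1L || q < 0L || q > p) stop("require p >= q >= 0 and p >= 1")
  Tn <- (p + q)^2 - p * q
  ico <- windup(spiral_code(20L, 1:12), as = "dual")
  # oriented triangles of the icosahedron = faces of its embedding
  ico_faces <- trace_faces(ico$embedding)
  stopifnot(length(ico_faces) == 20L)

  # Eisenstein integers as c(a, b) = a + b*zeta, zeta^2 = zeta - 1
  emul <- function(u, v) c(u[1]*v[1] - u[2]*v[2], u[1]*v[2] + u[2]*v[1] + u[2]*v[2])
  esub <- function(u, v) u - v
  eadd <- function(u, v) u + v
  enorm <- function(u) u[1]^2 + u[1]*u[2] + u[2]^2
  ediv <- function(u, v) {  # exact division u/v
    nv <- enorm(v)
    conj <- c(v[1] + v[2], -v[2])   # conjugate: a+b*zeta -> (a+b) - b*zeta
    w <- emul(u, conj)
    if (any(w %% nv != 0)) stop("non-exact Eisenstein division")
    w %/% nv
  }
  zeta <- c(0L, 1L)
  z <- c(p, q)
  corner_chart <- list(c(0L, 0L), z, emul(z, zeta))

  # chart membership: closed triangle (0, z, z*zeta) in doubled coordinates
  X <- function(u) 2 * u[1] + u[2]
  Y <- function(u) u[2]
  cross <- function(a, b, pnt)
    (X(b) - X(a)) * (Y(pnt) - Y(a)) - (Y(b) - Y(a)) * (X(pnt) - X(a))
  inside <- function(u) {
    cr <- c(cross(corner_chart[[1]], corner_chart[[2]], u),
            cross(corner_chart[[2]], corner_chart[[3]], u),
            cross(corner_chart[[3]], corner_chart[[1]], u))
    all(cr >= 0)
  }
  # lattice points of one chart
  pts <- list()
  for (i in (-q - 1L):(p + 1L)) for (j in (-1L):(p + q + 1L)) {
    u <- c(i, j)
    if (inside(u)) pts[[length(pts) + 1L]] <- u
  }
  # per-face corner vertex ids (in icosahedron) in walk order
  fcorner <- ico_faces
  # transition: map from chart of face f to chart of face fp across side s
  # (side s joins corners s and s%%3+1 of f)
  face_with_edge <- function(a, b) {
    for (ff in seq_len(20L)) {
      w <- fcorner[[ff]]
      for (k in 1:3) if (w[[k]] == a && w[[k %% 3L + 1L]] == b) return(ff)
    }
    stop("icosahedron face not found")
  }
  chart_of <- function(f, icov) corner_chart[[match(icov, fcorner[[f]])]]
  transition <- function(f, fp, va, vb) {
    # Eisenstein-affine map w -> mu*w + tau with chart_f(v) -> chart_fp(v)
    d1 <- esub(chart_of(fp, va), chart_of(fp, vb))
    d2 <- esub(chart_of(f, va), chart_of(f, vb))
    mu <- ediv(d1, d2)
    tau <- esub(chart_of(fp, va), emul(mu, chart_of(f, va)))
    list(mu = mu, tau = tau, fp = fp)
  }
  trans <- vector("list", 20L)
  for (f in seq_len(20L)) {
    w <- fcorner[[f]]
    trans[[f]] <- lapply(1:3, function(s) {
      a <- w[[s]]; b <- w[[s %% 3L + 1L]]
      transition(f, face_with_edge(b, a), a, b)
    })
  }
  key <- function(f, u) paste0(f, ":", u[1], ":", u[2])
  # union-find over chart points
  parent <- new.env(parent = emptyenv())
  uf_find <- function(k) {
    while (!is.null(parent[[k]]) && parent[[k]] != k) k <- parent[[k]]
    k
  }
  uf_unite <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    parent[[ra]] <- rb
    if (is.null(parent[[rb]])) parent[[rb]] <- rb
  }
  for (f in seq_len(20L)) for (u in pts) {
    k <- key(f, u)
    if (is.null(parent[[k]])) parent[[k]] <- k
  }
  # identify boundary points across sides
  on_side <- function(u, s) cross(corner_chart[[s]], corner_chart[[s %% 3L + 1L]], u) == 0
  for (f in seq_len(20L)) for (u in pts) {
    for (s in 1:3) if (on_side(u, s)) {
      tr <- trans[[f]][[s]]
      up <- eadd(emul(tr$mu, u), tr$tau)
      uf_unite(key(f, u), key(tr$fp, up))
    }
  }
  # resolve a neighbouring lattice point into some chart containing it
  dirs <- list(c(1L,0L), c(-1L,0L), c(0L,1L), c(0L,-1L), c(1L,-1L), c(-1L,1L))
  resolve <- function(f, u) {
    for (guard in 1:12) {
      if (inside(u)) return(list(f = f, u = u))
      moved <- FALSE
      for (s in 1:3) {
        if (cross(corner_chart[[s]], corner_chart[[s %% 3L + 1L]], u) < 0) {
          tr <- trans[[f]][[s]]
          u <- eadd(emul(tr$mu, u), tr$tau)
          f <- tr$fp
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
    stop("could not resolve lattice point into a chart")
  }
  # canonical ids
  allkeys <- unique(vapply(ls(parent), uf_find, character(1)))
  cid <- setNames(seq_along(allkeys), allkeys)
  id_of <- function(f, u) cid[[uf_find(key(f, u))]]
  nver <- length(allkeys)
  adj <- matrix(0L, nver, nver)
  for (f in seq_len(20L)) for (u in pts) {
    a <- id_of(f, u)
    for (d in dirs) {
      v <- u + d
      r <- if (inside(v)) list(f = f, u = v) else resolve(f, v)
      b <- id_of(r$f, r$u)
      if (a != b) adj[a, b] <- adj[b, a] <- 1L
    }
  }
  if (nver != 10L * Tn + 2L)
    stop("internal error: Goldberg subdivision produced ", nver,
         " vertices, expected ", 10L * Tn + 2L)
  td <- dual_from_adjacency(adj)
  if (as == "dual") td else dualize_inverse(td)
}

#' Dual of the k-gonal prism (bipyramid-like seed triangulation)
#'
#' The dual of the (m-2)-gonal prism: two apices of degree m - 2 joined to
#' every vertex of an (m-2)-ring of degree-4 vertices.  It has the vertex,
#' edge and face counts of a dual fullerene on the same m and serves as the
#' classic seed of polyhedral Stone-Wales random walks.
#'
#' @param m vertex count, m >= 5.
#' @return a `triangulation`.
#' @export
bipyramid_seed <- function(m) {
  m <- as.integer(m)
  if (m < 5L) stop("seed requires m >= 5")
  k <- m - 2L
  rot <- vector("list", m)
  a1 <- k + 1L; a2 <- k + 2L
  for (i in seq_len(k)) {
    prv <- if (i == 1L) k else i - 1L
    nxt <- if (i == k) 1L else i + 1L
    rot[[i]] <- c(prv, a1, nxt, a2)
  }
  rot[[a1]] <- rev(seq_len(k))
  rot[[a2]] <- seq_len(k)
  triangulation(planar_embedding(rot))
}
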
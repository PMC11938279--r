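# Shared fixtures and small independent oracles.  Enumerations are cached
# inside the package, so repeated calls across test files are cheap.

dodeca_dual <- function() windup(spiral_code(20, 1:12), as = "dual")

# icosahedron rotation system derived from the classical coordinates
# (cyclic permutations of (0, +-1, +-phi)), independent of the windup
# machinery: neighbours are the five nearest vertices, ordered by angle in
# the tangent plane at each vertex
icosa_rotation_handmade <- function() {
  phi <- (1 + sqrt(5)) / 2
  xyz <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  d2 <- as.matrix(dist(xyz))^2
  lapply(1:12, function(v) {
    nb <- which(abs(d2[v, ] - 4) < 1e-9)      # edge length 2
    p <- xyz[v, ] / sqrt(sum(xyz[v, ]^2))
    ref <- if (abs(p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * p) * p
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(p[2] * e1[3] - p[3] * e1[2],
            p[3] * e1[1] - p[1] * e1[3],
            p[1] * e1[2] - p[2] * e1[1])
    ang <- vapply(nb, function(u) {
      w <- xyz[u, ] - xyz[v, ]
      atan2(sum(w * e2), sum(w * e1))
    }, numeric(1))
    nb[order(ang)]
  })
}

# apply a random vertex relabelling to a dual triangulation
relabel_dual <- function(td, seed) {
  set.seed(seed)
  m <- td$m
  perm <- sample.int(m)
  adj <- embedding_adjacency(td$embedding)
  adj2 <- matrix(0L, m, m)
  adj2[perm, perm] <- adj
  dual_from_adjacency(adj2)
}

# naive isomer enumeration oracle: scan all 12-subsets of the face count,
# wind up, deduplicate by canonical code
enumerate_oracle <- function(n) {
  m <- n / 2 + 2
  subsets <- combn(m, 12)
  seen <- character(0)
  out <- list()
  for (k in seq_len(ncol(subsets))) {
    pos <- subsets[, k]
    f <- windup(spiral_code(n, pos), as = "dual")
    if (is_spiral_rejection(f)) next
    can <- unwind_canonical(f)$positions
    key <- paste(can, collapse = " ")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- can
    }
  }
  do.call(rbind, out[order(vapply(out, function(p)
    paste(sprintf("%03d", p), collapse = ""), character(1)))])
}

# brute-force gSW path enumeration up to a given even length: recursive
# scan over all vertex sequences, checking the Definition conditions as the
# sequence grows (pure condition checking, no zigzag-specific search order)
gsw_oracle <- function(td, max_len) {
  adj <- embedding_adjacency(td$embedding)
  deg <- embedding_degrees(td$embedding)
  m <- td$m
  out <- list()
  grow <- function(p) {
    l <- length(p)
    if (l >= 4 && l %% 2 == 0 && deg[p[1]] == 5 && deg[p[2]] == 6 &&
        deg[p[l - 1]] == 6 && deg[p[l]] == 5)
      out[[length(out) + 1L]] <<- p
    if (l >= max_len) return()
    for (u in seq_len(m)) {
      if (u %in% p) next
      if (adj[p[l], u] == 0) next
      if (l >= 2 && adj[p[l - 1], u] == 0) next
      grow(c(p, u))
    }
  }
  for (v in which(deg == 5)) grow(v)
  out
}

# brute-force gSW path enumeration restricted to length 4 (w = 2):
# all ordered vertex 4-tuples checked against the zigzag conditions
gsw_w2_oracle <- function(td) {
  adj <- embedding_adjacency(td$embedding)
  deg <- embedding_degrees(td$embedding)
  m <- td$m
  out <- list()
  for (v1 in seq_len(m)) for (v2 in seq_len(m)) for (v3 in seq_len(m))
    for (v4 in seq_len(m)) {
      p <- c(v1, v2, v3, v4)
      if (anyDuplicated(p)) next
      if (deg[v1] != 5 || deg[v4] != 5 || deg[v2] != 6 || deg[v3] != 6) next
      if (adj[v1, v2] == 0 || adj[v2, v3] == 0 || adj[v3, v4] == 0) next
      if (adj[v1, v3] == 0 || adj[v2, v4] == 0) next
      out[[length(out) + 1L]] <- p
    }
  out
}

# integer partition enumeration oracle (lists all partitions of k)
partitions_oracle <- function(k, maxpart = k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(k, maxpart))) {
    for (rest in partitions_oracle(k - p, p))
      out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

same_dual_graph <- function(a, b) {
  identical(unwind_canonical(a)$positions, unwind_canonical(b)$positions)
}
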
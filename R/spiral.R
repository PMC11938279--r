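#' Face-spiral codes
#'
#' A face spiral lists all n/2 + 2 faces of a fullerene so that each face
#' touches its predecessor and the earliest still-open face ("peeling like
#' an orange").  The code records the face sizes, equivalently the twelve
#' 1-based positions of the pentagons.  The canonical code of an isomer is
#' the lexicographically smallest size sequence over all starts and winding
#' directions, and is a complete isomorphism invariant on the spiralable
#' range (every fullerene below 380 vertices winds up from a spiral).
#'
#' @param n fullerene vertex count.
#' @param positions strictly increasing integer vector of the 12 pentagon
#'   positions, each in `1..(n/2 + 2)`.
#' @return an object of class `spiral_code` (fields `n`, `positions`,
#'   `sizes`).
#' @examples
#' spiral_code(20, 1:12)  # the dodecahedron: twelve pentagons, no hexagon
#' @export
spiral_code <- function(n, positions) {
  n <- as.integer(n)
  positions <- as.integer(positions)
  m <- n %/% 2L + 2L
  if (n %% 2L != 0L || n < 20L) stop("infeasible vertex count n = ", n)
  if (length(positions) != 12L) stop("a spiral code has exactly 12 pentagon positions")
  if (any(diff(positions) <= 0L)) stop("pentagon positions must be strictly increasing")
  if (positions[[1L]] < 1L || positions[[12L]] > m)
    stop("pentagon positions must lie in 1..", m)
  sizes <- rep(6L, m)
  sizes[positions] <- 5L
  structure(list(n = n, positions = positions, sizes = sizes),
            class = "spiral_code")
}

#' @export
print.spiral_code <- function(x, ...) {
  cat(x$n, ": ", paste(x$positions, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
format.spiral_code <- function(x, ...) {
  paste0(x$n, ": ", paste(x$positions, collapse = " "))
}

#' Is an object a spiral rejection?
#'
#' `windup` returns a rejection object (not an error) when a well-formed
#' code cannot close into a triangulation of the sphere.
#'
#' @param x any object.
#' @return logical.
#' @export
is_spiral_rejection <- function(x) inherits(x, "spiral_rejection")

#' Wind a face-spiral code up into a fullerene
#'
#' Faces are laid down in spiral order; each new face attaches to the
#' previous face and to the earliest open face, and the boundary rolls up
#' over saturated faces.  Codes that cannot close return a
#' `spiral_rejection` object rather than an error.
#'
#' @param code a `spiral_code`.
#' @param as return the primal `"fullerene"` (default) or its
#'   `"dual"` triangulation.
#' @return a `fullerene`, a `dual_triangulation`, or a `spiral_rejection`.
#' @export
windup <- function(code, as = c("fullerene", "dual")) {
  stopifnot(inherits(code, "spiral_code"))
  as <- match.arg(as)
  res <- .windup_cpp(code$sizes)
  if (!res$ok)
    return(structure(list(code = code, reason = "spiral does not close"),
                     class = "spiral_rejection"))
  m <- length(code$sizes)
  adj <- matrix(0L, m, m)
  for (v in seq_len(m)) adj[v, res$neighbors[[v]]] <- 1L
  t <- dual_from_adjacency(adj)
  if (as == "dual") t else dualize_inverse(t)
}

# in-session cache of full enumerations (deterministic, often reused)
.enum_cache <- new.env(parent = emptyenv())

# adjacency-only windup used by bulk scans (no embedding reconstruction)
windup_adjacency <- function(sizes) {
  res <- .windup_cpp(as.integer(sizes))
  if (!res$ok) return(NULL)
  m <- length(sizes)
  adj <- matrix(0L, m, m)
  for (v in seq_len(m)) adj[v, res$neighbors[[v]]] <- 1L
  adj
}

#' Canonical face-spiral code of a fullerene
#'
#' Searches all spiral starts (every start face, every adjacent second
#' face, both winding directions) and returns the lexicographically
#' smallest successful size sequence.  The result is deterministic and
#' identical for isomorphic inputs.
#'
#' @param f a `fullerene` or `dual_triangulation`.
#' @return a `spiral_code`.
#' @export
unwind_canonical <- function(f) {
  t <- if (inherits(f, "fullerene")) dualize(f) else f
  stopifnot(inherits(t, "dual_triangulation"))
  adj <- embedding_adjacency(t$embedding)
  deg <- embedding_degrees(t$embedding)
  sizes <- .canonical_spiral_cpp(adj, deg)
  if (length(sizes) == 0L)
    stop("no face spiral exists for this fullerene (unspiralable input)")
  spiral_code(2L * (t$m - 2L), which(sizes == 5L))
}

#' Enumerate fullerene isomers by canonical spiral
#'
#' Backtracks over partial spirals with early closure pruning, emitting one
#' canonical pentagon-position vector per isomorphism class, in ascending
#' lexicographic order.  A sequence is emitted only if it equals the
#' canonical code of the fullerene it winds up into.
#'
#' @param n feasible even vertex count (n = 22 gives zero isomers).
#' @param limit emit at most this many codes (0 = all).
#' @param reverse descending lexicographic order instead (the first row is
#'   then the lexicographically largest isomer, e.g. the isolated-pentagon
#'   buckminsterfullerene for n = 60).
#' @return integer matrix, one row per isomer, 12 pentagon positions per
#'   row; attribute `n` carries the vertex count.
#' @export
enumerate_isomers <- function(n, limit = 0L, reverse = FALSE) {
  n <- as.integer(n)
  if (n %% 2L != 0L || n < 20L) stop("infeasible vertex count n = ", n)
  key <- as.character(n)
  if (!reverse) {
    cached <- .enum_cache[[key]]
    if (!is.null(cached) && (limit == 0L || nrow(cached) >= limit)) {
      codes <- if (limit > 0L) cached[seq_len(min(limit, nrow(cached))), , drop = FALSE] else cached
      attr(codes, "n") <- n
      return(codes)
    }
  }
  codes <- .enumerate_spirals_cpp(n, as.integer(limit), reverse)
  if (!reverse && limit == 0L) .enum_cache[[key]] <- codes
  attr(codes, "n") <- n
  codes
}

#' Number of isomers of C_n
#'
#' @param n feasible even vertex count.
#' @return integer count (0 for n = 22).
#' @export
iso_count <- function(n) nrow(enumerate_isomers(n))

#' Retrieve the j-th isomer in lexicographic order
#'
#' `C_{n,j}` denotes the j-th isomer of C_n when canonical pentagon
#' position vectors are sorted ascending.
#'
#' @param n feasible even vertex count.
#' @param j 1-based lexicographic rank.
#' @param as `"fullerene"` or `"dual"`.
#' @return a `fullerene` (or `dual_triangulation`).
#' @export
isomer_by_index <- function(n, j, as = c("fullerene", "dual")) {
  as <- match.arg(as)
  j <- as.integer(j)
  codes <- enumerate_isomers(n, limit = j)
  if (nrow(codes) < j)
    stop("C_", n, " has fewer than ", j, " isomers")
  windup(spiral_code(n, codes[j, ]), as = as)
}

#' Unrank / rank 12-subsets in lexicographic order
#'
#' Bijection between `1..choose(len, 12)` and ascending 12-subsets of
#' `{1..len}`; used to draw uniform pentagon-position vectors.  `len` is
#' the face count n/2 + 2 under the package's default dialect, or n under
#' the length-n dialect.
#'
#' @param N rank, `1 <= N <= choose(len, 12)` (numeric; exact up to 2^53).
#' @param len size of the ground set.
#' @return `unrank_pentagon_vector`: increasing integer vector of length
#'   12; `rank_pentagon_vector`: the numeric rank.
#' @export
unrank_pentagon_vector <- function(N, len) {
  stopifnot(length(N) == 1L, N >= 1, N <= choose(len, 12))
  r <- N
  x <- 1L
  out <- integer(12L)
  for (k in seq_len(12L)) {
    repeat {
      cnt <- choose(len - x, 12L - k)
      if (r <= cnt) { out[[k]] <- x; x <- x + 1L; break }
      r <- r - cnt
      x <- x + 1L
    }
  }
  out
}

#' @rdname unrank_pentagon_vector
#' @param positions increasing integer vector of length 12.
#' @export
rank_pentagon_vector <- function(positions, len) {
  stopifnot(length(positions) == 12L, all(diff(positions) > 0))
  r <- 1
  prev <- 0L
  for (k in seq_len(12L)) {
    x <- positions[[k]]
    if (x > prev + 1L)
      for (y in (prev + 1L):(x - 1L)) r <- r + choose(len - y, 12L - k)
    prev <- x
  }
  r
}

#' Acceptance-rejection sampling of uniform random fullerenes
#'
#' Draws pentagon-position vectors uniformly, winds each up, and accepts
#' only when the vector equals the canonical code of the decoded fullerene.
#' Since each isomer owns exactly one canonical code, accepted draws are
#' uniform over the isomers of C_n.  Under the length-n dialect the ground
#' set is `{1..n}` instead of the face count, which lowers the acceptance
#' rate (about 1812/choose(60,12), i.e. 1e-9, at n = 60) without changing
#' the output law.
#'
#' @param n feasible even vertex count.
#' @param rng_seed integer seed (mandatory for reproducibility).
#' @param n_accept number of accepted isomers to return.
#' @param max_trials cap on the total number of draws; the sampler stops
#'   early (with fewer accepts) when it is hit.
#' @param dialect `"faces"` (ground set 1..n/2+2, default) or `"n"`.
#' @return list with `codes` (integer matrix of accepted canonical codes,
#'   one row each), `fullerene` (the first accepted isomer, or NULL),
#'   `trials` (total draws) and `trials_per_accept`.
#' @export
sample_rejection <- function(n, rng_seed, n_accept = 1L,
                             max_trials = 1e8, dialect = c("faces", "n")) {
  dialect <- match.arg(dialect)
  n <- as.integer(n)
  m <- n %/% 2L + 2L
  len <- if (dialect == "faces") m else n
  set.seed(as.integer(rng_seed))
  res <- .sample_rejection_cpp(n, as.integer(n_accept), max_trials, len)
  f <- NULL
  if (nrow(res$codes) >= 1L)
    f <- windup(spiral_code(n, res$codes[1L, ]))
  list(codes = res$codes, fullerene = f, trials = res$trials,
       trials_per_accept = res$trials_per_accept)
}
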
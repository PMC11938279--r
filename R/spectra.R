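#' Character parameters
#'
#' The (alpha, beta)-character of a graph is the trace of the matrix
#' exponential of alpha*A + beta*D (adjacency and degree matrices),
#' equivalently the sum of exp(alpha * lambda_j) over the eigenvalues of
#' A + (beta/alpha) D.  The package default (1/2, 1/4) follows the choice
#' alpha = 2*beta = 1/2 recommended for dual fullerene graphs, for which
#' the normalized closed-walk counts of A + D/2 have a hexagonal-lattice
#' limit; for primal fullerene graphs the natural choice is (1, 0).
#'
#' @param alpha,beta positive reals (alpha > 0).
#' @return object of class `character_params`.
#' @export
character_params <- function(alpha = 0.5, beta = 0.25) {
  stopifnot(alpha > 0, is.finite(beta / alpha))
  structure(list(alpha = alpha, beta = beta), class = "character_params")
}

# adjacency of any supported graph argument
.graph_adjacency <- function(g) {
  if (is.matrix(g)) return(g)
  if (inherits(g, c("dual_triangulation", "triangulation", "fullerene")))
    return(embedding_adjacency(g$embedding))
  if (inherits(g, c("planar_embedding", "subgraph_embedding"))) {
    n <- g$n_vertices
    a <- matrix(0L, n, n)
    for (v in seq_len(n)) a[v, g$rotation[[v]]] <- 1L
    return(a)
  }
  stop("unsupported graph argument")
}

#' Newton polynomial (power sum of eigenvalues)
#'
#' N(M, k) = sum of the k-th powers of the eigenvalues of M, i.e. the
#' trace of M^k.  For an adjacency matrix this counts the closed walks of
#' length k; N(A, 2) = 2 |E| and N(A, 3) = 6 x (number of triangles).
#'
#' @param g a graph (adjacency matrix, embedding, `fullerene`,
#'   `dual_triangulation`, or subgraph structure).
#' @param k order, k >= 0.
#' @param params optional `character_params`; when given, M = A +
#'   (beta/alpha) D instead of the plain adjacency matrix.
#' @return numeric trace of the k-th matrix power.
#' @export
newton_polynomial <- function(g, k, params = NULL) {
  stopifnot(k >= 0)
  a <- .graph_adjacency(g)
  m <- a
  if (!is.null(params)) {
    stopifnot(inherits(params, "character_params"))
    m <- a + (params$beta / params$alpha) * diag(rowSums(a))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sum(ev^k)
}

#' The (alpha, beta)-character of a graph
#'
#' Computed from the symmetric eigendecomposition of A + (beta/alpha) D as
#' sum_j exp(alpha * lambda_j); equal to the trace of expm(alpha A +
#' beta D) and invariant under isomorphism.  As alpha, beta -> 0 the
#' character converges to the number of vertices.
#'
#' @param g a graph (see [newton_polynomial()] for accepted forms).
#' @param params a `character_params` (default (1/2, 1/4)).
#' @return numeric scalar.
#' @export
graph_character <- function(g, params = character_params()) {
  stopifnot(inherits(params, "character_params"))
  a <- .graph_adjacency(g)
  if (nrow(a) == 0L) return(0)
  ev <- eigen(a + (params$beta / params$alpha) * diag(rowSums(a)),
              symmetric = TRUE, only.values = TRUE)$values
  sum(exp(params$alpha * ev))
}

# characters of all isomers of C_n (dual graphs), fast adjacency-only path
.characters_of_cn <- function(n, params = character_params(),
                              subgraph = c("dual", "hex")) {
  subgraph <- match.arg(subgraph)
  codes <- enumerate_isomers(n)
  m <- n / 2 + 2
  vapply(seq_len(nrow(codes)), function(j) {
    sizes <- rep(6L, m); sizes[codes[j, ]] <- 5L
    adj <- windup_adjacency(sizes)
    if (subgraph == "hex") {
      keep <- rowSums(adj) == 6L
      adj <- adj[keep, keep, drop = FALSE]
    }
    graph_character(adj, params)
  }, numeric(1))
}

#' Normalized character within C_n
#'
#' For n admitting both a Goldberg polyhedron and a (5,0)-nanotube (such
#' as 60, 80, 140), the two extremal structures centre and scale the
#' character: 0 corresponds to the Goldberg dual (minimal character), 1 to
#' the nanotube dual (maximal character).
#'
#' @param g a dual fullerene graph of C_n (any accepted graph form).
#' @param n the isomer family size (even; must admit both extremal
#'   structures).
#' @param params a `character_params`.
#' @return numeric scalar (in `[0, 1]` whenever the extremality of the two
#'   reference structures holds).
#' @export
normalized_character <- function(g, n, params = character_params()) {
  ext <- .extremal_characters(n, params)
  (graph_character(g, params) - ext$lo) / (ext$hi - ext$lo)
}

.extremal_characters <- function(n, params) {
  gp <- .goldberg_pq(n)
  if (is.null(gp) || n %% 10L != 0L)
    stop("n = ", n, " does not admit both a Goldberg polyhedron and a (5,0)-nanotube")
  lo <- graph_character(goldberg(gp[[1L]], gp[[2L]], as = "dual"), params)
  hi <- graph_character(nanotube_5_0(n, as = "dual"), params)
  list(lo = lo, hi = hi)
}

# integers p >= q >= 0 with n = 20((p+q)^2 - pq), if any
.goldberg_pq <- function(n) {
  if (n %% 20L != 0L) {
    # odd T values can still hit n/20 non-integer; bail out
  }
  if (n %% 20L != 0L) return(NULL)
  Tn <- n %/% 20L
  for (p in seq_len(ceiling(sqrt(Tn)) + 1L)) for (q in 0:p)
    if ((p + q)^2 - p * q == Tn) return(c(p, q))
  NULL
}

#' Character ranges of isomer sets
#'
#' Computes, for each n and each parameter pair, the minimum and maximum
#' (alpha, beta)-character over all C_n isomers, and flags pairwise
#' overlaps of the character intervals for consecutive n.  Small
#' parameters separate the ranges (characters approach the vertex count);
#' large parameters let the ranges overlap.
#'
#' @param ns integer vector of vertex counts (each fully enumerable).
#' @param param_list list of `character_params`.
#' @return list with `ranges` (data.frame: alpha, beta, n, min, max) and
#'   `overlaps` (data.frame: alpha, beta, n1, n2, overlap flag), where the
#'   overlap compares `[min, max]` intervals of consecutive entries of
#'   `ns`.
#' @export
character_range_experiment <- function(ns, param_list) {
  ranges <- list()
  overlaps <- list()
  for (p in param_list) {
    stopifnot(inherits(p, "character_params"))
    ch <- lapply(ns, .characters_of_cn, params = p)
    for (i in seq_along(ns))
      ranges[[length(ranges) + 1L]] <-
        data.frame(alpha = p$alpha, beta = p$beta, n = ns[[i]],
                   min = min(ch[[i]]), max = max(ch[[i]]))
    for (i in seq_len(length(ns) - 1L))
      overlaps[[length(overlaps) + 1L]] <-
        data.frame(alpha = p$alpha, beta = p$beta,
                   n1 = ns[[i]], n2 = ns[[i + 1L]],
                   overlap = max(ch[[i]]) >= min(ch[[i + 1L]]))
  }
  list(ranges = do.call(rbind, ranges), overlaps = do.call(rbind, overlaps))
}

#' Histogram of normalized characters over all isomers of C_n
#'
#' @param n vertex count admitting both extremal structures (60, 80, 140).
#' @param graph_choice use the full dual (`"dual"`) or its hexagonal
#'   subgraph (`"hex"`) for the per-isomer characters (the extremal
#'   references always use the full dual scaling of the chosen graph).
#' @param bins number of equal-width bins on `[0, 1]` (default 1000).
#' @param params a `character_params`.
#' @return list with `breaks`, `counts`, `density` and the raw
#'   `normalized` values.
#' @export
character_histogram <- function(n, graph_choice = c("dual", "hex"),
                                bins = 1000L, params = character_params()) {
  graph_choice <- match.arg(graph_choice)
  vals <- .characters_of_cn(n, params, subgraph = graph_choice)
  # centre and scale by the extremal isomers of the same graph choice
  if (graph_choice == "dual") {
    ext <- .extremal_characters(n, params)
    lo <- ext$lo; hi <- ext$hi
  } else {
    gp <- .goldberg_pq(n)
    sub6 <- function(td) {
      adj <- embedding_adjacency(td$embedding)
      keep <- rowSums(adj) == 6L
      adj[keep, keep, drop = FALSE]
    }
    lo <- graph_character(sub6(goldberg(gp[[1L]], gp[[2L]], as = "dual")), params)
    hi <- graph_character(sub6(nanotube_5_0(n, as = "dual")), params)
  }
  z <- (vals - lo) / (hi - lo)
  breaks <- seq(0, 1, length.out = bins + 1L)
  zc <- pmin(pmax(z, 0), 1)
  counts <- tabulate(pmin(findInterval(zc, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  list(breaks = breaks, counts = counts,
       density = counts / (sum(counts) * diff(breaks)[1L]),
       normalized = z)
}

#' Character collision scan (injectivity check)
#'
#' Compares the characters of all isomers with n <= n_max (across all n)
#' and reports collisions between non-isomorphic duals at a relative
#' tolerance; supports (without proving) the conjectured injectivity of
#' the character for parameters in (0, 1).
#'
#' @param n_max largest vertex count scanned.
#' @param params a `character_params`.
#' @param tol relative tolerance for equality (default 1e-9).
#' @return data.frame of collisions (n1, j1, n2, j2, ch1, ch2); zero rows
#'   when the character separates all scanned isomers.
#' @export
conjecture3_check <- function(n_max, params = character_params(), tol = 1e-9) {
  tab <- list()
  for (n in seq(20L, as.integer(n_max), by = 2L)) {
    codes <- enumerate_isomers(n)
    if (nrow(codes) == 0L) next
    ch <- .characters_of_cn(n, params)
    tab[[length(tab) + 1L]] <- data.frame(n = n, j = seq_along(ch), ch = ch)
  }
  tab <- do.call(rbind, tab)
  ord <- order(tab$ch)
  tab <- tab[ord, ]
  out <- list()
  for (i in seq_len(nrow(tab) - 1L)) {
    a <- tab[i, ]; b <- tab[i + 1L, ]
    if (abs(a$ch - b$ch) <= tol * max(abs(a$ch), abs(b$ch))) {
      out[[length(out) + 1L]] <-
        data.frame(n1 = a$n, j1 = a$j, n2 = b$n, j2 = b$j, ch1 = a$ch, ch2 = b$ch)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(n1 = integer(0), j1 = integer(0), n2 = integer(0),
                  j2 = integer(0), ch1 = numeric(0), ch2 = numeric(0))
}

#' Riemann zeta function by Euler-Maclaurin summation
#'
#' Partial sums of k^-s with an Euler-Maclaurin tail correction whose
#' remainder is bounded by the first omitted term; accurate to at least
#' ten significant digits for s > 1 (zeta(9) = 1.00200839... enters the
#' asymptotic isomer-count formula).
#'
#' @param s real, s > 1.
#' @param K number of explicit terms (default 100).
#' @return numeric value of zeta(s).
#' @export
riemann_zeta <- function(s, K = 100L) {
  stopifnot(length(s) == 1L, s > 1)
  k <- seq_len(K)
  head_sum <- sum(k^(-s))
  # Euler-Maclaurin tail: integral + half-term + Bernoulli corrections
  tail_sum <- K^(1 - s) / (s - 1) - 0.5 * K^(-s) +
    s / 12 * K^(-s - 1) -
    s * (s + 1) * (s + 2) / 720 * K^(-s - 3) +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) / 30240 * K^(-s - 5)
  head_sum + tail_sum
}
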
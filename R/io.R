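#' Read and write spiral code files
#'
#' One isomer per line in the format `"n: p1 p2 ... p12"` with 1-based
#' pentagon positions.  The reader is whitespace-tolerant; the writer is
#' canonical (single spaces), so write-read round-trips are exact.
#'
#' @param path file path or connection.
#' @return `read_spiral_file`: list of `spiral_code`.
#' @export
read_spiral_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("line ", i, ": expected \"n: p1 ... p12\"")
    n <- suppressWarnings(as.integer(trimws(parts[[1L]])))
    pos <- suppressWarnings(as.integer(strsplit(trimws(parts[[2L]]), "\\s+")[[1L]]))
    if (is.na(n) || anyNA(pos)) stop("line ", i, ": malformed integers")
    if (length(pos) != 12L)
      stop("line ", i, ": expected 12 pentagon positions, found ", length(pos))
    if (any(diff(pos) <= 0L)) stop("line ", i, ": positions must increase")
    spiral_code(n, pos)
  })
}

#' @rdname read_spiral_file
#' @param codes list of `spiral_code` (a single code is accepted).
#' @export
write_spiral_file <- function(codes, path) {
  if (inherits(codes, "spiral_code")) codes <- list(codes)
  writeLines(vapply(codes, format, character(1)), path)
}

#' Read and write planar-code streams
#'
#' The binary planar-code format used by the cubic/planar graph
#' generation ecosystem: the ASCII header `>>planar_code<<`, then per
#' graph one unsigned byte with the vertex count followed, for every
#' vertex, by its cyclically ordered neighbour list terminated by a zero
#' byte.  Only graphs with at most 255 vertices are handled.
#'
#' @param path file path or binary connection.
#' @return `read_planar_code`: list of `planar_embedding`.
#' @export
read_planar_code <- function(path) {
  con <- if (inherits(path, "connection")) path else {
    fc <- file(path, "rb"); on.exit(close(fc)); fc
  }
  header <- rawToChar(readBin(con, "raw", 15L))
  if (header != ">>planar_code<<")
    stop("malformed planar-code header at byte 0: ", header)
  out <- list()
  repeat {
    nb <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
    if (length(nb) == 0L) break
    if (nb == 0L) stop("graphs with more than 255 vertices are not supported")
    rot <- vector("list", nb)
    for (v in seq_len(nb)) {
      nbrs <- integer(0)
      repeat {
        x <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
        if (length(x) == 0L) stop("truncated planar-code stream in vertex ", v)
        if (x == 0L) break
        nbrs <- c(nbrs, x)
      }
      rot[[v]] <- nbrs
    }
    out[[length(out) + 1L]] <- planar_embedding(rot)
  }
  out
}

#' @rdname read_planar_code
#' @param graphs list of `planar_embedding` (or objects with an
#'   `embedding` field); a single graph is accepted.
#' @export
write_planar_code <- function(graphs, path) {
  if (!is.list(graphs) || !is.null(graphs$embedding) ||
      inherits(graphs, "planar_embedding")) graphs <- list(graphs)
  con <- if (inherits(path, "connection")) path else {
    fc <- file(path, "wb"); on.exit(close(fc)); fc
  }
  writeBin(charToRaw(">>planar_code<<"), con)
  for (g in graphs) {
    emb <- if (inherits(g, "planar_embedding")) g else g$embedding
    if (emb$n_vertices > 255L) stop("graph too large for single-byte planar code")
    writeBin(as.raw(emb$n_vertices), con)
    for (v in seq_len(emb$n_vertices))
      writeBin(as.raw(c(emb$rotation[[v]], 0L)), con)
  }
  invisible(NULL)
}

#' Read and write rotation-system text files
#'
#' A plain-text embedding format: a header line `# rotation-system 1-based`
#' followed by one vertex per line, `id: n1 n2 n3 ...` listing the
#' counterclockwise neighbour order.
#'
#' @param path file path.
#' @return `read_rotation_file`: a `planar_embedding`.
#' @export
read_rotation_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- integer(length(lines))
  rot <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("line ", i, ": expected \"id: neighbours\"")
    ids[[i]] <- as.integer(trimws(parts[[1L]]))
    rot[[i]] <- as.integer(strsplit(trimws(parts[[2L]]), "\\s+")[[1L]])
  }
  if (!identical(sort(ids), seq_along(ids)))
    stop("vertex ids must be 1..", length(ids))
  planar_embedding(rot[order(ids)])
}

#' @rdname read_rotation_file
#' @param emb a `planar_embedding` (or object with an `embedding` field).
#' @export
write_rotation_file <- function(emb, path) {
  if (!inherits(emb, "planar_embedding")) emb <- emb$embedding
  lines <- c("# rotation-system 1-based",
             vapply(seq_len(emb$n_vertices), function(v)
               paste0(v, ": ", paste(emb$rotation[[v]], collapse = " ")),
               character(1)))
  writeLines(lines, path)
}

#' Reference graph set
#'
#' Named dual triangulations used throughout the tests and examples: the
#' dodecahedron dual (C20), the smallest hexagon-bearing fullerene (C24),
#' the growth-construction seed (C36 isomer 1), the gSW-free isomer
#' C56,622, the glued gSW-free family member at t = 2 (C92), and the two
#' extremal C60 structures ((5,0)-nanotube and Goldberg (1,1)).  Every
#' fixture is validated on construction.
#'
#' @return named list of `dual_triangulation`.
#' @export
fixtures <- function() {
  list(
    c20 = windup(spiral_code(20, 1:12), as = "dual"),
    c24 = isomer_by_index(24, 1, as = "dual"),
    c36_1 = isomer_by_index(36, 1, as = "dual"),
    c56_622 = isomer_by_index(56, 622, as = "dual"),
    construction2_t2 = construction2(2),
    nanotube_c60 = nanotube_5_0(60, as = "dual"),
    goldberg_c60 = goldberg(1, 1, as = "dual")
  )
}
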
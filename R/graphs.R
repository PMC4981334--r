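#' Regular graphs for evolutionary dynamics
#'
#' A `regular_graph` holds `N` vertices each with exactly `k` distinct
#' neighbors, stored as an `N x k` integer matrix of 1-based neighbor
#' indices (row `i` lists the neighbors of vertex `i`). All constructors
#' produce simple, connected, vertex-symmetric adjacency; generation is
#' deterministic given parameters (and seed, where stochastic).
#'
#' @name regular_graph
NULL

new_regular_graph <- function(adj, family, seed = NA) {
  storage.mode(adj) <- "integer"
  g <- structure(list(N = nrow(adj), k = ncol(adj), adj = adj,
                      family = family, seed = seed),
                 class = "regular_graph")
  v <- validate_regular(g, g$k)
  if (!v) stop("internal error: constructed graph is not a valid ",
               g$k, "-regular connected graph: ",
               paste(attr(v, "diagnostics"), collapse = "; "))
  g
}

is_regular_graph <- function(x) inherits(x, "regular_graph")

#' @export
print.regular_graph <- function(x, ...) {
  cat(sprintf("regular graph [%s]: N = %d vertices, degree k = %d, %d edges\n",
              x$family, x$N, x$k, x$N * x$k / 2))
  invisible(x)
}

as_igraph <- function(g) {
  el <- cbind(rep(seq_len(g$N), g$k), as.vector(g$adj))
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Ring (generalized cycle)
#'
#' Each vertex `i` is connected to the `k/2` vertices on either side,
#' `i - k/2, ..., i - 1, i + 1, ..., i + k/2` (mod `N`). With `k = 2` this
#' is the cycle.
#'
#' @param N Number of vertices, at least `k + 2` (smaller rings would wrap
#'   around onto duplicate neighbors).
#' @param k Even degree, at least 2.
#' @return A `regular_graph` with family `"cycle"` (`k = 2`) or `"ring"`.
#' @examples
#' make_ring(100, 4)
#' @export
make_ring <- function(N, k) {
  if (k %% 2 != 0) stop("ring degree k must be even")
  if (k < 2) stop("degree k must be at least 2")
  if (N < k + 2) stop("N too small: a ring needs N >= k + 2 to avoid duplicate neighbors")
  half <- k / 2
  offs <- c(-(half:1), 1:half)
  adj <- outer(seq_len(N) - 1, offs, function(i, o) (i + o) %% N) + 1
  new_regular_graph(adj, if (k == 2) "cycle" else "ring")
}

#' Random regular graph
#'
#' Samples a simple `k`-regular graph on `N` vertices and rejects
#' disconnected outcomes, resampling until the graph is connected (retry cap
#' 10^4). The sequence of draws is deterministic given `seed`.
#'
#' @param N Number of vertices (`N > k`, `N * k` even).
#' @param k Degree.
#' @param seed Integer RNG seed.
#' @return A `regular_graph` with family `"random_regular"`.
#' @export
make_random_regular <- function(N, k, seed) {
  if (N <= k) stop("need N > k")
  if ((N * k) %% 2 != 0) stop("N * k must be even (handshake parity)")
  set.seed(seed)
  for (try in seq_len(1e4)) {
    ig <- igraph::sample_k_regular(N, k, directed = FALSE, multiple = FALSE)
    if (igraph::is_connected(ig)) {
      am <- igraph::as_adj_list(ig)
      adj <- t(vapply(am, function(v) sort(as.integer(v)), integer(k)))
      return(new_regular_graph(adj, "random_regular", seed = seed))
    }
  }
  stop("failed to sample a connected ", k, "-regular graph in 10^4 tries")
}

lattice_offsets <- list(
  vn4    = cbind(dx = c(1, -1, 0, 0), dy = c(0, 0, 1, -1)),
  hex6   = cbind(dx = c(1, -1, 0, 0, 1, -1), dy = c(0, 0, 1, -1, 1, -1)),
  moore8 = cbind(dx = c(1, -1, 0, 0, 1, -1, 1, -1),
                 dy = c(0, 0, 1, -1, 1, -1, -1, 1))
)

#' Periodic lattices of degree 4, 6 and 8
#'
#' Toroidal (periodic-boundary) lattices on a `side x side` grid: the square
#' lattice with von Neumann neighborhood (`k = 4`), the hexagonal tiling in
#' which every site has six neighbors, built as the triangular lattice
#' (`k = 6`), and the square lattice with Moore neighborhood (`k = 8`).
#' Periodic boundaries keep the graph exactly regular, as the theory
#' requires.
#'
#' @param kind One of `"vn4"`, `"hex6"`, `"moore8"`.
#' @param side Grid side; `N = side^2`. At least 3 (`moore8` needs
#'   `side >= 4`: on a 3-torus the Moore neighborhood reaches every other
#'   site, a degenerate lattice).
#' @return A `regular_graph` with family `"lattice_vn4"`, `"lattice_hex6"`
#'   or `"lattice_moore8"`.
#' @examples
#' make_lattice("vn4", 10)   # N = 100, k = 4
#' @export
make_lattice <- function(kind = c("vn4", "hex6", "moore8"), side) {
  kind <- match.arg(kind)
  if (side < 3) stop("lattice side must be at least 3")
  if (kind == "moore8" && side < 4)
    stop("moore8 needs side >= 4: wrap-around on side 3 degenerates the neighborhood")
  offs <- lattice_offsets[[kind]]
  N <- side^2
  xy <- cbind(x = (seq_len(N) - 1) %% side, y = (seq_len(N) - 1) %/% side)
  adj <- sapply(seq_len(nrow(offs)), function(o) {
    nx <- (xy[, "x"] + offs[o, "dx"]) %% side
    ny <- (xy[, "y"] + offs[o, "dy"]) %% side
    ny * side + nx + 1
  })
  new_regular_graph(adj, paste0("lattice_", kind))
}

#' Validate regularity invariants
#'
#' Checks that every vertex has exactly `k` distinct neighbors, no vertex is
#' its own neighbor, adjacency is symmetric, and the graph is connected.
#'
#' @param g A `regular_graph` (or anything with fields `N`, `k`, `adj`).
#' @param k Expected degree.
#' @return `TRUE`, or `FALSE` with a `diagnostics` attribute listing the
#'   violated invariants.
#' @export
validate_regular <- function(g, k) {
  bad <- character(0)
  adj <- g$adj
  if (!is.matrix(adj) || ncol(adj) != k) {
    bad <- c(bad, sprintf("degree: adjacency has %s columns, expected %d",
                          if (is.matrix(adj)) ncol(adj) else "no", k))
  } else {
    if (any(adj < 1 | adj > g$N)) bad <- c(bad, "neighbor index out of range")
    if (any(adj == row(adj))) bad <- c(bad, "self-loop")
    if (any(apply(adj, 1, anyDuplicated) > 0)) bad <- c(bad, "duplicate neighbor")
    if (length(bad) == 0) {
      sym <- all(vapply(seq_len(g$N), function(i)
        all(vapply(adj[i, ], function(j) i %in% adj[j, ], logical(1))),
        logical(1)))
      if (!sym) bad <- c(bad, "asymmetric adjacency")
      if (!igraph::is_connected(as_igraph(g))) bad <- c(bad, "disconnected")
    }
  }
  if (length(bad) == 0) return(TRUE)
  structure(FALSE, diagnostics = bad)
}

#' Read and write graphs as plain edge lists
#'
#' Edge-list files contain one whitespace-separated `u v` pair per line with
#' 0-based vertex indices, each undirected edge listed once.
#'
#' @param g A `regular_graph`.
#' @param path File path.
#' @return `write_edgelist()` returns `path` invisibly; `read_edgelist()`
#'   returns a `regular_graph` with family `"custom"` (the file must encode
#'   a connected regular graph).
#' @name edgelist-io
#' @export
write_edgelist <- function(g, path) {
  stopifnot(is_regular_graph(g))
  el <- cbind(rep(seq_len(g$N), g$k), as.vector(g$adj))
  el <- el[el[, 1] < el[, 2], , drop = FALSE] - 1L
  write.table(el, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname edgelist-io
#' @export
read_edgelist <- function(path) {
  el <- as.matrix(read.table(path, header = FALSE))
  if (ncol(el) != 2) stop("edge-list file must have two columns")
  el <- el + 1L
  N <- max(el)
  nbrs <- vector("list", N)
  for (r in seq_len(nrow(el))) {
    nbrs[[el[r, 1]]] <- c(nbrs[[el[r, 1]]], el[r, 2])
    nbrs[[el[r, 2]]] <- c(nbrs[[el[r, 2]]], el[r, 1])
  }
  degs <- lengths(nbrs)
  if (length(unique(degs)) != 1)
    stop("edge list does not encode a regular graph (degrees ",
         paste(range(degs), collapse = ".."), ")")
  adj <- t(vapply(nbrs, function(v) sort(as.integer(v)), integer(degs[1])))
  new_regular_graph(adj, "custom")
}
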
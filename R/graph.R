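# Undirected simple-graph container with bit-packed adjacency (32 adjacency
# booleans per 4-byte integer word) plus per-node neighbour sets. Node ids
# are dense 1-based integers internally; external labels live in `labels`
# and are mapped at I/O time.

#' Create an undirected simple graph
#'
#' @param n number of nodes.
#' @param edges optional 2-column matrix/data frame of 1-based node ids.
#' @param labels optional character vector of external node labels
#'   (defaults to `as.character(1:n)`).
#' @param packed_cutoff node count above which the bit-packed adjacency
#'   matrix is dropped and only neighbour sets are kept. The default keeps
#'   the bit matrix for every desk-scale graph.
#' @return An object of class `gd_graph`.
#' @export
gd_graph <- function(n, edges = NULL, labels = NULL, packed_cutoff = 4096L) {
  stopifnot(n >= 0)
  g <- structure(list(
    n = as.integer(n),
    labels = if (is.null(labels)) as.character(seq_len(n)) else as.character(labels),
    adj = rep(list(integer(0)), n),
    packed = if (n <= packed_cutoff)
      raw(ceiling(as.numeric(n) * n / 8)) else NULL,
    m = 0L), class = "gd_graph")
  if (length(g$labels) != n) stop("gd_graph: labels length must equal n")
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    for (e in seq_len(nrow(edges)))
      g <- apply_modification(g, "+", edges[e, 1L], edges[e, 2L])
  }
  g
}

#' @export
print.gd_graph <- function(x, ...) {
  cat(sprintf("undirected graph: %d nodes, %d edges (%s adjacency)\n",
              x$n, x$m,
              if (is.null(x$packed)) "neighbour-set" else "bit-packed"))
  invisible(x)
}

packed_index <- function(i, j, n) (as.numeric(i) - 1) * n + (j - 1)  # 0-based bit

# The bit matrix is stored in a raw vector: one adjacency boolean per bit,
# eight per byte — the 32-booleans-per-4-byte-word density of the capacity
# arithmetic. (R's signed integers cannot hold bit 31, so bytes, not ints.)
packed_get <- function(g, i, j) {
  idx <- packed_index(i, j, g$n)
  w <- idx %/% 8 + 1
  bitwAnd(as.integer(g$packed[w]), bitwShiftL(1L, idx %% 8)) != 0L
}

packed_set <- function(g, i, j, value) {
  for (p in list(c(i, j), c(j, i))) {
    idx <- packed_index(p[1L], p[2L], g$n)
    w <- idx %/% 8 + 1
    mask <- bitwShiftL(1L, idx %% 8)
    g$packed[w] <- as.raw(if (value) bitwOr(as.integer(g$packed[w]), mask)
                          else bitwAnd(as.integer(g$packed[w]), bitwNot(mask)))
  }
  g
}

#' Test for an edge
#' @param g a [gd_graph()].
#' @param u,v 1-based node ids.
#' @return Logical.
#' @export
has_edge <- function(g, u, v) {
  if (u == v) return(FALSE)
  if (!is.null(g$packed)) packed_get(g, u, v) else v %in% g$adj[[u]]
}

#' Apply a single edge modification
#'
#' Adding an edge that is present, or removing one that is absent, is an
#' error: it signals a corrupted modification stream.
#'
#' @param g a [gd_graph()].
#' @param op `"+"` (add) or `"-"` (remove).
#' @param u,v 1-based node ids, `u != v`.
#' @return The updated graph.
#' @export
apply_modification <- function(g, op, u, v) {
  u <- as.integer(u); v <- as.integer(v)
  if (u == v) stop("apply_modification: self-loop (", u, ",", v, ")")
  if (u < 1L || v < 1L || u > g$n || v > g$n)
    stop("apply_modification: node id out of range")
  op <- as.character(op)
  present <- has_edge(g, u, v)
  if (op == "+") {
    if (present) stop("apply_modification: ADD on existing edge (",
                      u, ",", v, ")")
    g$adj[[u]] <- sort(c(g$adj[[u]], v))
    g$adj[[v]] <- sort(c(g$adj[[v]], u))
    if (!is.null(g$packed)) g <- packed_set(g, u, v, TRUE)
    g$m <- g$m + 1L
  } else if (op == "-") {
    if (!present) stop("apply_modification: REMOVE on absent edge (",
                       u, ",", v, ")")
    g$adj[[u]] <- setdiff(g$adj[[u]], v)
    g$adj[[v]] <- setdiff(g$adj[[v]], u)
    if (!is.null(g$packed)) g <- packed_set(g, u, v, FALSE)
    g$m <- g$m - 1L
  } else stop("apply_modification: op must be '+' or '-'")
  g
}

#' Edge list of a graph
#' @param g a [gd_graph()].
#' @return Integer matrix with columns `u`, `v` (`u < v`), one row per edge.
#' @export
gd_edges <- function(g) {
  u <- rep.int(seq_len(g$n), lengths(g$adj))
  v <- unlist(g$adj, use.names = FALSE)
  keep <- u < v
  cbind(u = u[keep], v = v[keep])
}

#' Node degrees
#' @param g a [gd_graph()].
#' @return Integer vector of degrees.
#' @export
gd_degree <- function(g) lengths(g$adj)

#' h-index of a graph
#'
#' The largest `h` such that at least `h` nodes have degree at least `h`;
#' the quantity that governs the incremental counter's empirical cost.
#'
#' @param g a [gd_graph()].
#' @return Integer.
#' @export
h_index <- function(g) {
  d <- sort(gd_degree(g), decreasing = TRUE)
  h <- 0L
  while (h < length(d) && d[h + 1L] >= h + 1L) h <- h + 1L
  h
}

#' Node capacity of a bit-packed adjacency matrix
#'
#' Largest `n` such that a full `n x n` bit matrix (32 adjacency booleans
#' per 4-byte word) fits in `bytes` bytes. With `bytes = 2^30` (one
#' binary gigabyte) this is 92681.
#'
#' @param bytes memory budget in bytes (> 0).
#' @return Integer node capacity.
#' @examples
#' packed_capacity(2^30)  # 92681
#' @export
packed_capacity <- function(bytes) {
  stopifnot(bytes > 0)
  n <- floor(sqrt(bytes * 8))
  while ((n + 1)^2 <= bytes * 8) n <- n + 1
  while (n^2 > bytes * 8) n <- n - 1
  as.integer(n)
}

# 0-based edge matrix for the C++ kernels
edges0 <- function(g) {
  e <- gd_edges(g)
  storage.mode(e) <- "integer"
  e - 1L
}

# consistency check between the two adjacency representations
representations_agree <- function(g) {
  if (is.null(g$packed)) return(TRUE)
  for (u in seq_len(g$n)) for (v in seq_len(g$n)) {
    if (u == v) next
    if (packed_get(g, u, v) != (v %in% g$adj[[u]])) return(FALSE)
  }
  TRUE
}
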
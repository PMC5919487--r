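# Static orbit counting. count_graphlets() enumerates every connected
# induced subgraph on 2-5 nodes exactly once (exclusive-neighbourhood
# expansion in C++) and classifies via the mask lookup table.
# count_graphlets_brute() is the independent oracle: direct subset
# enumeration with permutation-search isomorphism, sharing no code with the
# lookup-table path.

count_object <- function(counts, totals, visited, labels) {
  dimnames(counts) <- list(labels, paste0("O", 0:72))
  names(totals) <- paste0("G", 0:29)
  structure(list(counts = counts, totals = totals, visited = visited),
            class = "graphlet_counts")
}

#' @export
print.graphlet_counts <- function(x, ...) {
  cat(sprintf("graphlet counts: %d nodes, %s graphlet occurrences (%s subgraphs visited)\n",
              nrow(x$counts), format(sum(x$totals), big.mark = ","),
              format(x$visited, big.mark = ",")))
  invisible(x)
}

#' Count all graphlet and orbit occurrences
#'
#' Enumerates every connected induced subgraph on 2-5 nodes exactly once and
#' returns the n-by-73 node/orbit count matrix together with the 30 per-class
#' graphlet totals. Column `O0` always equals the degree sequence.
#'
#' @param g a [gd_graph()].
#' @return A `graphlet_counts` object: `counts` (n x 73 matrix), `totals`
#'   (length-30 vector), `visited` (number of subgraphs enumerated).
#' @examples
#' tri <- gd_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
#' count_graphlets(tri)$totals[c("G0", "G2")]  # 3 edges, 1 triangle
#' @export
count_graphlets <- function(g) {
  res <- cpp_count_all(g$n, edges0(g), lookup_for_cpp())
  count_object(res$counts, res$totals, res$visited, g$labels)
}

# --- independent oracle ------------------------------------------------------

# canonical bit-string of a small adjacency matrix, by explicit permutation
# minimisation (no lookup table involved)
brute_env <- new.env(parent = emptyenv())

brute_key <- function(A) paste(A[upper.tri(A)] * 1L, collapse = "")

# match a subset adjacency matrix to a catalogue class by permutation search;
# returns list(gid, orbits = global orbit id per subset position)
brute_classify <- function(A) {
  s <- nrow(A)
  key <- paste0(s, ":", brute_key(A))
  hit <- brute_env[[key]]
  if (!is.null(hit)) return(hit)
  perms <- perm_matrix(s)
  classes <- gd_taxonomy()$classes
  res <- NULL
  for (cl in classes) {
    if (cl$size != s || cl$n_edges != sum(A) / 2L) next
    R <- matrix(FALSE, s, s)
    ep <- mask_pairs(cl$mask, s)
    for (r in seq_len(nrow(ep)))
      R[ep[r, 1L] + 1L, ep[r, 2L] + 1L] <- R[ep[r, 2L] + 1L, ep[r, 1L] + 1L] <- TRUE
    for (k in seq_len(nrow(perms))) {
      p <- perms[k, ]
      # relabel subset position i -> rep position p[i]; accept when it
      # reproduces the representative adjacency exactly
      ok <- TRUE
      for (i in seq_len(s - 1L)) {
        for (j in (i + 1L):s) {
          if (A[i, j] != R[p[i], p[j]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        res <- list(gid = cl$id, orbits = cl$orbit_global[p])
        break
      }
    }
    if (!is.null(res)) break
  }
  brute_env[[key]] <- res
  res
}

brute_connected <- function(A) {
  s <- nrow(A)
  reach <- A | diag(TRUE, s)
  for (k in seq_len(s)) reach <- (reach %*% reach) > 0
  all(reach)
}

#' Brute-force graphlet counting (independent oracle)
#'
#' Counts by testing every node subset of size 2..5 directly: connectivity by
#' reachability on the subset adjacency matrix, classification by explicit
#' permutation search against the catalogue's representative edge sets. No
#' code is shared with the lookup-table counting path; this is the oracle the
#' fast counters are validated against.
#'
#' @param g a [gd_graph()] with at most 40 nodes (combinatorial guard).
#' @return A `graphlet_counts` object.
#' @export
count_graphlets_brute <- function(g) {
  if (g$n > 40L) stop("count_graphlets_brute: n > 40 (combinatorial guard)")
  A <- matrix(FALSE, g$n, g$n)
  e <- gd_edges(g)
  if (nrow(e)) A[e] <- A[e[, 2:1, drop = FALSE]] <- TRUE
  counts <- matrix(0, g$n, 73)
  totals <- numeric(30)
  visited <- 0
  for (s in 2:min(5L, g$n)) {
    subs <- utils::combn(g$n, s)
    for (c0 in seq_len(ncol(subs))) {
      sub <- subs[, c0]
      As <- A[sub, sub, drop = FALSE]
      if (!brute_connected(As)) next
      visited <- visited + 1
      cl <- brute_classify(As)
      totals[cl$gid + 1L] <- totals[cl$gid + 1L] + 1
      for (p in seq_len(s))
        counts[sub[p], cl$orbits[p] + 1L] <- counts[sub[p], cl$orbits[p] + 1L] + 1
    }
  }
  count_object(counts, totals, visited, g$labels)
}
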
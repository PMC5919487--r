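# Graphlet/orbit taxonomy: the 30 connected isomorphism classes on 2-5 nodes
# (G0..G29), their 73 node orbits (O0..O72), and the edge-mask lookup tables
# used by every counter in the package.

.gd_cache <- new.env(parent = emptyenv())

#' Lexicographic rank of an unordered node-position pair
#'
#' Positions are 0-based, `i < j`, pairs ordered (0,1), (0,2), ..., (s-2,s-1).
#' This fixed ordering defines the bit weights of [edge_mask()].
#'
#' @param i,j 0-based positions, `i < j`.
#' @param s subgraph size (number of positions).
#' @return 0-based rank of the pair among the `choose(s, 2)` pairs.
#' @keywords internal
pair_rank <- function(i, j, s) {
  i * s - (i * (i + 1L)) %/% 2L + (j - i - 1L)
}

# all unordered pairs of 0..s-1 in rank order, one row per pair
pair_table <- function(s) {
  t(utils::combn(0:(s - 1L), 2L))
}

# all permutations of 1..s as a matrix, one permutation per row
perm_matrix <- function(s) {
  if (s == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(s - 1L)
  out <- vector("list", s)
  for (k in seq_len(s)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[[k]] <- block
  }
  do.call(rbind, out)
}

# decode a mask into its edge rows of pair_table(s)
mask_pairs <- function(mask, s) {
  pt <- pair_table(s)
  bit <- bitwAnd(bitwShiftR(mask, seq_len(nrow(pt)) - 1L), 1L)
  pt[bit == 1L, , drop = FALSE]
}

# connectivity of the s positions under the masked edge set
mask_connected <- function(mask, s) {
  if (s == 1L) return(TRUE)
  ep <- mask_pairs(mask, s)
  if (nrow(ep) < s - 1L) return(FALSE)
  seen <- logical(s)
  seen[1L] <- TRUE
  frontier <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- c(ep[ep[, 1L] == v, 2L], ep[ep[, 2L] == v, 1L])
      nb <- nb[!seen[nb + 1L]]
      seen[nb + 1L] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  all(seen)
}

# For size s, the action of every permutation on masks, as a matrix
# pm[mask + 1, k] = mask after relabelling position i -> perm[k, i].
perm_mask_action <- function(s) {
  pt <- pair_table(s)
  np <- nrow(pt)
  perms <- perm_matrix(s)
  nmask <- bitwShiftL(1L, np)
  bits <- sapply(seq_len(np), function(r) {
    bitwAnd(bitwShiftR(0:(nmask - 1L), r - 1L), 1L)
  })
  pm <- matrix(0L, nmask, nrow(perms))
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ] - 1L                     # 0-based images
    a <- p[pt[, 1L] + 1L]
    b <- p[pt[, 2L] + 1L]
    newrank <- pair_rank(pmin(a, b), pmax(a, b), s)
    pm[, k] <- as.integer(bits %*% bitwShiftL(1L, newrank))
  }
  list(perms = perms, action = pm)
}

#' Enumerate graphlet classes on 2-5 nodes from first principles
#'
#' Scans every edge mask of every subgraph size in 2..5, keeps the connected
#' ones, groups them by canonical form (minimum mask over all position
#' permutations) and partitions each class's positions into automorphism
#' orbits by explicit permutation search. No precomputed table is consulted;
#' this is the ground-truth builder behind [graphlet_catalogue()].
#'
#' @return A list with one entry per isomorphism class:
#'   `size`, `mask` (canonical representative), `n_edges`, `degrees`
#'   (of the representative labelling), `orbit_of_position` (0-based local
#'   orbit labels, one per position, labelled by each orbit's minimal
#'   position), and `n_orbits`.
#' @export
enumerate_graphlet_classes <- function() {
  classes <- list()
  for (s in 2:5) {
    pa <- perm_mask_action(s)
    nmask <- nrow(pa$action)
    canon <- do.call(pmin, lapply(seq_len(ncol(pa$action)),
                                  function(k) pa$action[, k]))
    conn <- vapply(0:(nmask - 1L), mask_connected, logical(1), s = s)
    reps <- sort(unique(canon[conn]))
    for (rep_mask in reps) {
      auts <- which(pa$action[rep_mask + 1L, ] == rep_mask)
      # orbit of position i = minimal image of i under the automorphism group
      img <- pa$perms[auts, , drop = FALSE]
      orbit_label <- apply(img, 2L, min) - 1L
      ep <- mask_pairs(rep_mask, s)
      deg <- tabulate(c(ep[, 1L], ep[, 2L]) + 1L, nbins = s)
      classes[[length(classes) + 1L]] <- list(
        size = s, mask = rep_mask, n_edges = nrow(ep), degrees = deg,
        orbit_of_position = orbit_label,
        n_orbits = length(unique(orbit_label)))
    }
  }
  classes
}

# Deterministic ordering of classes and of orbits within a class.
# Graphlets: (size, edge count, descending-sorted degree sequence compared
# lexicographically ascending, canonical mask). Orbits within a graphlet:
# (position degree, descending-sorted neighbour degrees, minimal position).
# Reproduces the standard small-graphlet numbering (path ends O1 before
# middle O2, claw leaves O6 before hub O7, ...) and the K5 = G29 / O72 anchor.
order_classes <- function(classes) {
  key <- t(vapply(classes, function(cl) {
    d <- sort(cl$degrees, decreasing = TRUE)
    c(cl$size, cl$n_edges, c(d, rep(0L, 5L - length(d))), cl$mask)
  }, numeric(8)))
  classes[do.call(order, as.data.frame(key))]
}

orbit_order_within <- function(cl) {
  s <- cl$size
  ep <- mask_pairs(cl$mask, s)
  adj <- vector("list", s)
  for (r in seq_len(nrow(ep))) {
    a <- ep[r, 1L] + 1L; b <- ep[r, 2L] + 1L
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  deg <- cl$degrees
  labs <- sort(unique(cl$orbit_of_position))
  key <- t(vapply(labs, function(l) {
    pos <- which(cl$orbit_of_position == l)[1L]
    nd <- sort(deg[adj[[pos]]], decreasing = TRUE)
    c(deg[pos], c(nd, rep(0L, 4L - length(nd))), pos)
  }, numeric(6)))
  labs[do.call(order, as.data.frame(key))]
}

# Build the full taxonomy: ordered classes, global orbit ids, lookup tables.
build_taxonomy <- function() {
  classes <- order_classes(enumerate_graphlet_classes())
  n_orb <- 0L
  for (g in seq_along(classes)) {
    cl <- classes[[g]]
    cl$id <- g - 1L
    ord <- orbit_order_within(cl)
    glob <- n_orb + seq_along(ord) - 1L
    cl$orbit_global <- glob[match(cl$orbit_of_position, ord)]
    cl$orbit_ids <- glob
    n_orb <- n_orb + length(ord)
    classes[[g]] <- cl
  }
  # lookup tables: per size, graphlet id per mask (-1 = disconnected) and
  # global orbit id per (mask, position)
  lookup <- list()
  for (s in 2:5) {
    pa <- perm_mask_action(s)
    nmask <- nrow(pa$action)
    canon_all <- do.call(pmin, lapply(seq_len(ncol(pa$action)),
                                      function(k) pa$action[, k]))
    argmin <- max.col(-pa$action, ties.method = "first")
    conn <- vapply(0:(nmask - 1L), mask_connected, logical(1), s = s)
    idx <- vapply(classes, function(cl)
      if (cl$size == s) cl$mask else -1L, integer(1))
    by_mask_g <- rep(-1L, nmask)
    orb <- matrix(-1L, nmask, s)
    for (g in which(idx >= 0L)) {
      cl <- classes[[g]]
      hit <- which(canon_all == cl$mask & conn)
      for (m in hit) {
        by_mask_g[m] <- cl$id
        p <- pa$perms[argmin[m], ]          # action(mask, p) == canonical rep
        orb[m, ] <- cl$orbit_global[p]
      }
    }
    lookup[[s]] <- list(graphlet = by_mask_g, orbit = orb)
  }
  list(classes = classes, lookup = lookup, n_orbits = n_orb)
}

gd_taxonomy <- function() {
  if (is.null(.gd_cache$taxonomy)) .gd_cache$taxonomy <- build_taxonomy()
  .gd_cache$taxonomy
}

#' The graphlet/orbit catalogue
#'
#' Returns the catalogue of all 30 connected 2-5-node graphlet classes
#' (G0..G29) and their 73 node orbits (O0..O72). The catalogue is computed by
#' canonical-form enumeration and automorphism search, not transcribed, and
#' is cached for the session.
#'
#' @return An object of class `graphlet_catalogue` with components
#'   `graphlets` (data frame: `id`, `size`, `n_edges`, `redundancy`, `edges`,
#'   `orbits`), `orbits` (data frame: `orbit`, `graphlet`), and the internal
#'   class list.
#' @examples
#' cat <- graphlet_catalogue()
#' nrow(cat$graphlets)  # 30
#' nrow(cat$orbits)     # 73
#' @export
graphlet_catalogue <- function() {
  tax <- gd_taxonomy()
  gl <- do.call(rbind, lapply(tax$classes, function(cl) {
    ep <- mask_pairs(cl$mask, cl$size)
    data.frame(
      id = cl$id, size = cl$size, n_edges = cl$n_edges,
      redundancy = cl$n_edges - (cl$size - 1L),
      edges = paste(ep[, 1L], ep[, 2L], sep = "-", collapse = ","),
      orbits = paste(cl$orbit_global, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  ob <- do.call(rbind, lapply(tax$classes, function(cl)
    data.frame(orbit = cl$orbit_ids, graphlet = cl$id)))
  structure(list(graphlets = gl, orbits = ob, classes = tax$classes),
            class = "graphlet_catalogue")
}

#' @export
print.graphlet_catalogue <- function(x, ...) {
  cat(sprintf("graphlet catalogue: %d graphlets, %d orbits (sizes %s)\n",
              nrow(x$graphlets), nrow(x$orbits),
              paste(range(x$graphlets$size), collapse = "-")))
  invisible(x)
}

#' Edge mask of an ordered node tuple
#'
#' Encodes the subgraph induced on `positions` as an integer: pair
#' `(i, j)`, `i < j` (0-based tuple positions, lexicographic order)
#' contributes `2^pair_rank(i, j)` when `adjacent(positions[i+1],
#' positions[j+1])` is true.
#'
#' @param positions vector of 2 to 5 distinct node identifiers.
#' @param adjacent predicate `function(a, b)` returning `TRUE` when the two
#'   nodes are joined by an edge.
#' @return Integer mask in `[0, 2^choose(s, 2))`.
#' @export
edge_mask <- function(positions, adjacent) {
  s <- length(positions)
  if (s < 2L || s > 5L) stop("edge_mask: tuple size must be in 2..5")
  if (anyDuplicated(positions)) stop("edge_mask: positions must be distinct")
  pt <- pair_table(s)
  mask <- 0L
  for (r in seq_len(nrow(pt))) {
    if (isTRUE(adjacent(positions[pt[r, 1L] + 1L], positions[pt[r, 2L] + 1L])))
      mask <- mask + bitwShiftL(1L, r - 1L)
  }
  mask
}

#' Classify an edge mask
#'
#' Looks up the graphlet class and per-position orbits of a masked subgraph.
#' A mask whose edges do not connect all positions classifies as
#' disconnected — an ordinary outcome, not an error, because the incremental
#' counter must classify before-states that fall apart without the modified
#' edge.
#'
#' @param mask integer in `[0, 2^choose(size, 2))`.
#' @param size subgraph size, 2..5.
#' @return A list: `connected` (logical), `graphlet` (id 0..29, or `NA` when
#'   disconnected), `orbits` (integer vector of per-position orbit ids, or
#'   `NULL`).
#' @export
classify_mask <- function(mask, size) {
  if (!(size %in% 2:5)) stop("classify_mask: size must be in 2..5")
  np <- choose(size, 2L)
  if (mask < 0 || mask >= 2^np) stop("classify_mask: mask out of range")
  lk <- gd_taxonomy()$lookup[[size]]
  g <- lk$graphlet[mask + 1L]
  if (g < 0L)
    return(list(connected = FALSE, graphlet = NA_integer_, orbits = NULL))
  list(connected = TRUE, graphlet = g, orbits = lk$orbit[mask + 1L, ])
}

#' Redundancy of a graphlet class
#'
#' The number of edges removable without disconnecting the graphlet:
#' `n_edges - (size - 1)`. Zero exactly for the tree-shaped graphlets.
#'
#' @param graphlet_id integer id(s) in 0..29.
#' @return Integer vector of redundancies.
#' @export
graphlet_redundancy <- function(graphlet_id) {
  if (any(graphlet_id < 0L | graphlet_id > 29L))
    stop("graphlet_redundancy: id out of range 0..29")
  gl <- graphlet_catalogue()$graphlets
  gl$redundancy[match(graphlet_id, gl$id)]
}

# 30-vector of redundancies indexed by graphlet id + 1 (internal hot path)
redundancy_vector <- function() {
  if (is.null(.gd_cache$redvec)) {
    gl <- graphlet_catalogue()$graphlets
    .gd_cache$redvec <- gl$redundancy[order(gl$id)]
  }
  .gd_cache$redvec
}

# lookup tables flattened for the C++ core
lookup_for_cpp <- function() {
  if (is.null(.gd_cache$cpp_lookup)) {
    lk <- gd_taxonomy()$lookup
    .gd_cache$cpp_lookup <- list(
      g2 = lk[[2]]$graphlet, o2 = lk[[2]]$orbit,
      g3 = lk[[3]]$graphlet, o3 = lk[[3]]$orbit,
      g4 = lk[[4]]$graphlet, o4 = lk[[4]]$orbit,
      g5 = lk[[5]]$graphlet, o5 = lk[[5]]$orbit)
  }
  .gd_cache$cpp_lookup
}

#' Write the catalogue reference dump
#'
#' Writes a plain-text TSV of the full catalogue (id, size, edge list, orbit
#' per position, redundancy), the format shipped under `inst/extdata` and
#' used by the regression tests.
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalogue_dump <- function(path) {
  gl <- graphlet_catalogue()$graphlets
  utils::write.table(gl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
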
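# shared fixture builders: seeded random graphs and valid random
# modifications, used by the unit, property and acceptance tests

random_er_graph <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  gd_graph(n, pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
}

# one random valid modification for g: removal of a present edge or
# addition of an absent pair, with roughly equal probability
random_modification <- function(g) {
  pres <- gd_edges(g)
  all_p <- which(upper.tri(matrix(0, g$n, g$n)), arr.ind = TRUE)
  akey <- paste(all_p[, 1], all_p[, 2])
  pkey <- if (nrow(pres)) paste(pres[, 1], pres[, 2]) else character(0)
  absent <- all_p[!(akey %in% pkey), , drop = FALSE]
  if ((stats::runif(1) < 0.5 && nrow(pres)) || nrow(absent) == 0) {
    e <- pres[sample.int(nrow(pres), 1), ]
    list(op = "-", u = e[[1]], v = e[[2]])
  } else {
    e <- absent[sample.int(nrow(absent), 1), ]
    list(op = "+", u = e[[1]], v = e[[2]])
  }
}

apply_sparse_delta <- function(counts, d) {
  if (nrow(d$delta))
    counts[cbind(d$delta$node, d$delta$orbit + 1)] <-
      counts[cbind(d$delta$node, d$delta$orbit + 1)] + d$delta$delta
  counts
}

# graph distances from a set of sources (unit edges, BFS)
bfs_distances <- function(g, sources) {
  dist <- rep(Inf, g$n)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(g$adj[frontier]))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}
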
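# Evolving-network generators: an initial static graph (Barabasi-Albert,
# Erdos-Renyi, or geometric) plus an ordered stream of single-edge
# modifications. Each step removes one present edge under the model's
# detachment rule and adds one absent edge under its attachment rule, so the
# edge count is conserved and the instantaneous graph stays plausible under
# the generating model. `degree_param` is the target mean degree for every
# model (ER: p = d/(n-1); BA: m = round(d/2) attachments per node;
# geometric: radius with expected interior degree d).

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

pair_id <- function(u, v, n) (pmin(u, v) - 1) * n + pmax(u, v)  # unordered key

gen_initial_er <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

gen_initial_ba <- function(n, m) {
  # growth with preferential attachment via the repeated-endpoint urn
  edges <- matrix(0L, 0L, 2L)
  urn <- 1L
  for (v in 2:n) {
    k <- min(m, v - 1L)
    targets <- unique(sample(urn, size = min(length(urn), 4L * k),
                             replace = TRUE))
    targets <- targets[targets != v][seq_len(min(k, sum(targets != v)))]
    if (length(targets) < k)
      targets <- union(targets,
                       setdiff(sample(v - 1L), targets)[seq_len(k - length(targets))])
    edges <- rbind(edges, cbind(as.integer(targets), v))
    urn <- c(urn, rep(v, length(targets)), targets)
  }
  edges
}

gen_initial_geo <- function(n, r, coords) {
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d) & d < r, arr.ind = TRUE)
  pairs
}

# rank jitter: 1 + Geometric(1/2), capped
jitter_rank <- function(k_max) min(1L + stats::rgeom(1L, 0.5), k_max)

#' Generate an evolving network
#'
#' @param model `"ba"`, `"er"`, or `"geo"`.
#' @param n number of nodes (>= 5).
#' @param degree_param target mean degree.
#' @param o number of modification steps (each one edge removal followed by
#'   one edge addition; the stream has `2 * o` records).
#' @param seed integer seed; the whole object is deterministic given it.
#' @return An object of class `evolving_network`: `initial` ([gd_graph()]),
#'   `mods` (data frame `op`, `u`, `v`), `model`, `n`, `degree_param`, `o`,
#'   `seed`.
#' @export
evolving_network <- function(model = c("ba", "er", "geo"), n, degree_param,
                             o, seed) {
  model <- match.arg(model)
  if (n < 5L) stop("evolving_network: n must be >= 5")
  if (o < 0L) stop("evolving_network: o must be >= 0")
  if (degree_param <= 0 || degree_param >= n)
    stop("evolving_network: degree_param out of range")
  with_local_seed(seed, {
    coords <- NULL
    edges <- switch(model,
      er = gen_initial_er(n, degree_param / (n - 1)),
      ba = gen_initial_ba(n, max(1L, as.integer(round(degree_param / 2)))),
      geo = {
        coords <- cbind(stats::runif(n), stats::runif(n))
        gen_initial_geo(n, sqrt(degree_param / (pi * (n - 1))), coords)
      })
    g <- gd_graph(n, edges)
    mods <- evolve_steps(g, model, o, coords)
    structure(list(initial = g, mods = mods, model = model, n = n,
                   degree_param = degree_param, o = as.integer(o),
                   seed = seed),
              class = "evolving_network")
  })
}

evolve_steps <- function(g, model, o, coords) {
  op <- character(0); us <- integer(0); vs <- integer(0)
  dmat <- if (model == "geo") as.matrix(stats::dist(coords)) else NULL
  for (step in seq_len(o)) {
    if (g$m == 0L) break
    e <- gd_edges(g)
    # --- detachment ---
    if (model == "geo") {
      ord <- order(dmat[e], decreasing = TRUE)
      pick <- e[ord[jitter_rank(nrow(e))], ]
    } else {
      pick <- e[sample.int(nrow(e), 1L), ]
    }
    g <- apply_modification(g, "-", pick[1L], pick[2L])
    op <- c(op, "-"); us <- c(us, pick[1L]); vs <- c(vs, pick[2L])
    # --- attachment ---
    add <- attach_edge(g, model, pick, dmat)
    g <- apply_modification(g, "+", add[1L], add[2L])
    op <- c(op, "+"); us <- c(us, add[1L]); vs <- c(vs, add[2L])
  }
  data.frame(op = op, u = us, v = vs, stringsAsFactors = FALSE)
}

attach_edge <- function(g, model, removed, dmat) {
  n <- g$n
  if (model == "er") {
    repeat {
      u <- sample.int(n, 1L); v <- sample.int(n, 1L)
      if (u != v && !has_edge(g, u, v)) return(c(u, v))
    }
  }
  if (model == "ba") {
    # keep one endpoint of the removed edge, re-attach it preferentially
    keep <- removed[sample.int(2L, 1L)]
    deg <- gd_degree(g)
    w <- deg + 1e-9
    w[keep] <- 0
    w[g$adj[[keep]]] <- 0
    if (all(w == 0)) {  # saturated neighbourhood: fall back to uniform
      cand <- setdiff(which(seq_len(n) != keep), g$adj[[keep]])
      return(c(keep, cand[sample.int(length(cand), 1L)]))
    }
    return(c(keep, sample.int(n, 1L, prob = w)))
  }
  # geo: closest currently-absent pair, with rank jitter
  cand_u <- integer(0); cand_v <- integer(0); cand_d <- numeric(0)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  present <- logical(n * n)
  e <- gd_edges(g)
  if (nrow(e)) present[pair_id(e[, 1L], e[, 2L], n)] <- TRUE
  absent <- !present[pair_id(ut[, 1L], ut[, 2L], n)]
  du <- ut[absent, , drop = FALSE]
  dd <- dmat[du]
  ord <- order(dd)
  pick <- du[ord[jitter_rank(nrow(du))], ]
  c(pick[1L], pick[2L])
}

#' @export
print.evolving_network <- function(x, ...) {
  cat(sprintf("evolving %s network: n=%d, target degree %.2f, %d steps (seed %s)\n",
              toupper(x$model), x$n, x$degree_param, x$o, format(x$seed)))
  invisible(x)
}

#' Replay an evolving network through both counters
#'
#' Replays the modification stream, recording for every step the number of
#' subgraphs visited by the incremental counter and by a full static
#' recount — the operation-count comparison behind the incremental method's
#' speedup (wall-clock is hardware-dependent and deliberately not asserted).
#' Count agreement between the two counters is verified at sampled
#' checkpoints and on the final state; disagreement is an integrity error.
#'
#' @param evo an [evolving_network()].
#' @param checkpoint_every verify incremental-vs-static count equality every
#'   this many steps (`Inf` = final state only).
#' @return A list: `per_step` (data frame `step`, `op`, `inc_visited`,
#'   `static_visited`), `final_counts` (`graphlet_counts`), `checkpoints`
#'   (number verified).
#' @export
benchmark_replay <- function(evo, checkpoint_every = Inf) {
  g <- evo$initial
  base <- count_graphlets(g)
  counts <- base$counts
  totals <- base$totals
  steps <- NROW(evo$mods)
  inc_v <- stat_v <- numeric(steps)
  ops <- character(steps)
  ncheck <- 0L
  if (steps) for (i in seq_len(steps)) {
    d <- count_delta(g, evo$mods$op[i], evo$mods$u[i], evo$mods$v[i])
    upd <- add_delta(counts, totals, d)
    counts <- upd$counts; totals <- upd$totals
    g <- apply_modification(g, evo$mods$op[i], evo$mods$u[i], evo$mods$v[i])
    stat <- count_graphlets(g)
    inc_v[i] <- d$visited
    stat_v[i] <- stat$visited
    ops[i] <- evo$mods$op[i]
    if (i %% checkpoint_every == 0 || i == steps) {
      if (!isTRUE(all.equal(unname(stat$counts), unname(counts))) ||
          !isTRUE(all.equal(unname(stat$totals), unname(totals))))
        stop("benchmark_replay: counter disagreement at step ", i,
             " (integrity error)")
      ncheck <- ncheck + 1L
    }
  }
  list(per_step = data.frame(step = seq_len(steps), op = ops,
                             inc_visited = inc_v, static_visited = stat_v),
       final_counts = count_object(counts, totals, NA_real_, g$labels),
       checkpoints = ncheck)
}

#' Parameter grid of the timing experiments
#'
#' The full-scale grid (n from 1000 to 16000, mean degree 2 to 64, 10000
#' time points) mirrors the published timing setup; desk-scale tests use
#' much smaller instances of the same models.
#'
#' @return Data frame with columns `model`, `n`, `degree_param`, `o`.
#' @export
evolving_grid <- function() {
  expand.grid(model = c("ba", "er", "geo"),
              n = c(1000L, 2000L, 4000L, 8000L, 16000L),
              degree_param = c(2, 4, 8, 16, 32, 64),
              o = 10000L, stringsAsFactors = FALSE)
}
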
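test_that("delta matches the closed-form small cases", {
  # two isolated nodes: adding the edge creates exactly one G0
  g <- gd_graph(2)
  d <- count_delta(g, "+", 1, 2)
  expect_equal(d$delta$delta, c(1, 1))
  expect_equal(d$delta$orbit, c(0, 0))
  expect_equal(unname(d$totals["G0"]), 1)
  expect_equal(sum(d$totals != 0), 1)

  # closing a 3-path into a triangle
  p3 <- gd_graph(3, rbind(c(1, 2), c(2, 3)))
  d <- count_delta(p3, "+", 1, 3)
  expect_equal(unname(d$totals[c("G0", "G1", "G2")]), c(1, -1, 1))
  dd <- d$delta
  get <- function(node, orbit) {
    hit <- dd$delta[dd$node == node & dd$orbit == orbit]
    if (length(hit)) hit else 0
  }
  for (end in c(1, 3)) {
    expect_equal(get(end, 0), 1)
    expect_equal(get(end, 1), -1)
    expect_equal(get(end, 3), 1)
  }
  expect_equal(get(2, 2), -1)
  expect_equal(get(2, 3), 1)
})

test_that("delta enforces the modification preconditions", {
  tri <- make_toy_graph("triangle")
  expect_error(count_delta(tri, "+", 1, 2), "ADD on existing")
  expect_error(count_delta(gd_graph(3), "-", 1, 2), "REMOVE on absent")
})

test_that("delta is exact and reversible on random instances", {
  set.seed(303)
  for (rep in 1:60) {
    g <- random_er_graph(sample(5:25, 1), runif(1, 0.05, 0.6))
    mod <- random_modification(g)
    before <- count_graphlets(g)
    d <- count_delta(g, mod$op, mod$u, mod$v)
    g2 <- apply_modification(g, mod$op, mod$u, mod$v)
    after <- count_graphlets(g2)
    expect_equal(apply_sparse_delta(before$counts, d), after$counts)
    expect_equal(before$totals + d$totals, after$totals)
    # reversibility: the opposite modification cancels exactly
    d2 <- count_delta(g2, if (mod$op == "+") "-" else "+", mod$u, mod$v)
    expect_equal(d$totals + d2$totals, d$totals * 0)
    both <- merge(d$delta, d2$delta, by = c("node", "orbit"), all = TRUE)
    both[is.na(both)] <- 0
    expect_true(all(both$delta.x + both$delta.y == 0))
  }
})

test_that("delta support stays within distance 3 of the endpoints", {
  set.seed(31)
  for (rep in 1:30) {
    g <- random_er_graph(sample(10:30, 1), runif(1, 0.05, 0.2))
    mod <- random_modification(g)
    gp <- if (mod$op == "+") apply_modification(g, "+", mod$u, mod$v) else g
    d <- count_delta(g, mod$op, mod$u, mod$v)
    if (!nrow(d$delta)) next
    dist <- bfs_distances(gp, c(mod$u, mod$v))
    expect_true(all(dist[unique(d$delta$node)] <= 3))
  }
})

test_that("changed_sets yields each changed set exactly once", {
  # isolated edge
  g <- gd_graph(2, rbind(c(1, 2)))
  expect_equal(changed_sets(g, 1, 2), list(c(1L, 2L)))
  # triangle
  tri <- make_toy_graph("triangle")
  cs <- changed_sets(tri, 1, 2)
  expect_setequal(lapply(cs, paste, collapse = ","), list("1,2", "1,2,3"))
  # K5: all supersets of the edge within the clique
  expect_length(changed_sets(make_toy_graph("K5"), 1, 2), 8L)
  expect_error(changed_sets(gd_graph(3), 1, 2), "not present")
  # uniqueness and membership on random instances
  set.seed(41)
  for (rep in 1:30) {
    g <- random_er_graph(sample(8:20, 1), runif(1, 0.1, 0.4))
    e <- gd_edges(g)
    if (!nrow(e)) next
    pick <- e[sample.int(nrow(e), 1), ]
    cs <- changed_sets(g, pick[[1]], pick[[2]])
    keys <- vapply(cs, paste, "", collapse = ",")
    expect_equal(anyDuplicated(keys), 0L)
    expect_true(all(vapply(cs, function(s)
      all(c(pick[[1]], pick[[2]]) %in% s), logical(1))))
    expect_true(all(lengths(cs) <= 5))
  }
})

test_that("incremental work is bounded by the static enumeration", {
  set.seed(47)
  for (rep in 1:20) {
    g <- random_er_graph(sample(10:30, 1), runif(1, 0.1, 0.3))
    mod <- random_modification(g)
    d <- count_delta(g, mod$op, mod$u, mod$v)
    stat <- count_graphlets(if (mod$op == "+")
      apply_modification(g, "+", mod$u, mod$v) else g)
    expect_lte(d$visited, stat$visited)
  }
  # strict whenever edges exist outside the modified edge's ball: two
  # components, modify inside one
  g <- gd_graph(8, rbind(c(1, 2), c(2, 3), c(5, 6), c(6, 7), c(7, 8)))
  d <- count_delta(g, "+", 1, 3)
  stat <- count_graphlets(apply_modification(g, "+", 1, 3))
  expect_lt(d$visited, stat$visited)
})

test_that("replay accumulates deltas to the exact final counts", {
  g <- gd_graph(3)
  empty <- replay_modifications(g, NULL)
  expect_equal(empty$counts_obj$counts, count_graphlets(g)$counts)

  mods <- data.frame(op = c("+", "+", "+"), u = c(1, 2, 1), v = c(2, 3, 3))
  r <- replay_modifications(g, mods, verify_final = TRUE)
  expect_equal(unname(r$counts_obj$totals[c("G0", "G2")]), c(3, 1))

  set.seed(53)
  g <- random_er_graph(15, 0.2)
  ops <- list()
  gg <- g
  for (i in 1:150) {
    m <- random_modification(gg)
    ops[[i]] <- m
    gg <- apply_modification(gg, m$op, m$u, m$v)
  }
  mods <- do.call(rbind, lapply(ops, as.data.frame))
  r <- replay_modifications(g, mods)
  ref <- count_graphlets(gg)
  expect_equal(r$counts_obj$counts, ref$counts)
  expect_equal(r$counts_obj$totals, ref$totals)
})

test_that("replay reports the offending step of a corrupted stream", {
  g <- gd_graph(3)
  mods <- data.frame(op = c("+", "+"), u = c(1, 1), v = c(2, 2))
  expect_error(replay_modifications(g, mods), "step 2")
})
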
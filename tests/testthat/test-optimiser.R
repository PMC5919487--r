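test_that("redundancy penalty matches closed forms", {
  path <- make_toy_graph("path")
  expect_equal(redundancy_penalty(count_graphlets(path)$totals), 0)
  tri <- make_toy_graph("triangle")
  expect_equal(redundancy_penalty(count_graphlets(tri)$totals), 1)
  k4 <- make_toy_graph("K4")
  expect_equal(redundancy_penalty(count_graphlets(k4)$totals), 7)
  expect_error(redundancy_penalty(1:5), "30")
})

test_that("penalty_increase equals the static penalty difference", {
  # joining two components creates only tree graphlets
  g <- gd_graph(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(penalty_increase(g, 2, 3), 0)
  # closing a triangle on an isolated 3-path
  p3 <- gd_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(penalty_increase(p3, 1, 3), 1)
  # final edge of K5, checked against the brute static difference
  k5m <- gd_graph(5, t(utils::combn(5, 2))[-1, ])
  before <- redundancy_penalty(count_graphlets_brute(k5m)$totals)
  after <- redundancy_penalty(count_graphlets_brute(make_toy_graph("K5"))$totals)
  expect_equal(penalty_increase(k5m, 1, 2), after - before)
  expect_error(penalty_increase(p3, 1, 2), "already present")
})

test_that("penalty accumulation is independent of the build order", {
  set.seed(71)
  for (rep in 1:20) {
    g <- random_er_graph(sample(6:15, 1), runif(1, 0.2, 0.6))
    target <- redundancy_penalty(count_graphlets(g)$totals)
    e <- gd_edges(g)
    if (nrow(e) < 2) next
    ord <- sample(nrow(e))
    gg <- gd_graph(g$n)
    acc <- 0
    for (i in ord) {
      acc <- acc + penalty_increase(gg, e[i, 1], e[i, 2])
      gg <- apply_modification(gg, "+", e[i, 1], e[i, 2])
    }
    expect_equal(acc, target)
  }
})

test_that("grow accepts in rank order when all increases are equal", {
  ranked <- data.frame(source = c("a", "b", "c", "d"),
                       target = c("b", "c", "d", "e"),
                       score = c(4, 3, 2, 1))
  grown <- grow_network(ranked)
  expect_equal(grown$accepted$rank_in, 1:4)
  expect_equal(grown$accepted$penalty_increase, rep(0, 4))
})

test_that("grow defers a clique-closing edge behind an independent edge", {
  # after a-b and a-c are in, b-c closes a triangle; with x-y in the window
  # the 90th-percentile gate passes the penalty-free candidates first
  ranked <- data.frame(source = c("a", "a", "b", "x"),
                       target = c("b", "c", "c", "y"),
                       score = c(4, 3, 2, 1))
  grown <- grow_network(ranked, optimiser_config(k = 4))
  keys <- paste(grown$accepted$source, grown$accepted$target)
  expect_equal(keys, c("a b", "a c", "x y", "b c"))
  expect_equal(grown$accepted$penalty_increase[4], 1)
})

test_that("grow respects budget, uniqueness, and prefix structure", {
  set.seed(77)
  fx <- make_planted_grn(seed = 3)
  one <- grow_network(fx$ranked, optimiser_config(budget = 1))
  expect_equal(nrow(one$accepted), 1L)
  expect_equal(one$accepted$rank_in, 1L)
  grown <- grow_network(fx$ranked, optimiser_config(budget = 40))
  keys <- paste(grown$accepted$source, grown$accepted$target)
  expect_equal(anyDuplicated(keys), 0L)
  # a permutation of a prefix of the pending window's reach
  expect_true(all(grown$accepted$rank_in <=
                    40 + optimiser_config()$k))
  expect_equal(grown$graph$m, 40L)
  expect_error(grow_network(fx$ranked[0, ]), "empty")
})

test_that("optimiser config validates its domain", {
  expect_error(optimiser_config(k = 0), "k must be")
  expect_error(optimiser_config(percentile = 100), "percentile")
  expect_error(optimiser_config(percentile = 0), "percentile")
})

test_that("evaluate_f1 behaves at the extremes and under permutation", {
  pairs <- data.frame(source = sprintf("a%03d", 1:200),
                      target = sprintf("b%03d", 1:200))
  gold <- pairs[1:60, ]
  perfect <- data.frame(pairs, score = c(rep(2, 60), rep(1, 140))[1:200])
  perfect$score <- seq(200, 1)
  r <- evaluate_f1(perfect, gold, top = 200)
  expect_equal(r$auroc, 1)
  expect_equal(r$aupr, 1)
  expect_equal(r$f1, 1)
  inverted <- perfect
  inverted$score <- seq_len(200)
  expect_equal(evaluate_f1(inverted, gold, top = 200)$auroc, 0)
  # permutation null: AUROC concentrates at 1/2
  set.seed(83)
  aurocs <- replicate(20, {
    perm <- perfect
    perm$score <- sample(perm$score)
    evaluate_f1(perm, gold, top = 200)$auroc
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
  expect_error(evaluate_f1(perfect, pairs[0, ], top = 100), "undefined")
})

test_that("ranked lists are canonicalised (undirected, deduplicated, sorted)", {
  ranked <- data.frame(source = c("b", "a", "c", "c"),
                       target = c("a", "b", "d", "c"),
                       score = c(3, 5, 4, 9))
  norm <- graphletdelta:::normalise_ranked(ranked)
  expect_equal(nrow(norm), 2L)           # self-pair dropped, duplicate merged
  expect_equal(norm$score, c(5, 4))      # best score kept, descending
  expect_equal(norm$source[1], "a")
})
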
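test_that("catalogue has the full 2-5-node taxonomy", {
  cat <- graphlet_catalogue()
  expect_equal(nrow(cat$graphlets), 30L)
  expect_equal(nrow(cat$orbits), 73L)
  expect_equal(cat$graphlets$id, 0:29)
  expect_equal(cat$orbits$orbit, 0:72)
  expect_equal(unname(table(cat$graphlets$size)), c(1L, 2L, 6L, 21L),
               ignore_attr = TRUE)
  # orbit ids within a graphlet are contiguous and graphlet-ordered
  expect_true(all(diff(cat$orbits$graphlet) >= 0))
  # every graphlet induces a connected graph
  for (cl in cat$classes)
    expect_true(graphletdelta:::mask_connected(cl$mask, cl$size))
})

test_that("numbering anchors match the standard taxonomy", {
  cat <- graphlet_catalogue()
  gl <- cat$graphlets
  expect_equal(gl$edges[gl$id == 0], "0-1")             # G0 = edge, O0
  expect_equal(gl$orbits[gl$id == 0], "0,0")
  expect_equal(sort(gl$orbits[gl$id == 2]), "3,3,3")    # triangle = G2/O3
  # 3-path: ends O1, middle O2
  p3 <- classify_mask(3L, 3L)                           # edges 0-1, 0-2
  expect_equal(p3$graphlet, 1L)
  expect_equal(sort(p3$orbits), c(1L, 1L, 2L))
  expect_equal(p3$orbits[1], 2L)                        # position 0 = middle
  # K5 = G29 with every position in O72
  k5 <- classify_mask(1023L, 5L)
  expect_equal(k5$graphlet, 29L)
  expect_equal(k5$orbits, rep(72L, 5))
})

test_that("classification is complete over every mask", {
  ids <- integer(0)
  for (s in 2:5) {
    lk <- graphletdelta:::gd_taxonomy()$lookup[[s]]
    expect_length(lk$graphlet, 2^choose(s, 2))
    expect_equal(lk$graphlet[1], -1L)   # mask 0 disconnected for all sizes
    ids <- c(ids, unique(lk$graphlet[lk$graphlet >= 0]))
  }
  s5 <- graphletdelta:::gd_taxonomy()$lookup[[5]]$graphlet
  expect_equal(length(unique(s5[s5 >= 0])), 21L)
  expect_equal(sort(ids), 0:29)
})

test_that("classification is invariant to position permutation", {
  set.seed(101)
  for (rep in 1:1000) {
    s <- sample(2:5, 1)
    mask <- sample.int(2^choose(s, 2), 1) - 1L
    perm <- sample(s)
    cl <- classify_mask(mask, s)
    # permute the mask: edge (i,j) -> (perm[i], perm[j])
    pt <- graphletdelta:::pair_table(s)
    pmask <- 0L
    for (r in seq_len(nrow(pt))) {
      if (bitwAnd(bitwShiftR(mask, r - 1L), 1L) == 1L) {
        a <- perm[pt[r, 1] + 1L] - 1L
        b <- perm[pt[r, 2] + 1L] - 1L
        pmask <- pmask + bitwShiftL(1L, graphletdelta:::pair_rank(min(a, b), max(a, b), s))
      }
    }
    pcl <- classify_mask(pmask, s)
    expect_identical(pcl$graphlet, cl$graphlet)
    if (cl$connected) expect_identical(pcl$orbits[perm], cl$orbits)
  }
})

test_that("each position has exactly one orbit and orbits partition positions", {
  cat <- graphlet_catalogue()
  for (cl in cat$classes) {
    expect_length(cl$orbit_global, cl$size)
    expect_true(all(cl$orbit_global %in% cl$orbit_ids))
    expect_setequal(unique(cl$orbit_global), cl$orbit_ids)
  }
})

test_that("redundancy is edges minus spanning-tree edges, zero iff tree", {
  expect_equal(graphlet_redundancy(0L), 0L)
  expect_equal(graphlet_redundancy(2L), 1L)
  expect_equal(graphlet_redundancy(29L), 6L)
  gl <- graphlet_catalogue()$graphlets
  expect_equal(gl$redundancy, gl$n_edges - (gl$size - 1L))
  expect_equal(gl$redundancy == 0L, gl$n_edges == gl$size - 1L)
  expect_error(graphlet_redundancy(30L), "out of range")
  expect_error(graphlet_redundancy(-1L), "out of range")
})

test_that("edge_mask follows the documented pair ranking", {
  no_edge <- function(a, b) FALSE
  all_edge <- function(a, b) TRUE
  expect_equal(edge_mask(1:5, no_edge), 0L)
  expect_equal(edge_mask(1:5, all_edge), 1023L)
  expect_equal(edge_mask(1:2, all_edge), 1L)
  # pair (0,1) is the low bit, pairs lexicographic
  g <- make_toy_graph("path")  # 1-2-3-4
  adj <- function(a, b) has_edge(g, a, b)
  expect_equal(edge_mask(c(1, 2, 3), adj), 1L + 4L)  # edges (0,1),(1,2)
  expect_error(edge_mask(1L, all_edge), "size")
  expect_error(edge_mask(1:6, all_edge), "size")
  expect_error(edge_mask(c(1, 1), all_edge), "distinct")
})

test_that("classify_mask validates its domain", {
  expect_error(classify_mask(-1L, 3L), "out of range")
  expect_error(classify_mask(8L, 3L), "out of range")
  expect_error(classify_mask(0L, 6L), "size")
  expect_false(classify_mask(0L, 4L)$connected)
})

test_that("catalogue matches the shipped reference dump", {
  ref <- read.table(system.file("extdata", "graphlet_catalogue.tsv",
                                package = "graphletdelta"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(graphlet_catalogue()$graphlets, ref, ignore_attr = TRUE)
})
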
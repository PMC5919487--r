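# Programmatic fixtures: named toy graphs used across the test suite, and
# the planted gene-regulatory-network generator that emulates the failure
# mode the redundancy criterion targets — a sparse scale-free true network
# whose predicted ranking is contaminated by densely interconnected
# false-positive modules around hub genes.

#' Named toy graphs
#'
#' @param name one of `"edge"`, `"path"` (4-node path), `"triangle"`,
#'   `"C4"`, `"C5"`, `"K4"`, `"K5"`, `"star"` (centre plus 10 leaves).
#' @return A [gd_graph()].
#' @export
make_toy_graph <- function(name = c("edge", "path", "triangle", "C4", "C5",
                                    "K4", "K5", "star")) {
  name <- match.arg(name)
  cyc <- function(k) cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
  switch(name,
    edge = gd_graph(2L, rbind(c(1L, 2L))),
    path = gd_graph(4L, cbind(1:3, 2:4)),
    triangle = gd_graph(3L, cyc(3L)),
    C4 = gd_graph(4L, cyc(4L)),
    C5 = gd_graph(5L, cyc(5L)),
    K4 = gd_graph(4L, t(utils::combn(4L, 2L))),
    K5 = gd_graph(5L, t(utils::combn(5L, 2L))),
    star = gd_graph(11L, cbind(1L, 2:11)))
}

#' Planted gene-regulatory-network fixture
#'
#' Emulates a GENIE3-style predicted ranking of an organism's regulatory
#' network: the true network is a sparse preferential-attachment (scale-free)
#' graph; the ranked candidate list mixes the true edges (high scores plus
#' noise) with clusters of false-positive edges that densely interconnect
#' hub neighbourhoods — the "highly connected subnetworks" of predicted
#' networks — plus diffuse low-scoring decoys.
#'
#' @param n_genes number of genes (default 100).
#' @param n_hub_modules number of hub-centred false-positive cliques
#'   (default 3).
#' @param module_size genes per false-positive module (default 12); hub
#'   neighbourhoods smaller than this are padded with the next
#'   highest-degree genes, mimicking co-regulated target sets.
#' @param n_decoys number of diffuse low-score decoy pairs (default 300).
#' @param seed integer seed; the fixture is deterministic given it.
#' @return A list: `ranked` (data frame `source`, `target`, `score`),
#'   `gold` (data frame of true interactions), `n_genes`, `seed`.
#' @export
make_planted_grn <- function(n_genes = 100L, n_hub_modules = 3L,
                             module_size = 12L, n_decoys = 300L, seed = 1L) {
  with_local_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    true_e <- gen_initial_ba(n_genes, 1L)          # scale-free tree
    deg <- tabulate(c(true_e[, 1L], true_e[, 2L]), nbins = n_genes)
    hubs <- order(deg, decreasing = TRUE)[seq_len(n_hub_modules)]
    # false-positive modules: clique over each hub neighbourhood (padded
    # with further hub genes), the densely interconnected subnetworks that
    # tree-ensemble predictors hallucinate among co-regulated genes
    fp <- matrix(0L, 0L, 2L)
    for (h in hubs) {
      memb <- unique(c(h, true_e[true_e[, 1L] == h, 2L],
                       true_e[true_e[, 2L] == h, 1L]))
      extra <- setdiff(order(deg, decreasing = TRUE), memb)
      if (length(memb) < module_size)
        memb <- c(memb, extra[seq_len(module_size - length(memb))])
      memb <- memb[seq_len(module_size)]
      fp <- rbind(fp, t(utils::combn(memb, 2L)))
    }
    key <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    fp <- fp[!duplicated(key(fp)), , drop = FALSE]
    fp <- fp[!(key(fp) %in% key(true_e)), , drop = FALSE]
    decoys <- cbind(sample.int(n_genes, n_decoys, TRUE),
                    sample.int(n_genes, n_decoys, TRUE))
    decoys <- decoys[decoys[, 1L] != decoys[, 2L], , drop = FALSE]
    decoys <- decoys[!(key(decoys) %in% c(key(true_e), key(fp))), ,
                     drop = FALSE]
    ranked <- data.frame(
      source = genes[c(true_e[, 1L], fp[, 1L], decoys[, 1L])],
      target = genes[c(true_e[, 2L], fp[, 2L], decoys[, 2L])],
      score = c(stats::rnorm(nrow(true_e), 0.75, 0.10),
                stats::rnorm(nrow(fp), 0.65, 0.08),
                stats::rnorm(nrow(decoys), 0.40, 0.12)),
      stringsAsFactors = FALSE)
    ranked <- normalise_ranked(ranked)
    gold <- data.frame(source = genes[true_e[, 1L]],
                       target = genes[true_e[, 2L]], stringsAsFactors = FALSE)
    list(ranked = ranked, gold = gold, n_genes = n_genes, seed = seed)
  })
}
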
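# graphletdelta

Exact, incremental counting of graphlet and orbit occurrences in undirected
networks, and a graphlet-redundancy criterion for growing ranked
gene-regulatory networks.

## The problem

Graphlets — the 30 connected simple graphs on 2–5 nodes, G0…G29 — and
their 73 node orbits O0…O72 summarise the local topology around every node
of a network as an *n* × 73 count matrix *C*, where *C*[i, j] is the number
of connected induced subgraphs in which node *i* occupies orbit O_j.
Topology-optimisation loops (for instance, post-processing a predicted
gene-regulatory network) need these counts after *millions* of single-edge
changes, and recounting from scratch each time is intractable. Because
every subgraph whose count changes contains both endpoints of the modified
edge, the signed difference

```
C[G'] = C[G] + Δ(G, G')
```

can be computed by exploring only the modified edge's depth-3
neighbourhood, enumerating each changed subgraph exactly once, and
classifying its node set with and without the modified edge via an
edge-mask lookup table. That incremental counter, its static baseline and
brute-force oracle, evolving Barabási–Albert / Erdős–Rényi / geometric
network generators, and a redundancy-gated procedure that grows a network
from a ranked interaction list are all implemented here, with the hot
enumeration paths in C++ (Rcpp).

The redundancy of a graphlet is `edges − (size − 1)` — the edges removable
without disconnecting it (0 for trees, 6 for the 5-clique). The redundancy
penalty of a network, Σ_g occurrences(g) × redundancy(g), prices the
densely interconnected false-positive modules typical of predicted
regulatory networks; ranked interactions are accepted only while their
penalty increase stays below the 90th-percentile gate over the current
k = 100 candidate window.

## Worked example

Closing the triangle on a 3-path `1–2–3`:

```r
library(graphletdelta)
g <- gd_graph(3, rbind(c(1, 2), c(2, 3)))
d <- count_delta(g, "+", 1, 3)
d$totals[d$totals != 0]
#> G0 G1 G2
#>  1 -1  1
```

One edge appears (G0 +1), the 3-path becomes a triangle (G1 −1, G2 +1);
the per-node orbit rows move accordingly (ends: O0+1, O1−1, O3+1; middle:
O2−1, O3+1). On an evolving 100-node Erdős–Rényi network the incremental
counter visits ~1–3 thousand subgraphs per step while a static recount
visits ~150 thousand:

```r
evo <- evolving_network("er", 100, 6, o = 5, seed = 1)
b <- benchmark_replay(evo)
mean(b$per_step$static_visited / b$per_step$inc_visited)
#> [1] 102.7
```

Reranking a synthetic predicted regulatory network (sparse scale-free
truth + hub-clique false positives) with the redundancy gate:

```r
fx <- make_planted_grn(seed = 1)
res <- optimise_and_evaluate(fx$ranked, fx$gold, top = 150)
c(raw = res$raw$f1, reranked = res$reranked$f1)
#>      raw reranked
#>    0.786    0.800
```

F1 is the harmonic mean of AUROC and AUPR over the leading interactions;
the gate defers clique-closing false positives, so the reranked prefix
recovers more true interactions.

A command-line interface wraps the same operations
(`inst/scripts/graphletdelta`): subcommands `count`, `delta`, `generate`,
`optimise`, `fixture`; logs to stderr, machine output to files; exit codes
0 / 1 / 2 (success / usage or parse error / verification mismatch).

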
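---
title: "CumulativeRank: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CumulativeRank: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumrank)
```

## The problem

In an undirected contact network — people linked by communication,
collaboration or physical contact — a handful of nodes act as
*super-spreaders*: seeding an epidemic or a rumour at these nodes yields a
disproportionately large final outbreak. Purely local indices (degree) are
cheap but myopic; purely global ones (betweenness, eigenvector centrality)
are accurate but too expensive for networks with millions of nodes.
CumulativeRank (CR) aims at the middle ground: it combines a **semi-local**
structural-hole score with a **global connectivity** score, both computable
in roughly `O(n <k>^2 + n^2)` time.

A node is a good spreader under CR when it simultaneously

* bridges otherwise-unconnected parts of its extended neighbourhood
  (low *improved network constraint*), and
* occupies a position whose removal would shatter the network
  (low *tenacity*).

Low scores mean high influence throughout; CR ranks ascending.

## Step 1 — local advantage: from LocalRank to INCC

For each node `v` define the exact integer counts

* `N_v` — number of distinct nodes within two steps of `v` (excluding `v`),
* `Q_v = sum_{w in Gamma(v)} N_w`,
* `LR_v = sum_{j in Gamma(v)} Q_j` (LocalRank).

Burt's network constraint coefficient,

```
NCC_v = sum_{j in Gamma(v)} ( p_vj + sum_k p_vk p_kj )^2 ,   p_vj = 1/deg(v),
```

measures how concentrated `v`'s ties are; the inner sum runs over common
neighbours `k` of `v` and `j` (for any other `k` one of the two factors is
zero). NCC sees only the first ring, so two bridges with identical local
tie patterns but very different second rings get identical scores. The
improved coefficient replaces the uniform tie proportions with semi-local
weights:

```
INCC_v = sum_{j in Gamma(v)} ( p'_vj + sum_k p'_vk p'_kj )^2 ,
p'_uw = Q_w / LR_u  for an edge {u, w}, 0 otherwise.
```

A leaf always has `NCC = INCC = 1` (a single tie, `p = 1`, no indirect
term), which is also the maximum attainable on the 15-node example
network. The implementation enumerates only common-neighbour
intersections, giving the advertised `O(n <k>^2)` average cost, and keeps
`N`, `Q`, `LR` as exact integers so the constraint scores carry no
accumulated floating-point error.

One worked-example subtlety: on the bundled [example_network()], every
published per-node value (N, Q, LR, NCC, all CR cells) is reproduced
exactly at printed precision, except the INCC cell of the hub node G,
which the published table gives as 0.328 while the defining formula —
cross-checked against an exhaustive enumeration of all length-1 and
length-2 `p'`-paths — yields 0.327189. No alternative reading of the
formula reproduces 0.328 without breaking several other cells, so the
package keeps the formula value and the test suite records the printed
cell as a known discrepancy. The downstream CR value of G (0.047) is
unaffected at printed precision.

## Step 2 — global advantage: key nodes and tenacity

Key nodes are found with the classical depth-first `dfn`/`low` rule: a
node is key if it is a root with two or more tree children, or has a tree
child whose `low` value is at least the node's `dfn` — exactly the
articulation points. The traversal is **iterative** (explicit stack), a
hard design requirement here: recursive DFS overflows on deep graphs,
while the iterative version handles a path of 100,000 nodes in the test
suite.

Each node's tenacity is

```
R_v = (1 + m(G - v)) / w(G - v)
```

with `m` the largest-component size and `w` the component count after
deleting `v`. The defining expression is sometimes written with a
`min{...}` and a side condition `w >= 2`; we evaluate it as a plain
per-node value with no exclusion — removing a non-cut node of a connected
graph leaves `w = 1` and `m = n - 1`, so `R_v = n`. This is the only
reading consistent with every published per-node value on the example
network (all ten non-cut nodes have `R = 15`). The key-node set is used as
a shortcut: on connected input only articulation points need an explicit
component recount; everyone else gets `R = n` directly. On disconnected
input the formula is evaluated literally for every node (global giant,
all components counted).

`TC_v` is the min–max normalization of `R` to `[0, 1]`. When **all** `R`
are equal (regular biconnected graphs such as complete graphs) the
normalization is 0/0; we define `TC = 0` for every node, so CR degrades
gracefully to its local term. That convention is ours — the degenerate
case has no published prescription.

## Step 3 — the combination, and a normalization inconsistency

The published combination rule is written with root-sum denominators,

```
CR_v = INCC_v / sqrt(sum_j INCC_j) + TC_v / sqrt(sum_j TC_j),
```

but evaluated that way it does **not** reproduce the published per-node CR
column of the worked example (it gives CR_H = 0.093 where 0.027 is
printed). Plain-sum denominators,

```
CR_v = INCC_v / sum_j INCC_j + TC_v / sum_j TC_j,
```

reproduce every printed CR cell to 3 decimals. Both claims are asserted
as tests; `normalization = "sum"` is the frozen default and `"sqrt"` is
kept behind the flag. Both modes agree on the top node. Since each term
of the sum-normalized CR is a share of a fixed budget, `CR` scales like
`1/n`; meaningful differences between nodes shrink with network size.
For that reason ranks group ties by *numerical equality* (within `1e-9`),
not at a fixed decimal precision: on the worked example the published tie
groups (I = J and L = M = N = O) are exact arithmetic ties anyway, while
on graphs of a few hundred nodes rounding CR to 3 decimals would collapse
most of the ranking into spurious ties. Inside a tied group, `top_k()`
breaks ties lexicographically by label — an arbitrary but deterministic
rule that keeps SIR seeding reproducible.

Benchmark rankings (`dc`, `bc`, `ec`, `lr`, `pr`) rank descending.
Eigenvector centrality is computed by power iteration on the shifted
operator `A + I` — the shift leaves the principal eigenvector unchanged
and guarantees convergence on bipartite graphs, where iterating `A`
alone oscillates — scaled to unit max-norm, with convergence tolerance
`1e-13` on the max-norm change. PageRank uses damping 0.85 on the
bidirected reading of the graph (each undirected edge carries rank both
ways; out-degree = degree), iterated to max-change below `1e-10`, at most
1000 sweeps, with dangling mass redistributed uniformly. Both agree with
the independent igraph implementations to `1e-8` in the test suite;
betweenness *is* delegated to igraph and cross-checked against a
hand-written shortest-path-counting oracle.

## The SIR evaluation harness

The simulator is the discrete-time **all-contact** SIR process. Per step,
synchronously:

1. every currently infected node contacts each susceptible neighbour
   independently with infection probability `beta`; a susceptible with
   `j` infected neighbours is infected with probability
   `1 - (1 - beta)^j`;
2. every node infected *before* this step recovers with probability
   `gamma` (default 0.3, the standard protocol value here).

Newly infected nodes neither transmit nor recover in their infection
step. This update order is a modelling choice (the protocol leaves it
unstated); we chose it because it makes `beta = gamma = 1` an exact BFS
wave — the final scope is the seed's component and the convergence time
is eccentricity + 1 — which in turn gives sharp test oracles. Whether
recovery may hit same-step infections is a genuine ambiguity; our
convention is documented, not inferred.

The spreading scope is `F(t) = (n_I(t) + n_R(t))/n`; it is nondecreasing,
starts at `|seeds|/n` and its terminal value `F(t_c)` (the recovered
fraction once no infected remain) measures the seed set's spreading
ability. Replicates use per-run derived seeds (`rng_seed + run index`),
so aggregates are bit-reproducible and enlarging `runs` never perturbs
earlier replicates. `max_steps = 10 n` is a pure runaway guard; with
`gamma > 0` the process terminates almost surely far earlier.

The recommended operating point is `beta` slightly above the
heterogeneous mean-field threshold `beta_th = <k>/<k^2>`
([epidemic_threshold()]); `compare_seed_sets()` defaults to
`1.5 * beta_th`. A caveat worth knowing: `beta_th` ignores the infectious
*period*. With mean period `1/gamma ≈ 3.3` steps the per-edge
transmissibility at `beta = 1.5 beta_th` can be deeply supercritical on
small synthetic graphs, driving the final scope toward saturation — and
in that regime ten *dispersed* random seeds can slightly outperform ten
clustered hub seeds, because the hubs' spheres of influence overlap. The
test suite documents exactly this on a 500-node Barabási–Albert graph:
single-seed comparisons behave as expected (hub ≫ random), while the
ten-seed comparison at `1.5 * beta_th` inverts. Seed-set quality is only
informative near the *effective* transmissibility threshold, i.e. where
final scopes stay well below saturation.

## What the synthetic generators emulate — and what they do not

`generate_synthetic()` provides Erdős–Rényi `G(n, p)` graphs (sparse
homogeneous contact structure; used for the oracle-equivalence property
suites at `n <= 30`) and Barabási–Albert graphs (heavy-tailed degrees,
the qualitative signature of the social networks this method targets;
used at `n = 500` for the seed-set evaluation). Neither reproduces the
high clustering, community structure or degree correlations of real
social networks, and desk-scale sizes keep `beta_th` orders of magnitude
larger than in empirical networks of `10^4`–`10^5` nodes. Passing the
property suites therefore certifies the *algorithms* (every score equals
its brute-force oracle; the simulator has the right limits, conservation
laws and couplings), not the empirical claim that CR-selected seeds beat
other centralities' seeds on real networks — evaluating that requires the
real edge lists, which the harness reads via `read_edge_list()` but which
are not bundled.

## Numerical and degenerate-input conventions

* Comparisons against printed values use round-half-up at the printed
  precision (R's `round()` rounds half to even).
* Isolated (degree-0) nodes: constraint scores are undefined; per-node
  `ncc()`/`incc()` raise an error, `local_scores()` flags the row and
  stores `NA`, and `cumulative_rank()` ranks such nodes last with a
  warning rather than inventing a score.
* Disconnected graphs: characteristic path length averages over connected
  pairs only; eigenvector centrality is computed on the largest component
  (others score 0, with a message); tenacity is evaluated literally.
* Self-loops and repeated edge lines in input files are sanitized (with a
  warning counting drops), not rejected — public edge-list archives
  contain both.
* Edge-list tokens beyond the second are ignored, so weighted files load;
  weights are never used.

## Problem sizes used by the bundled checks

The test suite exercises: the 15-node worked example (exact published
values); ~450 random graphs of 5–30 nodes against brute-force oracles;
a 100,000-node path (iterative DFS depth robustness); and SIR property
checks with 1,500–2,000 replicates on the worked example plus 200-replicate
seed-set comparisons on a 500-node Barabási–Albert graph. These sizes keep
the full suite near a minute on one CPU while leaving every algorithmic
claim oracle-checked.

## Known limitations

* FA-style hybrid ranking (k-shell entropy × local degree sum) is not
  implemented: its entropy component is defined only in secondary
  literature and guessing it would silently diverge from published
  comparisons.
* Directed and weighted spreading, SIS/SEIR variants, and continuous-time
  (Gillespie) dynamics are out of scope.
* Whole-graph tenacity over vertex cut *sets* is not implemented — only
  the per-node variant used by CR.
* CR's global term is blind on biconnected graphs (all `TC = 0`), where
  the method is INCC alone by construction.
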
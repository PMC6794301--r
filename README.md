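# cumrank

Identifying and quantifying potential super-spreaders in undirected
contact networks with the **CumulativeRank** (CR) algorithm, plus a
discrete-time SIR harness for evaluating how well any ranking actually
seeds an epidemic or an information cascade.

## Who this is for

Network epidemiologists and computational social scientists who need to
pick the `k` most potent initial spreaders in a contact / communication
graph, at a cost that scales to large networks (`O(n <k>^2 + n^2)` rather
than the `O(n^3)` of eigenvector or `O(n^2 log n + nm)` of betweenness
centrality).

## The method

CumulativeRank scores each node by combining a semi-local and a global
term; **low CR = high spreading ability**:

    CR_i = INCC_i / Σ_j INCC_j  +  TC_i / Σ_j TC_j

* **INCC** (improved network constraint coefficient) — a structural-hole
  constraint in which tie proportions are weighted semi-locally:
  with `N_w` the two-step neighbourhood size, `Q_j = Σ_{w∈Γ(j)} N_w` and
  `LR_i = Σ_{j∈Γ(i)} Q_j` (LocalRank),

      INCC_i = Σ_{j∈Γ(i)} ( p'_ij + Σ_k p'_ik p'_kj )²,   p'_ij = Q_j / LR_i,

  the inner sum running over common neighbours `k`. Low INCC marks
  brokers whose first *and second* rings are rich.
* **TC** — min–max normalized per-node *tenacity*
  `R_i = (1 + m(G−i)) / w(G−i)`, where `m` and `w` are the giant-component
  size and component count after removing `i`. Key nodes (articulation
  points, found by an iterative depth-first `dfn`/`low` rule) are the only
  nodes that need an explicit recount; removal of anyone else leaves
  `R = n`. Low tenacity marks nodes that hold the network together.

The package also implements the benchmark rankings (degree, betweenness,
eigenvector, LocalRank, PageRank) and an all-contact discrete-time SIR
simulator (infection probability `β` per contact, recovery probability
`γ` per step) to compare seed sets by their mean final spreading scope
`F(t_c)`.

## Worked example

The bundled 15-node network (`example_network()`, also shipped as
`inst/extdata/example_network.edgelist`) is the standard worked example:

```r
library(cumrank)
g <- example_network()
network_summary(g)
#> Network: n = 15 nodes, m = 19 edges
#>   <k> = 2.5333   <k^2> = 8.2667   H = 1.2881
#>   clustering C = 0.4289   path length L = 2.9429
#>   epidemic threshold beta_th = 0.3065

identify_key_nodes(g)
#> [1] "C" "F" "G" "H" "K"

r <- cumulative_rank(g)
head(r[order(r$rank), c("node", "incc", "tc", "score", "rank")], 6)
#>    node  incc     tc  score rank
#> 8     H 0.323 0.0000 0.0271    1
#> 11    K 0.365 0.0000 0.0306    2
#> 7     G 0.327 0.2083 0.0471    3
#> 3     C 0.566 0.0833 0.0553    4
#> 6     F 0.771 0.3333 0.0960    5
#> 2     B 0.829 1.0000 0.1637    6
```

Node `H` wins: it has the lowest constraint (INCC 0.323 — it brokers the
eastern block) *and* minimal tenacity (its removal splits the network
into three pieces with an 8-node giant, `R = (1+8)/3 = 3`, so `TC = 0`). The five key nodes C, F, G, H, K fill
the top five CR ranks. Seeding an SIR epidemic from the CR top-3 and
comparing with other rankings:

```r
compare_seed_sets(g, methods = c("cr", "dc", "bc"), k = 3,
                  beta = 0.4, runs = 500, rng_seed = 42)
#>   method final_scope sd_final_scope time_steps  n beta   p
#> 1     cr       0.836          0.123       11.1 15  0.4 0.2
#> 2     dc       0.836          0.123       11.1 15  0.4 0.2
#> 3     bc       0.782          0.155       11.2 15  0.4 0.2
```

`final_scope` is the mean fraction of the network ever reached; CR's
seeds {H, K, G} reach 83.6% on average (here tying degree centrality,
which picks the same top-3 up to ties, and beating betweenness).

A thin CLI over the same functions ships in `inst/cli/cumrank`:

```sh
Rscript inst/cli/cumrank rank --edge-list graph.txt --method cr --top 10
Rscript inst/cli/cumrank sir --edge-list graph.txt --seeds A,B --beta 0.05 --runs 100
Rscript inst/cli/cumrank compare --edge-list graph.txt --top 10 --runs 100
```

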
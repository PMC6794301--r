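# Step 1 of the CumulativeRank pipeline: semi-local neighbourhood counts
# (N, Q, LR) and the structural-hole constraint coefficients (NCC, INCC).

# N, Q, LR for every node, from the adjacency list. All three are exact
# integer counts: N_v is the number of distinct nodes within two steps of
# v (v excluded), Q_v sums N over v's neighbours, LR_v sums Q over v's
# neighbours.
semi_local <- function(g) {
  adj <- adj_list(g)
  n <- length(adj)
  N <- integer(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    reach <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
    N[v] <- length(reach) - (v %in% reach)
  }
  Q <- unname(vapply(adj, function(nb) sum(N[nb]), numeric(1)))
  LR <- unname(vapply(adj, function(nb) sum(Q[nb]), numeric(1)))
  list(adj = adj, N = N, Q = Q, LR = LR)
}

# Burt constraint at node i. With binary ties, p_ij = 1/degree(i) for every
# neighbour j; the indirect term p_ik * p_kj is nonzero only for common
# neighbours k of i and j.
ncc_at <- function(adj, deg, i) {
  nb <- adj[[i]]
  if (length(nb) == 0L) {
    stop("network constraint is undefined for an isolated node",
         call. = FALSE)
  }
  p_i <- 1 / length(nb)
  total <- 0
  for (j in nb) {
    common <- intersect(nb, adj[[j]])
    total <- total + (p_i + p_i * sum(1 / deg[common]))^2
  }
  total
}

# Improved constraint at node i: ties are weighted semi-locally,
# p'_ij = Q_j / LR_i, so the two-step neighbourhood sizes of i's
# neighbours enter the constraint. Same common-neighbour structure as NCC.
incc_at <- function(adj, Q, LR, i) {
  nb <- adj[[i]]
  if (length(nb) == 0L) {
    stop("improved network constraint is undefined for an isolated node",
         call. = FALSE)
  }
  total <- 0
  for (j in nb) {
    common <- intersect(nb, adj[[j]])
    indirect <- sum((Q[common] / LR[i]) * (Q[j] / LR[common]))
    total <- total + (Q[j] / LR[i] + indirect)^2
  }
  total
}

#' Two-step neighbourhood size
#'
#' The number of distinct first- and second-degree neighbours of a node
#' (the node itself excluded); the building block `N` of the LocalRank
#' cascade.
#'
#' @param g An undirected `igraph`.
#' @param v A node label.
#' @return An integer count.
#' @examples
#' two_step_count(example_network(), "C") # 10
#' @export
two_step_count <- function(g, v) {
  g <- check_graph(g)
  i <- node_index(g, v)
  semi_local(g)$N[i]
}

#' Q value of a node
#'
#' The sum of the two-step neighbourhood sizes `N` over a node's
#' neighbours: `Q_v = sum_{w in Gamma(v)} N_w`.
#'
#' @inheritParams two_step_count
#' @return A count.
#' @examples
#' q_value(example_network(), "C") # 24
#' @export
q_value <- function(g, v) {
  g <- check_graph(g)
  i <- node_index(g, v)
  semi_local(g)$Q[i]
}

#' LocalRank centrality of a node
#'
#' The semi-local centrality `LR_v = sum_{j in Gamma(v)} Q_j`, which
#' aggregates neighbourhood information up to four steps away at
#' near-local cost.
#'
#' @inheritParams two_step_count
#' @return A count.
#' @examples
#' local_rank(example_network(), "C") # 92
#' @export
local_rank <- function(g, v) {
  g <- check_graph(g)
  i <- node_index(g, v)
  semi_local(g)$LR[i]
}

#' Burt network constraint coefficient (NCC)
#'
#' `NCC_v = sum_{j in Gamma(v)} (p_vj + sum_k p_vk p_kj)^2` with uniform
#' tie proportions `p_vj = 1/degree(v)` and the inner sum running over
#' common neighbours `k` of `v` and `j`. Low constraint marks structural-
#' hole brokers; a leaf node always has NCC = 1.
#'
#' @inheritParams two_step_count
#' @return A nonnegative score.
#' @examples
#' round(ncc(example_network(), "C"), 2) # 0.46
#' @export
ncc <- function(g, v) {
  g <- check_graph(g)
  i <- node_index(g, v)
  unname(ncc_at(adj_list(g), unname(degree(g)), i))
}

#' Improved network constraint coefficient (INCC)
#'
#' Replaces the uniform tie proportions of [ncc()] with semi-local weights
#' `p'_vj = Q_j / LR_v`, so that the richness of each neighbour's own
#' two-step neighbourhood enters the constraint. Lower INCC means larger
#' claimed local influence; leaves have INCC = 1.
#'
#' @inheritParams two_step_count
#' @return A nonnegative score.
#' @examples
#' round(incc(example_network(), "C"), 3) # 0.566
#' round(incc(example_network(), "F"), 3) # 0.771
#' @export
incc <- function(g, v) {
  g <- check_graph(g)
  i <- node_index(g, v)
  sl <- semi_local(g)
  unname(incc_at(sl$adj, sl$Q, sl$LR, i))
}

#' Per-node table of semi-local scores
#'
#' Computes degree, `N`, `Q`, `LR`, `NCC` and `INCC` for every node in one
#' pass. Isolated (degree-0) nodes get `NA` constraint scores and are
#' flagged in the `isolated` column; such nodes are ranked last downstream
#' rather than being assigned an invented score.
#'
#' @param g An undirected `igraph`.
#' @return A `data.frame` with columns `node`, `degree`, `N`, `Q`, `LR`,
#'   `NCC`, `INCC`, `isolated`, one row per node in vertex order.
#' @examples
#' head(local_scores(example_network()))
#' @export
local_scores <- function(g) {
  g <- check_graph(g)
  sl <- semi_local(g)
  deg <- degree(g)
  n <- vcount(g)
  NCC <- rep(NA_real_, n)
  INCC <- rep(NA_real_, n)
  for (i in which(deg > 0)) {
    NCC[i] <- ncc_at(sl$adj, deg, i)
    INCC[i] <- incc_at(sl$adj, sl$Q, sl$LR, i)
  }
  data.frame(
    node = V(g)$name,
    degree = as.integer(deg),
    N = sl$N,
    Q = sl$Q,
    LR = sl$LR,
    NCC = NCC,
    INCC = INCC,
    isolated = deg == 0L,
    stringsAsFactors = FALSE
  )
}
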
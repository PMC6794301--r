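# Independent brute-force oracles, written from the defining formulas with
# no shared code with the package internals (plain BFS, literal double
# sums). Used to cross-check every algorithmic claim on small graphs.

oracle_adj <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# BFS distances from a single source; Inf where unreachable.
oracle_bfs_dist <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Component sizes of the graph with the vertices in `drop` removed.
oracle_component_sizes <- function(adj, drop = integer(0)) {
  n <- length(adj)
  seen <- logical(n)
  seen[drop] <- TRUE
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      size <- size + 1L
      for (u in adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Per-node tenacity by direct vertex deletion.
oracle_tenacity <- function(g) {
  adj <- oracle_adj(g)
  vapply(seq_along(adj), function(v) {
    sizes <- oracle_component_sizes(adj, drop = v)
    (1 + max(sizes)) / length(sizes)
  }, numeric(1))
}

# Key nodes by the component-count definition: w(G - v) > w(G).
oracle_key_nodes <- function(g) {
  adj <- oracle_adj(g)
  base <- length(oracle_component_sizes(adj))
  hit <- vapply(seq_along(adj), function(v) {
    length(oracle_component_sizes(adj, drop = v)) > base
  }, logical(1))
  igraph::V(g)$name[hit]
}

# Semi-local counts recomputed independently via BFS distance <= 2.
oracle_semi_local <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  N <- vapply(seq_len(n), function(v) {
    d <- oracle_bfs_dist(adj, v)
    sum(d > 0 & d <= 2)
  }, numeric(1))
  Q <- vapply(seq_len(n), function(v) sum(N[adj[[v]]]), numeric(1))
  LR <- vapply(seq_len(n), function(v) sum(Q[adj[[v]]]), numeric(1))
  list(N = N, Q = Q, LR = LR)
}

# INCC by literal enumeration of all length-1 and length-2 p'-paths: the
# inner sum runs over every k != i, j, with p'(u, w) = Q_w / LR_u when
# {u, w} is an edge and 0 otherwise.
oracle_incc <- function(g, v) {
  adj <- oracle_adj(g)
  n <- length(adj)
  sl <- oracle_semi_local(g)
  pprime <- function(u, w) {
    if (w %in% adj[[u]]) sl$Q[w] / sl$LR[u] else 0
  }
  i <- match(as.character(v), igraph::V(g)$name)
  total <- 0
  for (j in adj[[i]]) {
    indirect <- 0
    for (k in seq_len(n)) {
      if (k != i && k != j) {
        indirect <- indirect + pprime(i, k) * pprime(k, j)
      }
    }
    total <- total + (pprime(i, j) + indirect)^2
  }
  total
}

# Mean shortest-path length over connected ordered pairs, by all-pairs BFS.
oracle_path_length <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  tot <- 0
  cnt <- 0
  for (s in seq_len(n)) {
    d <- oracle_bfs_dist(adj, s)
    reach <- d[is.finite(d) & d > 0]
    tot <- tot + sum(reach)
    cnt <- cnt + length(reach)
  }
  if (cnt == 0) NaN else tot / cnt
}

# Betweenness by explicit shortest-path counting: sigma_s(v) path counts
# from BFS, then the pair-dependency sum over all unordered pairs.
oracle_betweenness <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    sg <- numeric(n)
    d[s] <- 0
    sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (is.infinite(d[u])) {
            d[u] <- d[v] + 1
            nxt <- c(nxt, u)
          }
          if (d[u] == d[v] + 1) {
            sg[u] <- sg[u] + sg[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

# Independent SIR simulator, deliberately written contact-by-contact (one
# Bernoulli draw per infected-susceptible contact) rather than with the
# aggregated 1-(1-beta)^j rule; equal in distribution.
oracle_sir_final_scope <- function(g, seeds, beta, gamma) {
  adj <- oracle_adj(g)
  n <- length(adj)
  state <- rep("S", n)
  state[match(seeds, igraph::V(g)$name)] <- "I"
  while (any(state == "I")) {
    infected <- which(state == "I")
    newly <- integer(0)
    for (v in infected) {
      for (u in adj[[v]]) {
        if (state[u] == "S" && stats::runif(1) < beta) {
          newly <- c(newly, u)
        }
      }
    }
    recovering <- infected[stats::runif(length(infected)) < gamma]
    state[recovering] <- "R"
    state[unique(newly)] <- "I"
  }
  mean(state != "S")
}

# Random test graphs. `min_degree = 1` retries until no isolated node.
random_gnp <- function(n, p, seed, min_degree = 0L) {
  repeat {
    g <- generate_synthetic("erdos_renyi", n = n, param = p, seed = seed)
    if (min(igraph::degree(g)) >= min_degree) return(g)
    seed <- seed + 10000L
  }
}

random_connected_gnp <- function(n, p, seed) {
  repeat {
    g <- generate_synthetic("erdos_renyi", n = n, param = p, seed = seed)
    if (igraph::is_connected(g)) return(g)
    seed <- seed + 10000L
  }
}
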
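# Step 3: the CumulativeRank combination, ranked output with ties, and
# the benchmark centralities it is compared against.

round_half_up <- function(x, digits) {
  pow <- 10^digits
  floor(x * pow + 0.5) / pow
}

# Dense ranks from scores, grouping ties within a small absolute
# tolerance so floating-point noise cannot split symmetric nodes, while
# genuinely close scores on large graphs stay distinguishable. (On the
# worked example the published tie groups I = J and L = M = N = O are
# exact arithmetic ties, so they are reproduced at any tolerance.)
dense_rank_scores <- function(score, ascending = TRUE, digits = NULL,
                              tol = 0) {
  key <- score
  if (!is.null(digits)) key <- round_half_up(key, digits)
  if (!ascending) key <- -key
  finite_max <- if (any(is.finite(key))) max(key[is.finite(key)]) else 0
  key[!is.finite(key)] <- finite_max + 1 + tol * 2
  o <- order(key)
  grp <- integer(length(key))
  cur <- 0L
  prev <- -Inf
  for (i in o) {
    if (key[i] - prev > tol) cur <- cur + 1L
    grp[i] <- cur
    prev <- key[i]
  }
  grp
}

new_rank_result <- function(df, direction, ...) {
  attrs <- list(...)
  for (a in names(attrs)) attr(df, a) <- attrs[[a]]
  attr(df, "direction") <- direction
  class(df) <- c("rank_result", "data.frame")
  df
}

#' CumulativeRank scores and ranking
#'
#' Combines the local and global node scores into
#' `CR_v = INCC_v / D(INCC) + TC_v / D(TC)`, where `D` is either the plain
#' sum of the scores over all nodes (`normalization = "sum"`, the default)
#' or the square root of that sum (`normalization = "sqrt"`). Nodes with
#' the *lowest* CR are the most influential spreaders: they combine strong
#' semi-local brokerage (low INCC) with a critical connectivity position
#' (low tenacity). The published per-node values for the worked example
#' network are reproduced by `"sum"`; `"sqrt"` is retained behind this flag
#' because the combination rule is sometimes written with root-sum
#' denominators, which yields a different scale (the induced ranking keeps
#' the same top node but not the same scores).
#'
#' If every node has the same tenacity, the global term is dropped with a
#' message and CR reduces to its local term. Degree-0 nodes cannot carry a
#' constraint score; they are ranked last with a warning.
#'
#' @param g An undirected `igraph` with at least 2 nodes.
#' @param normalization `"sum"` (default) or `"sqrt"`.
#' @return A `data.frame` of class `rank_result` with columns `node`,
#'   `method` (`"cr"`), `incc`, `tc`, `score` and dense `rank`
#'   (1 = most influential; scores equal within `1e-9` share a rank).
#' @examples
#' r <- cumulative_rank(example_network())
#' r[order(r$rank), c("node", "score", "rank")]
#' @seealso [rank_order()], [top_k()], [benchmark_centrality()]
#' @export
cumulative_rank <- function(g, normalization = c("sum", "sqrt")) {
  normalization <- match.arg(normalization)
  g <- check_graph(g)
  if (vcount(g) < 2L) {
    stop("ranking needs at least 2 nodes", call. = FALSE)
  }
  ls <- local_scores(g)
  gs <- tenacity_all(g)
  if (any(ls$isolated)) {
    warning("degree-0 node(s) present; they are ranked last", call. = FALSE)
  }
  sum_incc <- sum(ls$INCC, na.rm = TRUE)
  sum_tc <- sum(gs$TC)
  denom_incc <- if (normalization == "sum") sum_incc else sqrt(sum_incc)
  cr <- ls$INCC / denom_incc
  if (sum_tc > 0) {
    denom_tc <- if (normalization == "sum") sum_tc else sqrt(sum_tc)
    cr <- cr + gs$TC / denom_tc
  } else {
    message("all tenacity values are equal; CR reduces to its local term")
  }
  cr[is.na(cr)] <- Inf
  out <- data.frame(
    node = ls$node,
    method = "cr",
    incc = ls$INCC,
    tc = gs$TC,
    score = cr,
    stringsAsFactors = FALSE
  )
  out$rank <- dense_rank_scores(cr, ascending = TRUE, tol = 1e-9)
  new_rank_result(out, direction = "ascending", normalization = normalization)
}

# Principal eigenvector of the adjacency matrix by power iteration on the
# shifted operator A + I (same eigenvector; the shift makes the iteration
# converge on bipartite graphs too), scaled to unit max-norm.
eigen_power <- function(g, tol = 1e-13, max_iter = 100000L) {
  n <- vcount(g)
  if (n == 1L) {
    return(1)
  }
  if (!is_connected(g)) {
    comp <- components(g)
    giant <- which(comp$membership == which.max(comp$csize))
    message("graph is disconnected; eigenvector centrality is computed on ",
            "the largest component (other nodes score 0)")
    x <- numeric(n)
    x[giant] <- eigen_power(induced_subgraph(g, giant), tol, max_iter)
    return(x)
  }
  A <- as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(A %*% x) + x
    x_new <- x_new / max(x_new)
    if (max(abs(x_new - x)) < tol) {
      return(x_new)
    }
    x <- x_new
  }
  stop(sprintf(
    "eigenvector power iteration did not converge in %d iterations (tol %g)",
    max_iter, tol), call. = FALSE)
}

# PageRank on the undirected graph read as bidirected: each edge carries
# rank in both directions and the out-degree equals the degree. Dangling
# (degree-0) nodes redistribute their mass uniformly, the standard
# convention, so the scores always sum to 1.
pagerank_power <- function(g, damping = 0.85, tol = 1e-10,
                           max_iter = 1000L) {
  n <- vcount(g)
  A <- as_adjacency_matrix(g, sparse = TRUE)
  deg <- degree(g)
  dangling <- deg == 0
  safe_deg <- pmax(deg, 1)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- damping * as.numeric(A %*% (x / safe_deg)) +
      damping * sum(x[dangling]) / n + (1 - damping) / n
    if (max(abs(x_new - x)) < tol) {
      return(x_new)
    }
    x <- x_new
  }
  stop(sprintf(
    "PageRank power iteration did not converge in %d iterations (tol %g)",
    max_iter, tol), call. = FALSE)
}

#' Benchmark centrality rankings
#'
#' The five classical rankings CumulativeRank is compared against:
#' * `dc` — degree centrality, `degree / (n - 1)`;
#' * `bc` — shortest-path betweenness;
#' * `ec` — eigenvector centrality (principal adjacency eigenvector by
#'   power iteration, unit max-norm; on disconnected input it is computed
#'   on the largest component, with a message);
#' * `lr` — LocalRank, the semi-local cascade of [local_rank()];
#' * `pr` — PageRank with damping 0.85 on the bidirected reading of the
#'   graph, iterated to a maximum change below `1e-10` (at most 1000
#'   sweeps).
#'
#' Benchmarks rank in *descending* score order (rank 1 = highest score),
#' unlike CumulativeRank where low scores win.
#'
#' @param g An undirected `igraph` with at least 2 nodes.
#' @param method One of `"dc"`, `"bc"`, `"ec"`, `"lr"`, `"pr"`.
#' @param damping PageRank damping factor, default 0.85.
#' @return A `data.frame` of class `rank_result` with columns `node`,
#'   `method`, `score`, `rank`.
#' @examples
#' benchmark_centrality(example_network(), "dc")
#' @export
benchmark_centrality <- function(g, method = c("dc", "bc", "ec", "lr", "pr"),
                                 damping = 0.85) {
  method <- match.arg(tolower(as.character(method)[1L]),
                      c("dc", "bc", "ec", "lr", "pr"))
  g <- check_graph(g)
  n <- vcount(g)
  if (n < 2L) {
    stop("ranking needs at least 2 nodes", call. = FALSE)
  }
  score <- switch(method,
    dc = degree(g) / (n - 1),
    bc = igraph::betweenness(g),
    ec = eigen_power(g),
    lr = semi_local(g)$LR,
    pr = pagerank_power(g, damping = damping)
  )
  out <- data.frame(
    node = V(g)$name,
    method = method,
    score = unname(as.numeric(score)),
    stringsAsFactors = FALSE
  )
  out$rank <- dense_rank_scores(out$score, ascending = FALSE, tol = 1e-9)
  new_rank_result(out, direction = "descending")
}

#' Influence order with tied groups
#'
#' Collapses a ranking into an ordered list of tied node groups, most
#' influential group first. Ties follow the dense ranks of the input; node
#' labels inside a group are sorted lexicographically for deterministic
#' output.
#'
#' @param r A `rank_result` from [cumulative_rank()] or
#'   [benchmark_centrality()].
#' @return A list of character vectors.
#' @examples
#' rank_order(cumulative_rank(example_network()))
#' @export
rank_order <- function(r) {
  stopifnot(is.data.frame(r), all(c("node", "rank") %in% names(r)))
  lapply(sort(unique(r$rank)), function(k) sort(r$node[r$rank == k]))
}

#' Top-k nodes of a ranking
#'
#' The first `k` nodes in influence order. Inside a tied group the order is
#' lexicographic by label, a deterministic tie-break that keeps downstream
#' SIR seeding reproducible.
#'
#' @param r A `rank_result`.
#' @param k Number of nodes, `1 <= k <= n`.
#' @return A character vector of length `k`.
#' @examples
#' top_k(cumulative_rank(example_network()), 5) # "H" "K" "G" "C" "F"
#' @export
top_k <- function(r, k) {
  stopifnot(is.data.frame(r), all(c("node", "rank") %in% names(r)))
  n <- nrow(r)
  if (k < 1 || k > n) {
    stop(sprintf("`k` must be between 1 and %d", n), call. = FALSE)
  }
  ord <- order(r$rank, r$node)
  r$node[ord][seq_len(k)]
}
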
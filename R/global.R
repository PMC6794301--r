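# Step 2 of the CumulativeRank pipeline: key nodes (articulation points
# found by an iterative dfn/low depth-first traversal) and per-node
# tenacity R = (1 + giant size after removal) / (component count after
# removal), min-max normalized to TC.

#' Identify key nodes by the depth-first dfn/low rule
#'
#' A node is a key node if it either is the root of the depth-first tree
#' with at least two descendants, or has a child `u` in the tree whose
#' lowest reachable depth-first number (`low`) is not less than the node's
#' own `dfn` — i.e. the classical articulation points, whose removal
#' disconnects (part of) the network. The traversal is iterative with an
#' explicit stack, so graphs far deeper than C's recursion limit (e.g. a
#' path of 1e5 nodes) are handled.
#'
#' @param g An undirected `igraph`.
#' @return A character vector of key-node labels (possibly empty), in
#'   vertex order.
#' @examples
#' identify_key_nodes(example_network()) # "C" "F" "G" "H" "K"
#' @export
identify_key_nodes <- function(g) {
  g <- check_graph(g)
  adj <- adj_list(g)
  n <- length(adj)
  if (n == 0L) {
    return(character(0))
  }
  is_art <- logical(n)
  dfn <- integer(n)
  low <- integer(n)
  counter <- 0L
  # explicit stacks: vertex, tree parent, next-neighbour cursor
  sv <- integer(n)
  sp <- integer(n)
  si <- integer(n)
  for (root in seq_len(n)) {
    if (dfn[root] != 0L) next
    root_children <- 0L
    top <- 1L
    sv[1L] <- root
    sp[1L] <- 0L
    si[1L] <- 1L
    counter <- counter + 1L
    dfn[root] <- counter
    low[root] <- counter
    while (top > 0L) {
      v <- sv[top]
      nb <- adj[[v]]
      if (si[top] <= length(nb)) {
        u <- nb[si[top]]
        si[top] <- si[top] + 1L
        if (u == sp[top]) next          # tree edge back to parent
        if (dfn[u] == 0L) {             # tree edge forward: descend
          counter <- counter + 1L
          dfn[u] <- counter
          low[u] <- counter
          if (v == root) root_children <- root_children + 1L
          top <- top + 1L
          sv[top] <- u
          sp[top] <- v
          si[top] <- 1L
        } else if (dfn[u] < low[v]) {   # back edge
          low[v] <- dfn[u]
        }
      } else {                          # all neighbours done: backtrack
        top <- top - 1L
        if (top > 0L) {
          p <- sv[top]
          if (low[v] < low[p]) low[p] <- low[v]
          if (p != root && low[v] >= dfn[p]) is_art[p] <- TRUE
        }
      }
    }
    if (root_children >= 2L) is_art[root] <- TRUE
  }
  V(g)$name[is_art]
}

tenacity_value <- function(g, i) {
  comp <- components(delete_vertices(g, i))
  (1 + max(comp$csize)) / comp$no
}

#' Per-node tenacity
#'
#' `R_v = (1 + m(G - v)) / w(G - v)`, where `m(G - v)` is the size of the
#' largest component and `w(G - v)` the number of components remaining
#' after deleting `v` (removal cost 1). The formula applies uniformly to
#' every node: removing a non-cut node of a connected graph leaves one
#' component of `n - 1` nodes, so `R_v = n`. Low tenacity marks nodes whose
#' removal shatters the network into many small pieces.
#'
#' @param g An undirected `igraph` with at least 2 nodes.
#' @param v A node label.
#' @return A positive score.
#' @examples
#' tenacity(example_network(), "G") # 5.5
#' tenacity(example_network(), "L") # 15
#' @export
tenacity <- function(g, v) {
  g <- check_graph(g)
  if (vcount(g) < 2L) {
    stop("tenacity is undefined on a single-node graph", call. = FALSE)
  }
  tenacity_value(g, node_index(g, v))
}

#' Tenacity and normalized tenacity for every node
#'
#' Computes the key-node flag, tenacity `R` and the min-max normalized
#' tenacity `TC in [0, 1]` for all nodes. On connected input the key-node
#' set is used as a shortcut: every non-key node gets `R = n` without
#' recomputing components; only the (few) key nodes need an explicit
#' vertex-deleted component count. If all `R` are equal (e.g. a regular
#' biconnected graph such as a complete graph), `TC` is defined as 0 for
#' every node, so the downstream CumulativeRank reduces to its local term.
#'
#' @param g An undirected `igraph` with at least 2 nodes.
#' @return A `data.frame` with columns `node`, `is_key`, `R`, `TC`.
#' @examples
#' tenacity_all(example_network())
#' @export
tenacity_all <- function(g) {
  g <- check_graph(g)
  n <- vcount(g)
  if (n < 2L) {
    stop("tenacity is undefined on a single-node graph", call. = FALSE)
  }
  labels <- V(g)$name
  is_key <- labels %in% identify_key_nodes(g)
  R <- numeric(n)
  if (is_connected(g)) {
    R[!is_key] <- n
    for (i in which(is_key)) {
      R[i] <- tenacity_value(g, i)
    }
  } else {
    for (i in seq_len(n)) {
      R[i] <- tenacity_value(g, i)
    }
  }
  rng <- range(R)
  TC <- if (rng[1L] == rng[2L]) {
    rep(0, n)
  } else {
    (R - rng[1L]) / (rng[2L] - rng[1L])
  }
  data.frame(node = labels, is_key = is_key, R = R, TC = TC,
             stringsAsFactors = FALSE)
}
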
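#' @importFrom igraph V V<- vcount ecount degree is_igraph is_directed
#'   is_simple simplify graph_from_data_frame as_adj_list as_edgelist
#'   components delete_vertices induced_subgraph is_connected transitivity
#'   mean_distance sample_gnp sample_pa as_adjacency_matrix
NULL

# Validate and canonicalize a user-supplied graph: undirected, simple,
# named vertices. Labels are opaque text; internal code works on integer
# indices but never exposes them.
check_graph <- function(g) {
  if (!is_igraph(g)) {
    stop("`g` must be an igraph object (see read_edge_list())", call. = FALSE)
  }
  if (is_directed(g)) {
    stop("`g` must be an undirected graph", call. = FALSE)
  }
  if (is.null(V(g)$name)) {
    V(g)$name <- as.character(seq_len(vcount(g)))
  }
  if (!is_simple(g)) {
    g <- simplify(g)
  }
  g
}

node_index <- function(g, v) {
  i <- match(as.character(v), V(g)$name)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(unique(v[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  i
}

# Adjacency as a plain list of integer neighbour indices.
adj_list <- function(g) {
  lapply(as_adj_list(g, mode = "all"), as.integer)
}

#' Read an undirected simple graph from a plain-text edge list
#'
#' Parses the SNAP dialect: one edge per line as two whitespace-separated
#' node labels, with comment lines starting with `comment_prefix` and blank
#' lines ignored. Tokens beyond the second are ignored (so weighted files
#' parse; weights are unused). Duplicate and reversed edge lines collapse to
#' a single edge; self-loop lines are dropped with a warning giving the
#' count. Node order is first-appearance order.
#'
#' @param path Path to the edge-list file.
#' @param comment_prefix Lines starting with this prefix (after trimming
#'   leading whitespace) are skipped. Default `"#"`.
#' @return An undirected simple `igraph` with character vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "A B", "B A", "B C"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g) # 2
#' @seealso [write_edge_list()], [example_network()]
#' @export
read_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) {
    stop("cannot read edge list: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, comment_prefix)
  lineno <- which(keep)
  toks <- strsplit(trimmed[keep], "[[:space:]]+")
  bad <- lengths(toks) < 2L
  if (any(bad)) {
    stop(sprintf("parse error at line %d: expected two node labels",
                 lineno[which(bad)[1L]]), call. = FALSE)
  }
  from <- vapply(toks, `[`, character(1), 1L)
  to <- vapply(toks, `[`, character(1), 2L)
  nodes <- unique(as.vector(rbind(from, to)))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop line(s)", sum(loops)), call. = FALSE)
    from <- from[!loops]
    to <- to[!loops]
  }
  dup <- duplicated(cbind(pmin(from, to), pmax(from, to)))
  g <- graph_from_data_frame(
    data.frame(from = from[!dup], to = to[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  simplify(g)
}

#' Write a graph as a plain-text edge list
#'
#' One line per edge, two whitespace-separated node labels; reading the file
#' back with [read_edge_list()] recovers an identical edge set.
#'
#' @param g An undirected `igraph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  g <- check_graph(g)
  el <- as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}

.example_edges <- matrix(c(
  "A", "E", "A", "F", "A", "G",
  "B", "C", "B", "D", "B", "G",
  "C", "G", "C", "H",
  "D", "G",
  "E", "G",
  "F", "G", "F", "L",
  "H", "I", "H", "J", "H", "K",
  "I", "J",
  "K", "M", "K", "N", "K", "O"
), ncol = 2L, byrow = TRUE)

#' The 15-node worked example network
#'
#' A fixed undirected graph with nodes `A`..`O` and 19 edges, used
#' throughout the documentation and tests as the worked example for the
#' CumulativeRank pipeline: node `G` is the hub of a dense western block,
#' `H` bridges to a clique-ish eastern block, and `K` fans out to three
#' leaves. The same graph ships as a plain-text fixture in
#' `system.file("extdata", "example_network.edgelist", package = "cumrank")`.
#'
#' @return An undirected simple `igraph` with 15 vertices and 19 edges.
#' @examples
#' g <- example_network()
#' igraph::degree(g, c("G", "H", "L"))
#' @export
example_network <- function() {
  graph_from_data_frame(
    data.frame(from = .example_edges[, 1L], to = .example_edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = LETTERS[1:15], stringsAsFactors = FALSE)
  )
}

#' Summary statistics of a network
#'
#' Computes the node and edge counts, the first two moments of the degree
#' distribution, the degree heterogeneity `H = <k^2>/<k>^2`, the average
#' local clustering coefficient (nodes of degree < 2 contribute 0), the
#' characteristic path length (averaged over connected pairs only, so
#' disconnected graphs are handled), and the heterogeneous mean-field
#' epidemic threshold `beta_th = <k>/<k^2>`.
#'
#' @param g An undirected `igraph`.
#' @return A list of class `network_summary` with elements `n`, `m`,
#'   `mean_degree`, `second_moment`, `heterogeneity`, `clustering`,
#'   `path_length`, `beta_th`.
#' @examples
#' network_summary(example_network())
#' @export
network_summary <- function(g) {
  g <- check_graph(g)
  n <- vcount(g)
  if (n == 0L) {
    stop("cannot summarize an empty graph", call. = FALSE)
  }
  deg <- degree(g)
  k1 <- mean(deg)
  k2 <- mean(deg^2)
  out <- list(
    n = n,
    m = ecount(g),
    mean_degree = k1,
    second_moment = k2,
    heterogeneity = if (k1 > 0) k2 / k1^2 else NA_real_,
    clustering = transitivity(g, type = "localaverage", isolates = "zero"),
    path_length = if (n > 1L) mean_distance(g, unconnected = TRUE) else NA_real_,
    beta_th = if (k2 > 0) k1 / k2 else NA_real_
  )
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network: n = %d nodes, m = %d edges\n", x$n, x$m))
  cat(sprintf("  <k> = %.4f   <k^2> = %.4f   H = %.4f\n",
              x$mean_degree, x$second_moment, x$heterogeneity))
  cat(sprintf("  clustering C = %.4f   path length L = %.4f\n",
              x$clustering, x$path_length))
  cat(sprintf("  epidemic threshold beta_th = %.4f\n", x$beta_th))
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# random stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic test network
#'
#' Reproducible Erdos-Renyi G(n, p) or Barabasi-Albert preferential
#' attachment graphs, used as desk-scale stand-ins for large empirical
#' contact networks in tests and benchmarks. Vertices are named
#' `"1"`..`"n"`. The caller's RNG stream is left untouched when a seed is
#' supplied.
#'
#' @param model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param n Number of nodes (>= 2).
#' @param param Edge probability in `(0, 1]` for Erdos-Renyi; number of
#'   edges attached per new node (>= 1) for Barabasi-Albert.
#' @param seed Optional integer seed; a fixed seed gives an identical graph
#'   on every call.
#' @return An undirected simple `igraph`.
#' @examples
#' g <- generate_synthetic("barabasi_albert", n = 100, param = 2, seed = 7)
#' igraph::is_connected(g)
#' @export
generate_synthetic <- function(model = c("erdos_renyi", "barabasi_albert"),
                               n, param, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(n) || n < 2) {
    stop("`n` must be at least 2", call. = FALSE)
  }
  if (model == "erdos_renyi") {
    if (!is.numeric(param) || param <= 0 || param > 1) {
      stop("edge probability must lie in (0, 1]", call. = FALSE)
    }
  } else {
    if (!is.numeric(param) || param < 1) {
      stop("attachment count must be >= 1", call. = FALSE)
    }
  }
  g <- with_seed(seed, {
    if (model == "erdos_renyi") {
      sample_gnp(n, param)
    } else {
      sample_pa(n, m = param, directed = FALSE)
    }
  })
  V(g)$name <- as.character(seq_len(vcount(g)))
  check_graph(g)
}
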
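# Discrete-time all-contact SIR simulation and the seed-set evaluation
# harness. Update order per step: (1) every currently infected node
# attempts to infect each susceptible neighbour independently with
# probability beta, so a susceptible with j infected neighbours turns
# infected with probability 1 - (1 - beta)^j; (2) every node that was
# infected *before* the step recovers with probability gamma. Newly
# infected nodes neither transmit nor recover in their infection step;
# with beta = gamma = 1 the process is a clean BFS wave.

#' Single SIR run
#'
#' Simulates one realisation of the discrete-time all-contact SIR process
#' from a given seed set. The spreading scope `F(t) = (n_I(t) + n_R(t))/n`
#' is recorded at every step; the run stops when no infected nodes remain
#' (or at `max_steps`, a runaway guard — with `gamma > 0` the process
#' terminates almost surely long before).
#'
#' @param g An undirected `igraph`.
#' @param seeds Character vector of initially infected node labels
#'   (nonempty; all other nodes start susceptible).
#' @param beta Per-contact infection probability in `[0, 1]`.
#' @param gamma Per-step recovery probability in `[0, 1]`, default 0.3.
#' @param max_steps Step cap, default `10 * n`.
#' @param rng_seed Optional integer; when given, the run is seeded with
#'   `rng_seed + run_index` so replicate runs draw independent substreams.
#' @param run_index Replicate index used to derive the substream seed.
#' @return An object of class `sir_run`: list with `trajectory` (a
#'   `data.frame` with columns `t`, `n_S`, `n_I`, `n_R`, `F`),
#'   `final_scope`, `steps` (the convergence step `t_c`), `converged`,
#'   `seeds`, `beta`, `gamma`.
#' @examples
#' r <- sir_run(example_network(), seeds = "H", beta = 0.5, rng_seed = 1)
#' r$final_scope
#' @export
sir_run <- function(g, seeds, beta, gamma = 0.3, max_steps = NULL,
                    rng_seed = NULL, run_index = 0L) {
  g <- check_graph(g)
  n <- vcount(g)
  if (length(seeds) == 0L) {
    stop("seed set must be nonempty", call. = FALSE)
  }
  if (beta < 0 || beta > 1 || gamma < 0 || gamma > 1) {
    stop("`beta` and `gamma` must lie in [0, 1]", call. = FALSE)
  }
  sidx <- unique(node_index(g, seeds))
  if (is.null(max_steps)) max_steps <- 10L * n
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed) + as.integer(run_index))
  adj <- adj_list(g)
  state <- integer(n)                 # 0 = S, 1 = I, 2 = R
  state[sidx] <- 1L
  n_inf <- length(sidx)
  rec <- matrix(0L, nrow = max_steps + 1L, ncol = 4L)
  rec[1L, ] <- c(0L, n - n_inf, n_inf, 0L)
  t <- 0L
  while (n_inf > 0L && t < max_steps) {
    t <- t + 1L
    infected <- which(state == 1L)
    contacts <- unlist(adj[infected], use.names = FALSE)
    cnt <- tabulate(contacts, nbins = n)
    cand <- which(cnt > 0L & state == 0L)
    newly <- cand[stats::runif(length(cand)) < 1 - (1 - beta)^cnt[cand]]
    recovering <- infected[stats::runif(length(infected)) < gamma]
    state[recovering] <- 2L
    state[newly] <- 1L
    n_inf <- sum(state == 1L)
    rec[t + 1L, ] <- c(t, sum(state == 0L), n_inf, sum(state == 2L))
  }
  rec <- rec[seq_len(t + 1L), , drop = FALSE]
  traj <- data.frame(
    t = rec[, 1L], n_S = rec[, 2L], n_I = rec[, 3L], n_R = rec[, 4L],
    F = (rec[, 3L] + rec[, 4L]) / n
  )
  structure(list(
    trajectory = traj,
    final_scope = traj$F[nrow(traj)],
    steps = t,
    converged = n_inf == 0L,
    seeds = V(g)$name[sidx],
    beta = beta,
    gamma = gamma
  ), class = "sir_run")
}

#' Replicated SIR runs with averaging
#'
#' Runs `runs` independent replicates of [sir_run()], each on its own
#' derived substream (`rng_seed + run index`), and aggregates: the mean
#' `F(t)` trajectory (shorter runs are padded by carrying their final scope
#' forward), and the per-run and mean/sd final scope and convergence step.
#' A fixed `rng_seed` makes the whole aggregate bit-reproducible, and
#' increasing `runs` never perturbs the earlier replicates.
#'
#' @inheritParams sir_run
#' @param runs Number of replicates (>= 1).
#' @param rng_seed Master integer seed, default 1.
#' @return An object of class `sir_summary`: list with `mean_trajectory`
#'   (mean `F` at t = 0, 1, ...), `final_scope` (per run),
#'   `mean_final_scope`, `sd_final_scope`, `steps` (per run), `mean_steps`,
#'   `runs`, `seeds`, `beta`, `gamma`, `rng_seed`.
#' @examples
#' s <- sir_average(example_network(), c("H", "G"), beta = 0.4, runs = 50)
#' s$mean_final_scope
#' @export
sir_average <- function(g, seeds, beta, gamma = 0.3, runs = 100L,
                        rng_seed = 1L, max_steps = NULL) {
  if (runs < 1L) {
    stop("`runs` must be >= 1", call. = FALSE)
  }
  g <- check_graph(g)
  reps <- vector("list", runs)
  for (r in seq_len(runs)) {
    reps[[r]] <- sir_run(g, seeds, beta, gamma, max_steps,
                         rng_seed = rng_seed, run_index = r)
  }
  fs <- vapply(reps, `[[`, numeric(1), "final_scope")
  st <- vapply(reps, function(x) as.numeric(x$steps), numeric(1))
  len <- max(vapply(reps, function(x) nrow(x$trajectory), integer(1)))
  fmat <- vapply(reps, function(x) {
    f <- x$trajectory$F
    c(f, rep(f[length(f)], len - length(f)))
  }, numeric(len))
  fmat <- matrix(fmat, nrow = len)
  structure(list(
    mean_trajectory = rowMeans(fmat),
    final_scope = fs,
    mean_final_scope = mean(fs),
    sd_final_scope = stats::sd(fs),
    steps = st,
    mean_steps = mean(st),
    runs = runs,
    seeds = reps[[1L]]$seeds,
    beta = beta,
    gamma = gamma,
    rng_seed = rng_seed
  ), class = "sir_summary")
}

#' @export
print.sir_summary <- function(x, ...) {
  cat(sprintf(
    "SIR: %d runs, beta = %.4g, gamma = %.4g, seeds = {%s}\n",
    x$runs, x$beta, x$gamma, paste(x$seeds, collapse = ", ")))
  cat(sprintf("  mean final scope F(t_c) = %.4f (sd %.4f)\n",
              x$mean_final_scope, x$sd_final_scope))
  cat(sprintf("  mean steps to converge  = %.2f\n", x$mean_steps))
  invisible(x)
}

#' Heterogeneous mean-field epidemic threshold
#'
#' `beta_th = <k> / <k^2>`; infection probabilities just above this
#' threshold allow macroscopic outbreaks while keeping seed identity
#' informative (far above it, any seed reaches most of the network).
#'
#' @param g An undirected `igraph` with at least one edge.
#' @return A probability.
#' @examples
#' epidemic_threshold(example_network()) # 38/124
#' @export
epidemic_threshold <- function(g) {
  g <- check_graph(g)
  if (ecount(g) == 0L) {
    stop("epidemic threshold is undefined for an edgeless graph",
         call. = FALSE)
  }
  network_summary(g)$beta_th
}

#' Compare seed sets selected by different rankings
#'
#' For each ranking method, selects the top-`k` nodes as initial
#' spreaders, runs the replicated SIR process with a shared master seed,
#' and tabulates the mean final spreading scope and mean steps to
#' convergence. The mean `F(t)` trajectories are attached as the
#' `"trajectories"` attribute for plotting with [plot_spreading()].
#'
#' @param g An undirected `igraph`.
#' @param methods Character vector from `"cr"`, `"dc"`, `"bc"`, `"ec"`,
#'   `"lr"`, `"pr"`.
#' @param k Seed-set size (<= n), default 10.
#' @param beta Infection probability; default `1.5 * epidemic_threshold(g)`.
#' @param gamma Recovery probability, default 0.3.
#' @param runs Replicates per method, default 100.
#' @param rng_seed Master seed shared by all methods, default 1.
#' @param normalization Passed to [cumulative_rank()].
#' @return A `data.frame` with one row per method and columns `method`,
#'   `final_scope`, `sd_final_scope`, `time_steps`, `n`, `beta`, `p`
#'   (seed fraction `k/n`).
#' @examples
#' g <- example_network()
#' compare_seed_sets(g, c("cr", "dc"), k = 3, beta = 0.5, runs = 50)
#' @export
compare_seed_sets <- function(g, methods = c("cr", "dc", "bc", "ec", "lr", "pr"),
                              k = 10L, beta = NULL, gamma = 0.3,
                              runs = 100L, rng_seed = 1L,
                              normalization = "sum") {
  g <- check_graph(g)
  n <- vcount(g)
  if (k > n) {
    stop("`k` exceeds the number of nodes", call. = FALSE)
  }
  if (is.null(beta)) beta <- min(1, 1.5 * epidemic_threshold(g))
  rows <- vector("list", length(methods))
  traj <- vector("list", length(methods))
  for (idx in seq_along(methods)) {
    m <- methods[idx]
    rk <- if (identical(m, "cr")) {
      cumulative_rank(g, normalization = normalization)
    } else {
      benchmark_centrality(g, m)
    }
    seeds <- top_k(rk, k)
    res <- sir_average(g, seeds, beta = beta, gamma = gamma,
                       runs = runs, rng_seed = rng_seed)
    rows[[idx]] <- data.frame(
      method = m,
      final_scope = res$mean_final_scope,
      sd_final_scope = res$sd_final_scope,
      time_steps = res$mean_steps,
      n = n,
      beta = beta,
      p = k / n,
      stringsAsFactors = FALSE
    )
    traj[[idx]] <- res$mean_trajectory
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(traj) <- methods
  attr(out, "trajectories") <- traj
  out
}

#' Plot mean spreading-scope curves
#'
#' Draws the mean `F(t)` trajectory of each method from a
#' [compare_seed_sets()] table.
#'
#' @param cmp Output of [compare_seed_sets()].
#' @param ... Further arguments to [graphics::matplot()].
#' @return `cmp`, invisibly.
#' @export
plot_spreading <- function(cmp, ...) {
  traj <- attr(cmp, "trajectories")
  if (is.null(traj)) {
    stop("`cmp` must come from compare_seed_sets()", call. = FALSE)
  }
  len <- max(lengths(traj))
  padded <- vapply(traj, function(f) {
    c(f, rep(f[length(f)], len - length(f)))
  }, numeric(len))
  padded <- matrix(padded, nrow = len, dimnames = list(NULL, names(traj)))
  graphics::matplot(seq_len(len) - 1L, padded, type = "l", lty = 1L,
                    xlab = "t", ylab = "F(t)", ...)
  graphics::legend("bottomright", legend = colnames(padded),
                   col = seq_len(ncol(padded)), lty = 1L, bty = "n")
  invisible(cmp)
}
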
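# Ground truth machinery. The generic simulator uses the integer-threshold
# coupling: each node draws k_i in 0..d_i+1 with P(k_i = a) = R_i(a) and
# activates once at least k_i neighbors are active (k_i = 0 seeds, k_i =
# d_i+1 never activates). For monotone cumulative responses this reproduces
# the marginal activation law exactly and makes the final state independent
# of the update schedule.

# sparse adjacency for the vectorized engine
net_adj_matrix <- function(net) {
  if (nrow(net$ei) == 0) {
    return(sparseMatrix(i = integer(0), j = integer(0), dims = c(net$n, net$n)))
  }
  sparseMatrix(i = c(net$ei[, 1], net$ei[, 2]),
               j = c(net$ei[, 2], net$ei[, 1]),
               x = 1, dims = c(net$n, net$n))
}

# K: reps x n integer matrix of thresholds; returns final active counts.
# Synchronous updates to the (schedule-independent) fixed point.
cascade_engine_counts <- function(A, K) {
  active <- K == 0L
  storage.mode(active) <- "double"
  repeat {
    cnt <- as.matrix(active %*% A)
    new_active <- (active == 1) | (cnt >= K)
    storage.mode(new_active) <- "double"
    if (sum(new_active) == sum(active)) break
    active <- new_active
  }
  as.integer(rowSums(active))
}

#' Sample an integer-threshold assignment
#'
#' Draws `k_i ~ R_i` independently per node: the number of active neighbors
#' needed to activate node `i` (`0` = initially active, `d_i + 1` = never).
#'
#' @param edges Edge tibble.
#' @param model A [cascade_model()].
#' @param seed Integer seed.
#' @return Tibble with columns `node`, `k`.
#' @export
sample_thresholds <- function(edges, model, seed = 1L) {
  net <- build_network(edges, nodes = edges_node_set(edges))
  k <- with_seed(seed, vapply(seq_len(net$n), function(i) {
    r <- build_response(model, net$deg[i], node = net$nodes[i])
    sample.int(net$deg[i] + 2L, 1L, prob = r$R) - 1L
  }, integer(1)))
  tibble(node = net$nodes, k = k)
}

#' Run one cascade to its fixed point
#'
#' Synchronous updates: a node is active at step `t` iff it was active or at
#' least `k_i` of its neighbors were active at `t - 1`. Monotone, so the
#' fixed point is reached within `N` steps and is schedule-independent.
#'
#' @param edges Edge tibble.
#' @param assignment Tibble with columns `node`, `k` (see
#'   [sample_thresholds()]).
#' @return Final number of active nodes.
#' @export
#' @examples
#' simulate_cascade(gen_path(3), tibble::tibble(node = c("1", "2", "3"), k = c(0, 1, 1)))
simulate_cascade <- function(edges, assignment) {
  net <- build_network(edges, nodes = edges_node_set(edges, assignment$node))
  k <- assignment$k[match(net$nodes, assignment$node)]
  if (anyNA(k)) abort("assignment is missing nodes")
  A <- net_adj_matrix(net)
  cascade_engine_counts(A, matrix(as.numeric(k), 1L, net$n, byrow = TRUE))
}

# sample a reps x n threshold matrix from the responses (uses current RNG)
sample_K <- function(responses, deg, reps) {
  n <- length(deg)
  K <- matrix(0, reps, n)
  for (i in seq_len(n)) {
    K[, i] <- sample.int(deg[i] + 2L, reps, replace = TRUE, prob = responses[[i]]$R) - 1
  }
  K
}

#' Monte Carlo estimate of the final-size distribution
#'
#' Draws `reps` independent threshold assignments and runs each cascade to
#' its fixed point.
#'
#' @param edges Edge tibble.
#' @param model A [cascade_model()].
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param chunk Replicates per vectorized batch (memory knob).
#' @return An object of class `empirical_distribution`: counts over
#'   `t = 0..N`, plus `reps` and `seed`.
#' @export
monte_carlo_distribution <- function(edges, model, reps = 1e5, seed = 1L,
                                     chunk = 20000L) {
  net <- build_network(edges, nodes = edges_node_set(edges))
  responses <- lapply(seq_len(net$n), function(i)
    build_response(model, net$deg[i], node = net$nodes[i]))
  A <- net_adj_matrix(net)
  counts <- integer(net$n + 1L)
  with_seed(seed, {
    left <- as.integer(reps)
    while (left > 0L) {
      b <- min(chunk, left)
      K <- sample_K(responses, net$deg, b)
      sizes <- cascade_engine_counts(A, K)
      counts <- counts + tabulate(sizes + 1L, nbins = net$n + 1L)
      left <- left - b
    }
  })
  new_empirical(counts, reps = as.integer(reps), seed = as.integer(seed),
                method = "monte_carlo")
}

new_empirical <- function(counts, reps, seed, method) {
  structure(list(t = seq_along(counts) - 1, counts = counts, reps = reps,
                 seed = seed, method = method),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat(sprintf("<empirical_distribution> %s, %d replicates (seed %d), N = %d\n",
              x$method, x$reps, x$seed, length(x$counts) - 1L))
  invisible(x)
}

#' @export
tidy.empirical_distribution <- function(x, ...) {
  tibble(t = x$t, count = x$counts, probability = x$counts / x$reps)
}

#' @export
glance.empirical_distribution <- function(x, ...) {
  p <- x$counts / x$reps
  tibble(n_nodes = length(x$counts) - 1L, reps = x$reps,
         mean_size = sum(x$t * p), method = x$method)
}

#' @export
autoplot.empirical_distribution <- function(object, ...) {
  d <- tidy(object)
  n <- length(object$counts) - 1L
  ggplot(d, aes(x = .data$t / n, y = .data$probability)) +
    geom_col(width = 1 / max(n, 1)) +
    labs(x = expression(rho), y = "probability",
         title = sprintf("Empirical final-size distribution (%s)", object$method))
}

#' Convert an empirical distribution to probabilities
#'
#' @param x An `empirical_distribution`.
#' @return A [cascade_distribution()].
#' @export
as_cascade_distribution <- function(x) {
  stopifnot(inherits(x, "empirical_distribution"))
  cascade_distribution(x$counts / x$reps, t = x$t,
                       n_nodes = length(x$counts) - 1L, method = x$method)
}

#' Exact final-size distribution by exhaustive enumeration
#'
#' Enumerates every integer-threshold assignment with its product
#' probability and runs the cascade engine on each; works on any graph (an
#' independent oracle for the message-passing results). The state space
#' `prod_i (d_i + 2)` must not exceed `limit`.
#'
#' @param edges Edge tibble.
#' @param model A [cascade_model()].
#' @param limit Enumeration guard (default `1e7` states).
#' @param chunk States per vectorized batch.
#' @return A [cascade_distribution()] with an attached `marginals` attribute
#'   (tibble `node`, `p`: exact per-node activation probabilities).
#' @export
brute_force_distribution <- function(edges, model, limit = 1e7, chunk = 100000L) {
  net <- build_network(edges, nodes = edges_node_set(edges))
  responses <- lapply(seq_len(net$n), function(i)
    build_response(model, net$deg[i], node = net$nodes[i]))
  enumerate_cascades(net, responses, limit = limit, chunk = chunk)
}

enumerate_cascades <- function(net, responses, limit = 1e7, chunk = 100000L) {
  n <- net$n
  sizes <- net$deg + 2L
  n_states <- prod(as.numeric(sizes))
  if (n_states > limit) {
    abort(sprintf(paste0("state space has %.3g assignments, above the limit %.3g; ",
                         "use monte_carlo_distribution() instead"), n_states, limit))
  }
  A <- net_adj_matrix(net)
  radix <- c(1, cumprod(as.numeric(sizes)))[seq_len(n)]
  probs <- numeric(n + 1L)
  marg <- numeric(n)
  done <- 0
  while (done < n_states) {
    b <- as.integer(min(chunk, n_states - done))
    idx <- done + seq_len(b) - 1
    K <- matrix(0, b, n)
    w <- rep(1, b)
    for (i in seq_len(n)) {
      ki <- (idx %/% radix[i]) %% sizes[i]
      K[, i] <- ki
      w <- w * responses[[i]]$R[ki + 1L]
    }
    live <- w > 0
    if (any(live)) {
      Kl <- K[live, , drop = FALSE]
      wl <- w[live]
      active <- Kl == 0
      storage.mode(active) <- "double"
      repeat {
        cnt <- as.matrix(active %*% A)
        new_active <- (active == 1) | (cnt >= Kl)
        storage.mode(new_active) <- "double"
        if (sum(new_active) == sum(active)) break
        active <- new_active
      }
      sizes_out <- as.integer(rowSums(active))
      probs <- probs + vapply(0:n, function(t) sum(wl[sizes_out == t]), numeric(1))
      marg <- marg + drop(wl %*% active)
    }
    done <- done + b
  }
  out <- cascade_distribution(probs, n_nodes = n, method = "brute_force")
  attr(out, "marginals") <- tibble(node = net$nodes, p = marg)
  out
}

#' Bond-percolation sampler for the independent cascade model
#'
#' Per replicate: every node is seeded independently with probability `p`,
#' every edge is occupied independently with probability `p`, and the final
#' active set is everything reachable from a seed along occupied edges. The
#' final outcome of the independent cascade model is equivalent to this
#' percolation process.
#'
#' @param edges Edge tibble.
#' @param p Seeding/transmission probability.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param chunk Replicates per vectorized batch.
#' @return An `empirical_distribution`.
#' @export
icm_bond_percolation_mc <- function(edges, p, reps = 1e5, seed = 1L,
                                    chunk = 20000L) {
  stopifnot(p >= 0, p <= 1)
  net <- build_network(edges, nodes = edges_node_set(edges))
  n <- net$n
  ne <- nrow(net$ei)
  counts <- integer(n + 1L)
  with_seed(seed, {
    left <- as.integer(reps)
    while (left > 0L) {
      b <- min(chunk, left)
      active <- matrix(runif(b * n) < p, b, n)
      occ <- if (ne > 0) matrix(runif(b * ne) < p, b, ne) else matrix(FALSE, b, 0)
      repeat {
        changed <- FALSE
        for (e in seq_len(ne)) {
          u <- net$ei[e, 1]; v <- net$ei[e, 2]
          push_v <- occ[, e] & active[, u] & !active[, v]
          push_u <- occ[, e] & active[, v] & !active[, u]
          if (any(push_v)) { active[push_v, v] <- TRUE; changed <- TRUE }
          if (any(push_u)) { active[push_u, u] <- TRUE; changed <- TRUE }
        }
        if (!changed) break
      }
      counts <- counts + tabulate(rowSums(active) + 1L, nbins = n + 1L)
      left <- left - b
    }
  })
  new_empirical(counts, reps = as.integer(reps), seed = as.integer(seed),
                method = "bond_percolation")
}
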
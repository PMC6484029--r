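# Loopy belief propagation for activation probabilities. For each directed
# edge i->j, p_ij = P(node i activates, with j's influence removed) satisfies
#   p_ij = E[ Rc_i(S) ],  S ~ Poisson-binomial of {p_ni : n in nb(i) \ j},
# and the node marginal p_i uses all neighbors. The expectation is computed
# by exact convolution of the incoming Bernoulli masses.

#' Loopy belief propagation for activation probabilities
#'
#' Iterates the self-consistent equations for the directed-edge probabilities
#' `p_ij` (probability that `i` activates before `j`, with `j` held
#' inactive) and derives the node marginals `p_i`. Initialization is `p_ij =
#' R_i(0)`; a fixed number of sweeps is run (default 50) and the largest
#' update of the final sweep is reported so non-convergence can be detected
#' by the caller — it is never fatal. On a tree the fixed point is exact once
#' the number of sweeps exceeds the diameter.
#'
#' @param edges Edge tibble.
#' @param model A [cascade_model()]; ignored when `responses` is given.
#' @param iters Number of sweeps through every directed edge.
#' @param sweep `"synchronous"` (Jacobi: all updates use the previous sweep)
#'   or `"asynchronous"` (in-place, in edge order).
#' @param responses Optional named list of `response_function`s.
#' @return An object of class `edge_beliefs`: list with `p_edge` (tibble
#'   `from`, `to`, `p` where `p = P(from active, given to removed)`),
#'   `p_node` (tibble `node`, `p`), `iterations_run`, `max_last_delta`.
#' @export
#' @examples
#' run_loopy_bp(gen_star(3), cascade_model("icm", p = 0.2))
run_loopy_bp <- function(edges, model = NULL, iters = 50L,
                         sweep = c("synchronous", "asynchronous"),
                         responses = NULL) {
  sweep <- match.arg(sweep)
  net <- build_network(edges, nodes = edges_node_set(edges))
  if (is.null(responses)) {
    if (is.null(model)) abort("either `model` or `responses` must be supplied")
    responses <- lapply(seq_len(net$n), function(i)
      build_response(model, net$deg[i], node = net$nodes[i]))
  } else {
    responses <- responses[net$nodes]
  }
  n <- net$n
  # directed edges: one per (node, neighbor) pair
  de_from <- rep.int(seq_len(n), lengths(net$adj))
  de_to <- unlist(net$adj, use.names = FALSE)
  nde <- length(de_from)
  # for updating p_{i -> j} we need incoming p_{n -> i}: index of directed
  # edge (n -> i) for each neighbor n of i
  in_edge <- vector("list", n)   # directed-edge ids n->i, aligned with adj[[i]]
  key <- paste(de_from, de_to)
  for (i in seq_len(n)) {
    in_edge[[i]] <- match(paste(net$adj[[i]], i), key)
  }
  out_by_node <- split(seq_len(nde), de_from)
  p <- vapply(seq_len(nde), function(e) responses[[de_from[e]]]$R[1], numeric(1))
  delta <- 0
  for (it in seq_len(iters)) {
    src <- if (sweep == "synchronous") p else NULL
    pnew <- p
    for (i in seq_len(n)) {
      oe <- out_by_node[[as.character(i)]]
      if (is.null(oe)) next
      Rc <- responses[[i]]$Rc
      cur <- if (sweep == "synchronous") src else pnew
      q <- cur[in_edge[[i]]]
      d <- length(q)
      for (k in seq_along(oe)) {
        pmf <- poisbinom_pmf(q[-k])
        val <- sum(pmf * Rc[seq_len(d)])
        if (sweep == "asynchronous") pnew[oe[k]] <- val else pnew[oe[k]] <- val
      }
    }
    if (it == iters) delta <- max(abs(pnew - p), 0)
    p <- pnew
  }
  p_node <- vapply(seq_len(n), function(i) {
    q <- p[in_edge[[i]]]
    pmf <- poisbinom_pmf(q)
    sum(pmf * responses[[i]]$Rc[seq_len(length(q) + 1L)])
  }, numeric(1))
  structure(
    list(
      p_edge = tibble(from = net$nodes[de_from], to = net$nodes[de_to], p = p),
      p_node = tibble(node = net$nodes, p = p_node),
      iterations_run = as.integer(iters),
      max_last_delta = delta
    ),
    class = "edge_beliefs"
  )
}

#' @export
print.edge_beliefs <- function(x, ...) {
  cat(sprintf("<edge_beliefs> %d directed edges, %d nodes; %d sweeps, final delta %.3g\n",
              nrow(x$p_edge), nrow(x$p_node), x$iterations_run, x$max_last_delta))
  cat(sprintf("  mean activation probability %.6g\n", mean(x$p_node$p)))
  invisible(x)
}

#' @export
tidy.edge_beliefs <- function(x, ...) x$p_edge

#' @export
glance.edge_beliefs <- function(x, ...) {
  tibble(n_nodes = nrow(x$p_node),
         n_directed_edges = nrow(x$p_edge),
         iterations = x$iterations_run,
         max_last_delta = x$max_last_delta,
         mean_activation = mean(x$p_node$p))
}

#' @export
autoplot.edge_beliefs <- function(object, ...) {
  ggplot(object$p_node, aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = 30) +
    labs(x = "node activation probability", y = "count",
         title = "Belief-propagation marginals")
}

#' Mean final cascade size implied by BP marginals
#'
#' @param b An `edge_beliefs` object.
#' @return `mean(p_i)`, the BP estimate of the expected final fraction of
#'   active nodes.
#' @export
mean_cascade_size <- function(b) {
  stopifnot(inherits(b, "edge_beliefs"))
  mean(b$p_node$p)
}
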
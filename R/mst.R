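#' Randomized minimum spanning forest with deleted-neighbor bookkeeping
#'
#' Assigns every edge an i.i.d. uniform pseudo-random weight from the seeded
#' generator (or uses supplied weights) and returns a minimum-weight spanning
#' forest together with, for each node, the neighbors it lost: `dnb(i)` is the
#' set of former neighbors of `i` whose edge was deleted, and `m_i = |dnb(i)|`.
#' With distinct random weights the forest is unique, so the result is
#' deterministic given the seed. The alternative weighting
#' `scheme = "degree"` uses minus the endpoint degree sum, preferring to cut
#' edges between high-degree nodes.
#'
#' @param edges Edge tibble (any network, possibly disconnected).
#' @param seed Integer seed for the random edge weights.
#' @param weights Optional numeric vector of edge weights (one per edge row,
#'   after deduplication); overrides `seed`.
#' @param scheme `"random"` (default) or `"degree"`.
#' @param nodes Optional full node set (to keep isolated nodes).
#' @return An object of class `spanning_forest`: list with `tree` (edge
#'   tibble of kept edges), `deleted` (edge tibble of removed edges), `dnb`
#'   (named list of character vectors), `m` (named integer), `nodes`.
#' @export
minimum_spanning_tree <- function(edges, seed = 1L, weights = NULL,
                                  scheme = c("random", "degree"), nodes = NULL) {
  scheme <- match.arg(scheme)
  net <- build_network(edges, nodes = edges_node_set(edges, nodes))
  ne <- nrow(net$ei)
  g <- net_to_igraph(net)
  if (is.null(weights)) {
    weights <- switch(scheme,
      random = with_seed(seed, runif(ne)),
      degree = -(net$deg[net$ei[, 1]] + net$deg[net$ei[, 2]]) +
        with_seed(seed, runif(ne)) * 1e-9  # jitter breaks ties deterministically
    )
  } else if (length(weights) != ne) {
    abort(sprintf("need %d weights, got %d", ne, length(weights)))
  }
  mst <- igraph::mst(g, weights = weights)
  kept_pairs <- igraph::as_edgelist(mst, names = FALSE)
  all_key <- paste(pmin(net$ei[, 1], net$ei[, 2]), pmax(net$ei[, 1], net$ei[, 2]))
  kept_key <- paste(pmin(kept_pairs[, 1], kept_pairs[, 2]),
                    pmax(kept_pairs[, 1], kept_pairs[, 2]))
  kept <- all_key %in% kept_key
  tree_ei <- net$ei[kept, , drop = FALSE]
  del_ei <- net$ei[!kept, , drop = FALSE]
  dnb <- stats::setNames(rep(list(character(0)), net$n), net$nodes)
  if (nrow(del_ei) > 0) {
    for (r in seq_len(nrow(del_ei))) {
      a <- del_ei[r, 1]; b <- del_ei[r, 2]
      dnb[[a]] <- c(dnb[[a]], net$nodes[b])
      dnb[[b]] <- c(dnb[[b]], net$nodes[a])
    }
  }
  structure(
    list(
      tree = tibble(from = net$nodes[tree_ei[, 1]], to = net$nodes[tree_ei[, 2]]),
      deleted = tibble(from = net$nodes[del_ei[, 1]], to = net$nodes[del_ei[, 2]]),
      dnb = dnb,
      m = stats::setNames(lengths(dnb), net$nodes),
      nodes = net$nodes
    ),
    class = "spanning_forest"
  )
}

#' @export
print.spanning_forest <- function(x, ...) {
  cat(sprintf("<spanning_forest> %d nodes, %d kept edges, %d deleted edges\n",
              length(x$nodes), nrow(x$tree), nrow(x$deleted)))
  invisible(x)
}

#' @export
tidy.spanning_forest <- function(x, ...) {
  bind_rows(
    mutate(x$tree, status = "kept"),
    mutate(x$deleted, status = "deleted")
  )
}
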
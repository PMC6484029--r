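# Networks are plain edge tables: a tibble with character columns `from` and
# `to`, one row per undirected edge. Node identifiers are opaque strings; the
# internal dense integer index follows first-appearance order in the table.

#' Read an undirected edge list
#'
#' Parses a plain-text edge list with one edge per line: two
#' whitespace-separated node identifiers. Lines starting with `#` and blank
#' lines are ignored. Duplicate edges (in either orientation) are collapsed
#' with a warning; self-loops are an error.
#'
#' @param path Path to the edge-list file (or a connection).
#' @return A tibble with character columns `from` and `to`, one row per
#'   distinct undirected edge, in first-appearance order.
#' @seealso [write_edge_list()]
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy path", "a b", "b c"), f)
#' read_edge_list(f)
read_edge_list <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    abort(sprintf("edge list '%s' does not exist", path))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(from = character(), to = character()))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 2L)) {
    bad <- idx[which(nt != 2L)[1]]
    abort(sprintf("expected 2 whitespace-separated tokens at line %d, found %d",
                  bad, nt[which(nt != 2L)[1]]))
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), 2L)
  loop <- from == to
  if (any(loop)) {
    abort(sprintf("self-loop at line %d ('%s')", idx[which(loop)[1]], from[which(loop)[1]]))
  }
  edges <- tibble(from = from, to = to)
  ded <- dedup_edges(edges)
  if (nrow(ded) < nrow(edges)) {
    warn(sprintf("removed %d duplicate edge(s)", nrow(edges) - nrow(ded)))
  }
  ded
}

#' Write an undirected edge list
#'
#' @param edges Edge tibble (columns `from`, `to`).
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, comment = NULL) {
  edges <- as_edge_tbl(edges)
  out <- character(0)
  if (!is.null(comment)) out <- paste0("# ", comment)
  out <- c(out, paste(edges$from, edges$to))
  writeLines(out, path)
  invisible(path)
}

as_edge_tbl <- function(edges) {
  if (!is.data.frame(edges)) {
    abort("`edges` must be a data frame with columns `from` and `to`")
  }
  if (!all(c("from", "to") %in% names(edges))) {
    if (ncol(edges) >= 2L) {
      edges <- stats::setNames(edges[1:2], c("from", "to"))
    } else {
      abort("`edges` must have columns `from` and `to`")
    }
  }
  tibble(from = as.character(edges$from), to = as.character(edges$to))
}

# canonical unordered key for an edge
edge_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "\r")
}

dedup_edges <- function(edges) {
  edges[!duplicated(edge_key(edges$from, edges$to)), , drop = FALSE]
}

# Generators can mark the intended node count (isolated nodes carry no edge);
# entry points pass this through so degree-0 nodes stay part of the system.
edges_node_set <- function(edges, nodes = NULL) {
  if (!is.null(nodes)) return(as.character(nodes))
  nn <- attr(edges, "n_nodes")
  if (!is.null(nn)) as.character(seq_len(nn)) else NULL
}

# Internal dense representation: nodes (character), n, ei (2-col integer edge
# matrix), adj (list of integer neighbor vectors), deg (integer vector).
build_network <- function(edges, nodes = NULL) {
  edges <- as_edge_tbl(edges)
  if (any(edges$from == edges$to)) {
    abort("self-loops are not allowed")
  }
  edges <- dedup_edges(edges)
  seen <- unique(c(rbind(edges$from, edges$to)))
  nodes <- if (is.null(nodes)) seen else unique(c(as.character(nodes), seen))
  n <- length(nodes)
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  ei <- cbind(i, j)
  adj <- vector("list", n)
  if (nrow(ei) > 0) {
    adj_all <- split(c(j, i), c(i, j))
    adj[as.integer(names(adj_all))] <- lapply(adj_all, as.integer)
  }
  adj[vapply(adj, is.null, logical(1))] <- list(integer(0))
  deg <- lengths(adj)
  list(nodes = nodes, n = n, ei = ei, adj = adj, deg = deg)
}

# igraph with vertices 1..n in index order (handles isolated nodes)
net_to_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n, directed = FALSE)
  if (nrow(net$ei) > 0) g <- igraph::add_edges(g, t(net$ei))
  g
}

#' Per-node degrees of an edge table
#'
#' @param edges Edge tibble.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated (degree 0).
#' @return Tibble with columns `node`, `degree`.
#' @export
degree_sequence <- function(edges, nodes = NULL) {
  net <- build_network(edges, nodes = nodes)
  tibble(node = net$nodes, degree = as.integer(net$deg))
}

#' Restrict an edge table to its largest connected component
#'
#' @param edges Edge tibble.
#' @return Edge tibble containing only edges of the largest component (ties
#'   broken by first-appearance node order).
#' @export
largest_component <- function(edges) {
  net <- build_network(edges)
  comp <- igraph::components(net_to_igraph(net))
  big <- which.max(comp$csize)
  keep <- comp$membership[net$ei[, 1]] == big
  tibble(from = net$nodes[net$ei[keep, 1]], to = net$nodes[net$ei[keep, 2]])
}

#' Synthetic network generators
#'
#' Edge-table generators for the study networks: stars, paths, uniformly
#' random labeled trees (Prüfer construction), hub trees (a path of
#' high-degree hubs with pendant leaves), and power-law configuration models.
#'
#' `gen_hub_tree()` connects the listed hubs along a path and attaches leaves
#' until each hub reaches its requested degree. If `n` exceeds the minimum
#' node count implied by the hub degrees, the extra nodes are attached as
#' chains below the leaves, round-robin, so hub degrees are preserved.
#'
#' `gen_power_law_config()` draws i.i.d. degrees from a truncated power law
#' \eqn{p(d) \propto d^{-\gamma}} on `d_min..d_max`, resamples one degree until
#' the sum is even, wires stubs by uniform random matching, then discards
#' self-loops and collapses multi-edges (the realized degree distortion is
#' reported via a message).
#'
#' @param n Number of nodes.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param hub_degrees Integer vector of requested hub degrees (length >= 1).
#' @param gamma Power-law exponent (> 1).
#' @param d_min,d_max Degree support bounds, `1 <= d_min <= d_max < n`.
#' @return An edge tibble (columns `from`, `to`).
#' @name generators
NULL

#' @rdname generators
#' @export
gen_star <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(tibble(from = character(), to = character()))
  tibble(from = "1", to = as.character(2:n))
}

#' @rdname generators
#' @export
gen_path <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(tibble(from = character(), to = character()))
  tibble(from = as.character(1:(n - 1)), to = as.character(2:n))
}

#' @rdname generators
#' @export
gen_uniform_tree <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  if (n == 1L) return(tibble(from = character(), to = character()))
  if (n == 2L) return(tibble(from = "1", to = "2"))
  el <- with_seed(seed, igraph::as_edgelist(igraph::sample_tree(n, method = "prufer")))
  tibble(from = as.character(el[, 1]), to = as.character(el[, 2]))
}

#' @rdname generators
#' @export
gen_hub_tree <- function(hub_degrees, n = NULL) {
  k <- length(hub_degrees)
  stopifnot(k >= 1, all(hub_degrees >= 1))
  path_deg <- if (k == 1L) 0L else c(1L, rep(2L, max(k - 2L, 0L)), 1L)
  leaves_per_hub <- hub_degrees - path_deg
  if (any(leaves_per_hub < 0)) {
    abort("hub degree smaller than its on-path degree; hub spec infeasible")
  }
  n_min <- k + sum(leaves_per_hub)
  if (is.null(n)) n <- n_min
  if (n < n_min) {
    abort(sprintf("n = %d is below the %d nodes implied by the hub degrees", n, n_min))
  }
  from <- character(0); to <- character(0)
  hubs <- as.character(seq_len(k))
  if (k > 1L) {
    from <- c(from, hubs[-k]); to <- c(to, hubs[-1])
  }
  nxt <- k + 1L
  leaves <- character(0)
  for (h in seq_len(k)) {
    if (leaves_per_hub[h] > 0) {
      ids <- as.character(seq(nxt, length.out = leaves_per_hub[h]))
      from <- c(from, rep(hubs[h], leaves_per_hub[h])); to <- c(to, ids)
      leaves <- c(leaves, ids)
      nxt <- nxt + leaves_per_hub[h]
    }
  }
  extra <- n - n_min
  if (extra > 0) {
    if (length(leaves) == 0L) abort("no leaves available to attach extra nodes")
    tails <- leaves
    for (e in seq_len(extra)) {
      slot <- ((e - 1L) %% length(tails)) + 1L
      id <- as.character(nxt); nxt <- nxt + 1L
      from <- c(from, tails[slot]); to <- c(to, id)
      tails[slot] <- id
    }
  }
  tibble(from = from, to = to)
}

#' @rdname generators
#' @export
gen_power_law_config <- function(n, gamma = 2.5, d_min = 1L, d_max, seed = 1L) {
  stopifnot(n >= 2, gamma > 1, d_min >= 1, d_min <= d_max, d_max < n)
  support <- d_min:d_max
  pr <- support^(-gamma)
  pr <- pr / sum(pr)
  with_seed(seed, {
    deg <- sample(support, n, replace = TRUE, prob = pr)
    while (sum(deg) %% 2L == 1L) {
      pos <- sample.int(n, 1L)
      deg[pos] <- sample(support, 1L, prob = pr)
    }
    stubs <- sample(rep.int(seq_len(n), deg))
    m <- length(stubs) / 2L
    from <- stubs[seq_len(m) * 2L - 1L]
    to <- stubs[seq_len(m) * 2L]
  })
  keep <- from != to
  n_loops <- sum(!keep)
  edges <- dedup_edges(tibble(from = as.character(from[keep]), to = as.character(to[keep])))
  n_multi <- sum(keep) - nrow(edges)
  if (n_loops + n_multi > 0) {
    inform(sprintf("configuration model simplified: %d self-loop(s) and %d multi-edge(s) dropped",
                   n_loops, n_multi))
  }
  # keep isolated nodes visible downstream by re-labeling to the full 1..n set
  attr(edges, "n_nodes") <- n
  edges
}

#' Expected mean degree of the truncated power law
#'
#' Direct summation of \eqn{\sum d \, d^{-\gamma} / \sum d^{-\gamma}} over the
#' degree support; used to sanity-check configuration-model draws.
#'
#' @inheritParams generators
#' @return A single number.
#' @export
power_law_mean_degree <- function(gamma, d_min, d_max) {
  d <- d_min:d_max
  sum(d * d^(-gamma)) / sum(d^(-gamma))
}

#' Generate a network by kind
#'
#' Dispatcher used by the command-line interface.
#'
#' @param kind One of `"star"`, `"path"`, `"uniform_tree"`, `"hub_tree"`,
#'   `"power_law_config_model"`.
#' @param ... Passed to the matching `gen_*()` function.
#' @return An edge tibble.
#' @export
generate_network <- function(kind, ...) {
  switch(kind,
    star = gen_star(...),
    path = gen_path(...),
    uniform_tree = gen_uniform_tree(...),
    hub_tree = gen_hub_tree(...),
    power_law_config_model = gen_power_law_config(...),
    abort(sprintf("unknown network kind '%s'", kind))
  )
}
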
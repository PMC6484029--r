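#' Root a tree
#'
#' Orients an undirected tree from a chosen root, producing the parent and
#' children maps, a postorder traversal (children before parents), the tree
#' height, and subtree sizes. With `root = NULL` a tree center is used: a node
#' of minimum eccentricity (the midpoint of a diameter path), ties broken by
#' node order. The root only affects traversal cost, never the cascade size
#' distribution.
#'
#' @param edges Edge tibble describing a tree (connected, `N - 1` edges).
#' @param root Node id, or `NULL` for the automatic center choice.
#' @return An object of class `rooted_tree`: a list with `nodes`, `root`,
#'   `parent` (named character, `NA` at the root), `children` (named list),
#'   `postorder` (character), `height`, and `subtree_size` (named integer).
#' @export
#' @examples
#' root_tree(gen_path(5))$root  # center of the path
root_tree <- function(edges, root = NULL) {
  net <- build_network(edges)
  rooted <- root_tree_int(net, root_idx = if (is.null(root)) NULL else {
    ri <- match(as.character(root), net$nodes)
    if (is.na(ri)) abort(sprintf("root '%s' is not a node of the tree", root))
    ri
  })
  nodes <- net$nodes
  parent <- ifelse(is.na(rooted$parent), NA_character_, nodes[rooted$parent])
  names(parent) <- nodes
  children <- lapply(rooted$children, function(ix) nodes[ix])
  names(children) <- nodes
  structure(
    list(nodes = nodes, root = nodes[rooted$root],
         parent = parent, children = children,
         postorder = nodes[rooted$postorder],
         height = rooted$height,
         subtree_size = stats::setNames(rooted$subtree_size, nodes),
         net = net, root_idx = rooted$root, int = rooted),
    class = "rooted_tree"
  )
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(sprintf("<rooted_tree> %d nodes, root '%s', height %d\n",
              length(x$nodes), x$root, x$height))
  invisible(x)
}

# Integer-index machinery used on large trees.
root_tree_int <- function(net, root_idx = NULL) {
  n <- net$n
  if (nrow(net$ei) != n - 1L) {
    abort(sprintf("not a tree: %d nodes but %d edges", n, nrow(net$ei)))
  }
  if (n == 1L) {
    return(list(root = 1L, parent = NA_integer_, children = list(integer(0)),
                postorder = 1L, height = 0L, subtree_size = 1L))
  }
  if (is.null(root_idx)) root_idx <- tree_center(net)
  ord <- integer(n); parent <- rep(NA_integer_, n); depth <- integer(n)
  visited <- logical(n)
  ord[1] <- root_idx; visited[root_idx] <- TRUE
  head_i <- 1L; tail_i <- 1L
  adj <- net$adj
  while (head_i <= tail_i) {
    v <- ord[head_i]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        tail_i <- tail_i + 1L
        ord[tail_i] <- w
        visited[w] <- TRUE
        parent[w] <- v
        depth[w] <- depth[v] + 1L
      }
    }
    head_i <- head_i + 1L
  }
  if (tail_i < n) abort("not a tree: graph is disconnected")
  postorder <- rev(ord)
  children <- vector("list", n)
  nonroot <- setdiff(seq_len(n), root_idx)
  ch <- split(nonroot, parent[nonroot])
  children[as.integer(names(ch))] <- ch
  children[vapply(children, is.null, logical(1))] <- list(integer(0))
  size <- rep(1L, n)
  for (v in postorder) {
    p <- parent[v]
    if (!is.na(p)) size[p] <- size[p] + size[v]
  }
  list(root = root_idx, parent = parent, children = children,
       postorder = postorder, height = max(depth), subtree_size = size)
}

# BFS distances from a start index (tree or general graph, unweighted)
bfs_dist <- function(net, start) {
  n <- net$n
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  q <- integer(n); q[1] <- start; head_i <- 1L; tail_i <- 1L
  prev <- rep(NA_integer_, n)
  while (head_i <= tail_i) {
    v <- q[head_i]
    for (w in net$adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        prev[w] <- v
        tail_i <- tail_i + 1L
        q[tail_i] <- w
      }
    }
    head_i <- head_i + 1L
  }
  list(dist = dist, prev = prev)
}

# Center of a tree: midpoint of a diameter path (double BFS); among the one
# or two midpoints, the smaller node index wins.
tree_center <- function(net) {
  b1 <- bfs_dist(net, 1L)
  u <- which.max(b1$dist)
  b2 <- bfs_dist(net, u)
  v <- which.max(b2$dist)
  path <- integer(0)
  cur <- v
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- b2$prev[cur]
  }
  L <- length(path) - 1L
  mids <- unique(c(path[L %/% 2L + 1L], path[(L + 1L) %/% 2L + 1L]))
  min(mids)
}
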
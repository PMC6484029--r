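test_that("edge lists parse, deduplicate and reject malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "a b", "", "b c"), f)
  e <- read_edge_list(f)
  expect_equal(e$from, c("a", "b"))
  expect_equal(e$to, c("b", "c"))

  writeLines(c("a b", "a b", "b a"), f)
  expect_warning(e2 <- read_edge_list(f), "duplicate")
  expect_equal(nrow(e2), 1L)

  writeLines(c("a b", "c c"), f)
  expect_error(read_edge_list(f), "self-loop at line 2")
  writeLines("a b c", f)
  expect_error(read_edge_list(f), "line 1")
})

test_that("write/read round trip preserves the network", {
  e <- gen_uniform_tree(15, seed = 4)
  f <- withr::local_tempfile()
  write_edge_list(e, f, comment = "fixture")
  e2 <- read_edge_list(f)
  expect_equal(e2, e)
})

test_that("star and path generators have the expected shape", {
  s <- gen_star(4)
  ds <- degree_sequence(s)
  expect_equal(sort(ds$degree), c(1, 1, 1, 3))
  p <- gen_path(5)
  dp <- degree_sequence(p)
  expect_equal(sum(dp$degree == 1), 2)
  expect_equal(sum(dp$degree == 2), 3)
})

test_that("uniform random trees are trees and seed-deterministic", {
  for (n in c(2, 5, 9, 30)) {
    e <- gen_uniform_tree(n, seed = n)
    expect_equal(nrow(e), n - 1L)
    net_nodes <- unique(c(e$from, e$to))
    expect_length(net_nodes, n)
    expect_error(root_tree(e), NA)  # connected tree roots fine
  }
  expect_identical(gen_uniform_tree(12, seed = 3), gen_uniform_tree(12, seed = 3))
  expect_false(identical(gen_uniform_tree(12, seed = 3), gen_uniform_tree(12, seed = 4)))
})

test_that("hub trees honor hub degrees and node budget", {
  e <- gen_hub_tree(c(5, 4))
  ds <- degree_sequence(e)
  expect_equal(ds$degree[ds$node == "1"], 5)
  expect_equal(ds$degree[ds$node == "2"], 4)
  expect_equal(nrow(e), nrow(ds) - 1L)  # tree

  e2 <- gen_hub_tree(c(5, 4), n = 15)
  ds2 <- degree_sequence(e2)
  expect_equal(nrow(ds2), 15)
  expect_equal(ds2$degree[ds2$node == "1"], 5)  # extras never touch hubs
  expect_equal(ds2$degree[ds2$node == "2"], 4)
  expect_error(gen_hub_tree(c(5, 4), n = 3), "below")
})

test_that("configuration model respects degree bounds and the truncated-law mean", {
  e <- suppressMessages(gen_power_law_config(543, 2.5, 1, 25, seed = 9))
  ds <- degree_sequence(e, nodes = as.character(1:543))
  expect_true(all(ds$degree >= 0 & ds$degree <= 25))
  expected <- power_law_mean_degree(2.5, 1, 25)
  expect_lt(abs(mean(ds$degree) - expected), 0.3)
  expect_identical(
    suppressMessages(gen_power_law_config(100, 2.5, 1, 10, seed = 2)),
    suppressMessages(gen_power_law_config(100, 2.5, 1, 10, seed = 2))
  )
})

test_that("spanning forest keeps trees intact and books deleted neighbors", {
  tr <- gen_uniform_tree(10, seed = 1)
  sp <- minimum_spanning_tree(tr, seed = 5)
  expect_equal(nrow(sp$tree), 9)
  expect_equal(nrow(sp$deleted), 0)
  expect_true(all(lengths(sp$dnb) == 0))

  sp_tri <- minimum_spanning_tree(tri_edges(), seed = 3)
  expect_equal(nrow(sp_tri$tree), 2)
  expect_equal(nrow(sp_tri$deleted), 1)
  u <- sp_tri$deleted$from[1]; v <- sp_tri$deleted$to[1]
  expect_equal(sp_tri$dnb[[u]], v)
  expect_equal(sp_tri$dnb[[v]], u)

  # denser graph: forest size and sum of m_i
  e <- dplyr::bind_rows(cycle_edges(8), tibble::tibble(from = c("1", "2"), to = c("5", "7")))
  sp2 <- minimum_spanning_tree(e, seed = 11)
  expect_equal(nrow(sp2$tree), 7)
  expect_equal(sum(sp2$m), 2 * (nrow(e) - 7))
  # union of kept and deleted edges is the original edge set
  all_edges <- dplyr::bind_rows(sp2$tree, sp2$deleted)
  key <- function(d) sort(paste(pmin(d$from, d$to), pmax(d$from, d$to)))
  expect_equal(key(all_edges), key(e))
})

test_that("spanning forest is deterministic in the seed and honors weights", {
  e <- cycle_edges(6)
  expect_identical(minimum_spanning_tree(e, seed = 2)$deleted,
                   minimum_spanning_tree(e, seed = 2)$deleted)
  w <- c(10, rep(1, 5))  # force the first edge out
  sp <- minimum_spanning_tree(e, weights = w)
  expect_equal(nrow(sp$deleted), 1)
  expect_equal(sp$deleted$from, "1")
})

test_that("tree rooting picks centers and honors explicit roots", {
  p5 <- gen_path(5)
  r <- root_tree(p5)
  expect_equal(r$root, "3")
  expect_equal(r$height, 2)
  expect_equal(r$subtree_size[[r$root]], 5)

  s <- root_tree(gen_star(7))
  expect_equal(s$root, "1")
  expect_equal(s$height, 1)

  r2 <- root_tree(gen_path(3), root = "1")
  expect_equal(r2$root, "1")
  expect_equal(r2$height, 2)

  expect_error(root_tree(tri_edges()), "not a tree")
  disc <- tibble::tibble(from = c("a", "c"), to = c("b", "d"))
  expect_error(root_tree(disc), "not a tree")
})

test_that("postorder visits children before parents with consistent sizes", {
  tr <- gen_uniform_tree(25, seed = 8)
  r <- root_tree(tr)
  pos <- match(r$nodes, r$postorder)
  for (v in r$nodes) {
    for (ch in r$children[[v]]) expect_lt(pos[match(ch, r$nodes)], pos[match(v, r$nodes)])
    expect_equal(r$subtree_size[[v]],
                 1L + sum(vapply(r$children[[v]], function(c) r$subtree_size[[c]], integer(1))))
  }
})

test_that("largest_component restricts to the biggest piece", {
  e <- dplyr::bind_rows(gen_path(4),
                        tibble::tibble(from = c("x"), to = c("y")))
  lc <- largest_component(e)
  expect_setequal(unique(c(lc$from, lc$to)), as.character(1:4))
})
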
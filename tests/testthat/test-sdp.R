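test_that("leaf messages match the degree-1 base case", {
  r <- build_response(icm(0.2), 1)
  m <- leaf_message(r)
  expect_equal(m$pA, matrix(c(0.64, 0.16, 0, 0.2), 2, 2), tolerance = 1e-15)
  expect_equal(m$pI, matrix(c(0.8, 0, 0, 0.2), 2, 2), tolerance = 1e-15)
  expect_equal(sum(m$pI), 1, tolerance = 1e-15)
  expect_equal(sum(m$pA), 1, tolerance = 1e-15)

  # p = 0: nothing activates without help
  m0 <- leaf_message(build_response(icm(0), 1))
  expect_equal(m0$pI[1, 1], 1)
  expect_equal(m0$pA[1, 1], 1)
  expect_equal(sum(m0$pI) + sum(m0$pA), 2)

  expect_error(leaf_message(build_response(icm(0.2), 3)), "degree 1")

  # the internal-node update with the identity convolution reproduces it
  id_cc <- convolve_children(list())
  expect_equal(internal_message(id_cc, r)$pI, m$pI, tolerance = 1e-15)
  expect_equal(internal_message(id_cc, r)$pA, m$pA, tolerance = 1e-15)
})

test_that("child convolution adds counts and indicators", {
  leaf <- leaf_message(build_response(icm(0.2), 1))
  cc <- convolve_children(list(leaf, leaf))
  expect_equal(cc$I, diag(c(0.64, 0.32, 0.04)), tolerance = 1e-15)
  expect_equal(cc$A[1, ], c(0.4096, 0, 0), tolerance = 1e-15)
  expect_equal(cc$A[2, ], c(0.2048, 0.256, 0), tolerance = 1e-15)
  expect_equal(cc$A[3, ], c(0.0256, 0.064, 0.04), tolerance = 1e-15)
  expect_equal(sum(cc$I), 1, tolerance = 1e-14)
  expect_equal(sum(cc$A), 1, tolerance = 1e-14)

  # single message: indicator column reinterpreted as the count axis
  cc1 <- convolve_children(list(leaf))
  expect_equal(cc1$I, leaf$pI)
  expect_equal(cc1$A, leaf$pA)
})

test_that("convolved tables vanish above the indicator diagonal (t < a)", {
  tr <- gen_uniform_tree(9, seed = 21)
  resp <- build_responses(tr, tmod())
  r <- root_tree(tr)
  msgs <- list()
  for (v in r$postorder) {
    kids <- r$children[[v]]
    cc <- convolve_children(msgs[kids])
    for (a in seq_len(ncol(cc$I)) - 1L) {
      if (a >= 1) {
        expect_equal(cc$I[seq_len(min(a, nrow(cc$I))), a + 1], rep(0, min(a, nrow(cc$I))))
        expect_equal(cc$A[seq_len(min(a, nrow(cc$A))), a + 1], rep(0, min(a, nrow(cc$A))))
      }
    }
    if (v != r$root) {
      msgs[[v]] <- internal_message(cc, resp[[v]], node = v)
      expect_equal(sum(msgs[[v]]$pI), 1, tolerance = 1e-12)
      expect_equal(sum(msgs[[v]]$pA), 1, tolerance = 1e-12)
      expect_equal(msgs[[v]]$pI[, 2], msgs[[v]]$pA[, 2], tolerance = 1e-14)
      expect_equal(msgs[[v]]$pI[1, 2], 0)  # an active node counts itself
    }
  }
})

test_that("tiny trees reproduce hand-enumerated distributions", {
  d2 <- run_sdp(gen_path(2), icm(0.2))
  expect_equal(d2$prob, c(0.64, 0.256, 0.104), tolerance = 1e-14)

  d3 <- run_sdp(gen_star(3), icm(0.2))
  expect_equal(d3$prob, c(0.512, 0.28672, 0.1536, 0.04768), tolerance = 1e-14)
  expect_equal(d3$prob[1], 0.8^3, tolerance = 1e-14)
  expect_equal(cascade_mean(d3), 0.73696, tolerance = 1e-10)

  # single node: [1 - R(0), R(0)]
  one <- tibble::tibble(from = character(), to = character())
  attr(one, "n_nodes") <- 1L
  d1 <- run_sdp(one, icm(0.3))
  expect_equal(d1$prob, c(0.7, 0.3), tolerance = 1e-15)
})

test_that("the sweep equals exhaustive enumeration on random small trees", {
  for (i in 1:30) {
    n <- 2L + (i %% 9L)
    tr <- gen_uniform_tree(n, seed = 100 + i)
    m <- random_model(i)
    sdp <- run_sdp(tr, m)
    bf <- brute_force_distribution(tr, m)
    expect_lt(max(abs(sdp$prob - bf$prob)), 1e-10)
  }
})

test_that("the distribution is invariant to the choice of root", {
  d_a <- run_sdp(gen_path(2), icm(0.2), root = "1")
  d_b <- run_sdp(gen_path(2), icm(0.2), root = "2")
  expect_equal(d_a$prob, d_b$prob, tolerance = 1e-14)
  for (i in 1:5) {
    tr <- gen_uniform_tree(12, seed = 300 + i)
    nodes <- unique(c(tr$from, tr$to))
    ref <- run_sdp(tr, tmod(), root = nodes[1])
    for (r in nodes[c(5, 12)]) {
      expect_lt(max(abs(run_sdp(tr, tmod(), root = r)$prob - ref$prob)), 1e-10)
    }
  }
})

test_that("degree/response mismatches are rejected", {
  tr <- gen_path(3)
  resp <- build_responses(gen_star(3), icm(0.2))
  names(resp) <- c("1", "2", "3")
  expect_error(run_sdp(tr, responses = resp), "mismatch")
  expect_error(run_sdp(tr, responses = build_responses(tr, icm(0.2))[1:2]),
               "no response function")
})

test_that("grid mode is exact for C >= N and preserves the mean otherwise", {
  tr <- gen_uniform_tree(30, seed = 17)
  exact <- run_sdp(tr, icm(0.2))
  expect_identical(run_sdp(tr, icm(0.2), resolution = 30)$prob, exact$prob)
  expect_identical(run_sdp(tr, icm(0.2), resolution = 64)$prob, exact$prob)

  for (C in c(6, 10, 16)) {
    g <- run_sdp(tr, icm(0.2), resolution = C)
    expect_equal(sum(g$prob), 1, tolerance = 1e-10)
    expect_lt(abs(cascade_mean(g) - cascade_mean(exact)), 1e-9)
    # re-binning engages only once a support exceeds C + 1 points: the
    # result is either still exact or on the equidistant N/C lattice
    step <- g$t[2] - g$t[1]
    expect_true(step == 1 || step == 30 / C)
    if (step == 1) expect_equal(g$prob, exact$prob, tolerance = 1e-12)
    expect_lt(max(g$t), 2 * 30)            # overshoot bounded (a few grid steps)
  }
  gt <- run_sdp(tr, tmod(), resolution = 8)
  expect_lt(abs(cascade_mean(gt) - cascade_mean(run_sdp(tr, tmod()))), 1e-9)
})

test_that("threshold contagion on a star is multi-modal", {
  d <- run_sdp(gen_star(11), tmod(0.5, 0.5))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_gte(n_local_modes(d), 2)
  bf <- brute_force_distribution(gen_star(11), tmod(0.5, 0.5))
  expect_lt(max(abs(d$prob - bf$prob)), 1e-10)
})

test_that("a Monte Carlo estimate agrees within sampling error", {
  tr <- gen_uniform_tree(12, seed = 77)
  d <- run_sdp(tr, icm(0.2))
  reps <- 2e4
  mc <- monte_carlo_distribution(tr, icm(0.2), reps = reps, seed = 5)
  tv <- total_variation(d, mc)
  expect_lt(tv, 3 * sqrt(length(d$prob)) / sqrt(reps))
})

test_that("child combination order does not change the result", {
  # hub with heterogeneous subtrees: combine order only affects speed
  tr <- gen_hub_tree(c(6, 3), n = 14)
  d1 <- run_sdp(tr, tmod(), root = "1")
  d2 <- run_sdp(tr, tmod(), root = "2")
  d3 <- run_sdp(tr, tmod())
  expect_lt(max(abs(d1$prob - d2$prob)), 1e-12)
  expect_lt(max(abs(d1$prob - d3$prob)), 1e-12)
})
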
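test_that("independent cascade responses match the closed forms", {
  r <- build_response(icm(0.2), 2)
  expect_equal(r$R, c(0.2, 0.16, 0.128, 0.512), tolerance = 1e-15)
  expect_equal(r$Rc, c(0.2, 0.36, 0.488), tolerance = 1e-15)

  r0 <- build_response(icm(0), 4)
  expect_equal(r0$R[6], 1)
  expect_equal(r0$R[1:5], rep(0, 5))

  # analytic cumulative identity for random (p, d)
  for (i in 1:20) {
    p <- ((i * 17) %% 97) / 100
    d <- 1L + (i %% 7L)
    r <- build_response(icm(p), d)
    expect_equal(r$Rc, 1 - (1 - p)^((0:d) + 1), tolerance = 1e-12)
    expect_equal(r$Rc, cumsum(r$R[1:(d + 1)]), tolerance = 1e-12)
  }
})

test_that("threshold responses evaluate the normal CDF on the degree grid", {
  r <- build_response(tmod(0.5, 0.5), 2)
  phi <- pnorm(c(-1, 0, 1))
  expect_equal(r$R, c(phi[1], phi[2] - phi[1], phi[3] - phi[2], 1 - phi[3]),
               tolerance = 1e-12)
  expect_equal(r$Rc, phi, tolerance = 1e-12)

  # degree 0: activates iff the threshold is nonpositive
  r0 <- build_response(tmod(0.5, 0.5), 0)
  expect_equal(r0$R, c(pnorm(-1), 1 - pnorm(-1)), tolerance = 1e-12)
})

test_that("responses are normalized with cumulative consistency across models", {
  for (i in 1:40) {
    m <- random_model(i)
    d <- i %% 9L
    r <- build_response(m, d)
    expect_lte(abs(sum(r$R) - 1), 1e-12)
    expect_true(all(r$R >= 0 & r$R <= 1))
    expect_true(all(diff(r$Rc) >= -1e-15))
    expect_equal(r$R[d + 2], 1 - r$Rc[d + 1], tolerance = 1e-12)
  }
})

test_that("tabulated threshold CDFs and per-node overrides work", {
  m <- cascade_model("threshold_custom_cdf", theta = c(0, 0.5, 1), F = c(0.1, 0.6, 1))
  r <- build_response(m, 2)
  expect_equal(r$Rc, c(0.1, 0.6, 1), tolerance = 1e-12)
  expect_equal(sum(r$R), 1, tolerance = 1e-12)

  mo <- cascade_model("icm", p = 0.2, per_node = list(a = list(p = 0.5)))
  expect_equal(build_response(mo, 1, node = "a")$R[1], 0.5)
  expect_equal(build_response(mo, 1, node = "b")$R[1], 0.2)
})

test_that("model configs survive a JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  m <- cascade_model("threshold_normal", mu = 0.5, sigma = 0.5,
                     per_node = list(`7` = list(mu = 0.1)))
  write_model_config(m, f)
  m2 <- read_model_config(f)
  expect_equal(m2$model, "threshold_normal")
  expect_equal(m2$mu, 0.5)
  expect_equal(m2$per_node$`7`$mu, 0.1)
  expect_equal(build_response(m2, 3, node = "7")$R,
               build_response(m, 3, node = "7")$R)
})

test_that("invalid responses and configs are rejected", {
  expect_error(response_function(c(0.5, 0.4, 0.2)), "not normalized")
  expect_error(response_function(c(0.5, 0.7, -0.2)), "outside")
  expect_error(cascade_model("icm", p = 1.2), "\\[0, 1\\]")
  expect_error(cascade_model("threshold_normal", mu = 0.5, sigma = 0), "positive")
  expect_error(cascade_model("threshold_custom_cdf", theta = c(0, 1), F = c(0.9, 0.1)),
               "nondecreasing")
})

test_that("ghost updates average the response over deleted neighbors", {
  r <- build_response(icm(0.2), 2)
  expect_identical(ghost_update(r, numeric(0)), r)

  g <- ghost_update(r, 0.5)
  expect_equal(g$degree, 1L)
  expect_equal(g$R, c(0.28, 0.144, 0.576), tolerance = 1e-15)
  expect_equal(sum(g$R), 1, tolerance = 1e-15)

  # an always-inactive ghost reduces to the response rebuilt at d - 1 (icm)
  g0 <- ghost_update(r, 0)
  r1 <- build_response(icm(0.2), 1)
  expect_equal(g0$R, r1$R, tolerance = 1e-12)
  expect_equal(g0$Rc, r1$Rc, tolerance = 1e-12)

  expect_error(ghost_update(r, c(0.1, 0.2, 0.3)), "more ghosts")
})

test_that("ghost updates preserve normalization and commute with p = 0 ghosts", {
  for (i in 1:12) {
    m <- random_model(i)
    d <- 2L + (i %% 5L)
    r <- build_response(m, d)
    gp <- (((i * 31) %% 100) / 100) * c(0.9, 0.4)[1:(1 + i %% 2)]
    g <- ghost_update(r, gp)
    expect_equal(sum(g$R), 1, tolerance = 1e-12)
    expect_equal(g$Rc, cumsum(g$R[1:(g$degree + 1)]), tolerance = 1e-12)
    # adding a p = 0 ghost first changes nothing downstream
    g2 <- ghost_update(ghost_update(r, 0), gp[1])
    g3 <- ghost_update(r, c(0, gp[1]))
    expect_equal(g2$R, g3$R, tolerance = 1e-12)
  }
})
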
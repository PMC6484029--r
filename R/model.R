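# Cascade model framework. A node of degree d is described by its response
# function: R(a) is the probability it activates exactly when a neighbors are
# active (and a-1 would not have sufficed), for a = 0..d; R(d+1) is the mass
# of never activating; Rc(a) = sum_{l<=a} R(l) is the probability it activates
# whenever a neighbors are active. Normalization: sum_{a=0}^{d+1} R(a) = 1.

#' Specify a cascade model
#'
#' @param model `"icm"` (independent cascade model: seeding/transmission
#'   probability `p`; final outcome equivalent to bond percolation),
#'   `"threshold_normal"` (fractional thresholds drawn from a Normal(`mu`,
#'   `sigma`) CDF; negative thresholds seed the cascade), or
#'   `"threshold_custom_cdf"` (thresholds from a tabulated CDF: right-
#'   continuous step function through points (`theta`, `F`)).
#' @param p Seeding/transmission probability in `[0, 1]` (icm).
#' @param mu,sigma Threshold mean and standard deviation (`sigma > 0`).
#' @param theta,F Tabulated CDF support and values (threshold_custom_cdf);
#'   `F` must be nondecreasing into `[0, 1]`.
#' @param per_node Optional named list of per-node parameter overrides, e.g.
#'   `list(a = list(p = 0.5))`.
#' @return An object of class `cascade_model`.
#' @export
#' @examples
#' cascade_model("icm", p = 0.2)
#' cascade_model("threshold_normal", mu = 0.5, sigma = 0.5)
cascade_model <- function(model = c("icm", "threshold_normal", "threshold_custom_cdf"),
                          p = NULL, mu = NULL, sigma = NULL,
                          theta = NULL, F = NULL, per_node = NULL) {
  model <- match.arg(model)
  cfg <- switch(model,
    icm = {
      if (is.null(p)) abort("icm requires `p`")
      if (p < 0 || p > 1) abort("`p` must lie in [0, 1]")
      list(model = model, p = p)
    },
    threshold_normal = {
      if (is.null(mu) || is.null(sigma)) abort("threshold_normal requires `mu` and `sigma`")
      if (sigma <= 0) abort("`sigma` must be positive")
      list(model = model, mu = mu, sigma = sigma)
    },
    threshold_custom_cdf = {
      if (is.null(theta) || is.null(F)) abort("threshold_custom_cdf requires `theta` and `F`")
      if (length(theta) != length(F)) abort("`theta` and `F` must have equal length")
      o <- order(theta)
      theta <- theta[o]; F <- F[o]
      if (any(diff(F) < 0) || any(F < 0 | F > 1)) {
        abort("`F` must be nondecreasing with values in [0, 1]")
      }
      list(model = model, theta = theta, F = F)
    }
  )
  cfg$per_node <- per_node
  structure(cfg, class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  pars <- switch(x$model,
    icm = sprintf("p = %g", x$p),
    threshold_normal = sprintf("mu = %g, sigma = %g", x$mu, x$sigma),
    threshold_custom_cdf = sprintf("%d tabulated CDF points", length(x$theta))
  )
  cat(sprintf("<cascade_model> %s (%s)%s\n", x$model, pars,
              if (is.null(x$per_node)) "" else
                sprintf(", %d per-node override(s)", length(x$per_node))))
  invisible(x)
}

#' Read / write a model configuration (JSON)
#'
#' The on-disk form is a small JSON object, e.g. `{"model":"icm","p":0.2}` or
#' `{"model":"threshold_normal","mu":0.5,"sigma":0.5}`, with an optional
#' `"per_node"` object keyed by node id.
#'
#' @param path File path.
#' @param model A `cascade_model`.
#' @return `read_model_config()` returns a `cascade_model`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(cascade_model, c(
    list(model = x$model),
    x[setdiff(names(x), c("model", "per_node"))],
    if (!is.null(x$per_node)) list(per_node = lapply(x$per_node, as.list))
  ))
}

#' @rdname read_model_config
#' @export
write_model_config <- function(model, path) {
  jsonlite::write_json(unclass(model)[!vapply(unclass(model), is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# threshold CDF evaluator for a node's parameters
model_cdf <- function(pars) {
  if (pars$model == "threshold_normal") {
    function(x) pnorm(x, mean = pars$mu, sd = pars$sigma)
  } else {
    theta <- pars$theta; F <- pars$F
    function(x) c(0, F)[findInterval(x, theta) + 1L]
  }
}

node_params <- function(config, node) {
  base <- unclass(config)
  base$per_node <- NULL
  if (!is.null(node) && !is.null(config$per_node[[as.character(node)]])) {
    base <- modifyList(base, config$per_node[[as.character(node)]])
  }
  base
}

#' Construct a response function
#'
#' `response_function()` validates a raw `(R, Rc)` pair; `build_response()`
#' derives one from a model configuration for a node of given degree.
#'
#' For the independent cascade model with parameter `p`:
#' \eqn{R(a) = p(1-p)^a} for \eqn{0 \le a \le d}, \eqn{R(d+1) = (1-p)^{d+1}},
#' \eqn{R^c(a) = 1-(1-p)^{a+1}}. For threshold models with threshold CDF `F`:
#' \eqn{R(0) = F(0)}, \eqn{R(a) = F(a/d) - F((a-1)/d)},
#' \eqn{R(d+1) = 1 - F(1)}, \eqn{R^c(a) = F(a/d)}. A degree-0 node activates
#' iff its threshold is nonpositive: \eqn{R^c(0) = F(0)}.
#'
#' @param R Numeric vector of length `d + 2` over `a = 0..d+1`.
#' @param Rc Numeric vector of length `d + 1` over `a = 0..d`; if omitted, the
#'   cumulative sum of `R`.
#' @param degree Node degree `d >= 0`.
#' @param config A `cascade_model`.
#' @param node Optional node id (used for per-node overrides and error
#'   messages).
#' @return An object of class `response_function`: list with `degree`, `R`,
#'   `Rc`.
#' @export
#' @examples
#' build_response(cascade_model("icm", p = 0.2), degree = 2)
response_function <- function(R, Rc = NULL, degree = length(R) - 2L, node = NULL) {
  d <- as.integer(degree)
  if (d < 0 || length(R) != d + 2L) {
    abort(sprintf("R must have length degree + 2 = %d, got %d", d + 2L, length(R)))
  }
  if (is.null(Rc)) Rc <- cumsum(R[seq_len(d + 1L)])
  tol <- 1e-12
  who <- if (is.null(node)) "" else sprintf(" (node '%s')", node)
  if (any(R < -tol) || any(R > 1 + tol) || any(Rc < -tol) || any(Rc > 1 + tol)) {
    abort(sprintf("response values outside [0, 1]%s", who))
  }
  s <- sum(R)
  if (abs(s - 1) > 1e-12 * max(1, d + 2)) {
    abort(sprintf("response not normalized%s: sum(R) = %.17g", who, s))
  }
  if (max(abs(Rc - cumsum(R[seq_len(d + 1L)]))) > 1e-10) {
    abort(sprintf("Rc is not the cumulative sum of R%s", who))
  }
  structure(list(degree = d, R = pmin(pmax(R, 0), 1), Rc = pmin(pmax(Rc, 0), 1)),
            class = "response_function")
}

#' @rdname response_function
#' @export
build_response <- function(config, degree, node = NULL) {
  stopifnot(inherits(config, "cascade_model"), degree >= 0)
  d <- as.integer(degree)
  pars <- node_params(config, node)
  if (pars$model == "icm") {
    p <- pars$p
    q <- 1 - p
    R <- c(p * q^(0:d), q^(d + 1L))
    Rc <- 1 - q^((0:d) + 1L)
  } else {
    Fi <- model_cdf(pars)
    grid <- if (d == 0L) 0 else (0:d) / d
    Rc <- Fi(grid)
    R <- c(Rc[1], diff(Rc), 1 - Rc[d + 1L])
  }
  response_function(R, Rc, degree = d, node = node)
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("<response_function> degree %d; R(0) = %.4g, never = %.4g\n",
              x$degree, x$R[1], x$R[x$degree + 2L]))
  invisible(x)
}

#' @export
tidy.response_function <- function(x, ...) {
  d <- x$degree
  tibble(a = 0:(d + 1L), R = x$R, Rc = c(x$Rc, NA_real_))
}

#' Build response functions for every node of a network
#'
#' @param edges Edge tibble.
#' @param config A `cascade_model`.
#' @param nodes Optional full node set (isolated nodes get degree 0).
#' @return Named list of `response_function`, keyed by node id.
#' @export
build_responses <- function(edges, config, nodes = NULL) {
  ds <- degree_sequence(edges, nodes = edges_node_set(edges, nodes))
  stats::setNames(
    map2(ds$node, ds$degree, function(nd, dg) build_response(config, dg, node = nd)),
    ds$node
  )
}

# pmf of a Poisson-binomial: sum of independent Bernoulli(probs). Exact
# iterative convolution for short inputs; divide-and-conquer with the shared
# 1-D convolution backend (FFT for long supports) otherwise.
poisbinom_pmf <- function(probs) {
  np <- length(probs)
  if (np == 0L) return(1)
  if (np < 64L) {
    pmf <- 1
    for (p in probs) pmf <- conv1d(pmf, c(1 - p, p))
    return(pmf)
  }
  half <- np %/% 2L
  conv1d(poisbinom_pmf(probs[seq_len(half)]),
         poisbinom_pmf(probs[(half + 1L):np]))
}

#' Average a response function over ghost neighbors
#'
#' When an edge to a neighbor is deleted (spanning-tree construction), the
#' lost neighbor is replaced by an independent "ghost" copy that is initially
#' active with probability `p_ni` and still counts toward the node's
#' activation, but not toward the cascade size. The response function built
#' for the original degree `d` is averaged over the ghosts' joint states
#' (a Poisson-binomial number `S` of active ghosts) and re-indexed to the
#' reduced degree `d_M = d - m`:
#' \eqn{\tilde R^c(a) = E[R^c(a + S)]} for \eqn{0 \le a \le d_M},
#' \eqn{\tilde R(a) = E[R(a + S)]} for \eqn{1 \le a \le d_M},
#' \eqn{\tilde R(0) = \tilde R^c(0)} and
#' \eqn{\tilde R(d_M + 1) = 1 - \tilde R^c(d_M)}, which preserves
#' normalization and the cumulative-sum identity exactly.
#'
#' @param r A `response_function` built for the original degree.
#' @param ghost_probs Activation probabilities of the deleted neighbors
#'   (length `m`).
#' @return A `response_function` of degree `d - m`.
#' @export
ghost_update <- function(r, ghost_probs) {
  stopifnot(inherits(r, "response_function"))
  m <- length(ghost_probs)
  if (m == 0L) return(r)
  d <- r$degree
  dM <- d - m
  if (dM < 0L) abort(sprintf("more ghosts (%d) than the original degree (%d)", m, d))
  pmf <- poisbinom_pmf(ghost_probs)  # over s = 0..m
  ERc <- vapply(0:dM, function(a) sum(pmf * r$Rc[a + (0:m) + 1L]), numeric(1))
  Rt <- numeric(dM + 2L)
  Rt[1] <- ERc[1]
  if (dM >= 1L) {
    Rt[2:(dM + 1L)] <- vapply(1:dM, function(a) sum(pmf * r$R[a + (0:m) + 1L]), numeric(1))
  }
  Rt[dM + 2L] <- 1 - ERc[dM + 1L]
  response_function(Rt, ERc, degree = dM)
}
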
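# Subtree distribution propagation: one bottom-up sweep over a rooted tree.
# Every non-root node n sends its parent a pair of 2-D tables:
#   pI[t, s] -- joint mass of (subtree active count T_n = t, own state s_n = s)
#               given the parent never activates toward n,
#   pA[t, r] -- mass of (adjusted count, trigger indicator r_n) given an
#               active parent; r_n = 1 means n activated before its parent.
# Children tables are combined by 2-D convolution (counts add along t, the
# child indicators add along the second axis), the node's response function
# turns the combination into its own message, and the root closes the sweep
# with the final-size distribution.

# ---- convolution backend -------------------------------------------------

# 1-D linear convolution; direct sum-product for short outputs, FFT above.
# Negative FFT round-off is clipped (failure beyond `tol` is an error) and
# the result rescaled to the exact mass product.
conv1d <- function(x, y, fft_threshold = 256L, tol = 1e-12) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(numeric(0))
  nout <- nx + ny - 1L
  if (nout <= fft_threshold) {
    out <- numeric(nout)
    if (nx <= ny) {
      for (i in seq_len(nx)) {
        idx <- i:(i + ny - 1L)
        out[idx] <- out[idx] + x[i] * y
      }
    } else {
      for (i in seq_len(ny)) {
        idx <- i:(i + nx - 1L)
        out[idx] <- out[idx] + y[i] * x
      }
    }
    return(out)
  }
  out <- convolve(x, rev(y), type = "open")
  neg <- out < 0
  if (any(neg)) {
    worst <- min(out)
    if (worst < -tol) {
      abort(sprintf("FFT convolution produced negative mass %.3g beyond tolerance", worst))
    }
    out[neg] <- 0
  }
  target <- sum(x) * sum(y)
  s <- sum(out)
  if (s > 0 && target > 0) out <- out * (target / s)
  out
}

# full 2-D convolution of nonnegative tables: rows (t) and columns (a) add
conv2d <- function(A, B) {
  ca <- ncol(A); cb <- ncol(B)
  out <- matrix(0, nrow(A) + nrow(B) - 1L, ca + cb - 1L)
  for (j1 in seq_len(ca)) {
    colA <- A[, j1]
    if (!any(colA != 0)) next
    for (j2 in seq_len(cb)) {
      colB <- B[, j2]
      if (!any(colB != 0)) next
      jo <- j1 + j2 - 1L
      out[, jo] <- out[, jo] + c(conv1d(colA, colB),
                                 numeric(nrow(out) - nrow(A) - nrow(B) + 1L))
    }
  }
  out
}

# ---- grid-resolution helpers ---------------------------------------------

# Mean-preserving rebin of masses at positions (0:(n-1)) * step_from onto the
# lattice with spacing step_to: each mass splits between the two bracketing
# lattice points.
rebin_vec <- function(v, step_from, step_to) {
  n <- length(v)
  pos <- (0:(n - 1)) * step_from / step_to
  k <- floor(pos + 1e-12)
  frac <- pos - k
  nout <- max(k) + 2L
  out <- numeric(nout)
  lo <- k + 1L
  for (i in seq_len(n)) {
    out[lo[i]] <- out[lo[i]] + v[i] * (1 - frac[i])
    out[lo[i] + 1L] <- out[lo[i] + 1L] + v[i] * frac[i]
  }
  if (out[nout] == 0) out <- out[-nout]
  out
}

rebin_mat <- function(M, step_from, step_to) {
  cols <- lapply(seq_len(ncol(M)), function(j) rebin_vec(M[, j], step_from, step_to))
  nr <- max(lengths(cols))
  vapply(cols, function(v) c(v, numeric(nr - length(v))), numeric(nr))
}

# Adds the node's own contribution of one active unit: mass at lattice index
# k moves to position k*step + 1, split mean-preservingly when step > 1.
shift_mass <- function(v, step = 1) {
  if (step == 1) return(c(0, v))
  f <- 1 / step
  n <- length(v)
  out <- numeric(n + 1L)
  out[1:n] <- v * (1 - f)
  out[2:(n + 1L)] <- out[2:(n + 1L)] + v * f
  out
}

# ---- messages -------------------------------------------------------------

new_message <- function(pI, pA, step = 1) {
  list(pI = pI, pA = pA, step = step)
}

msg_check <- function(msg, node = NULL, tol = 1e-9) {
  who <- if (is.null(node)) "" else sprintf(" at node '%s'", node)
  if (abs(sum(msg$pI) - 1) > tol || abs(sum(msg$pA) - 1) > tol) {
    abort(sprintf("message normalization violated%s: sum(pI) = %.17g, sum(pA) = %.17g",
                  who, sum(msg$pI), sum(msg$pA)))
  }
  msg
}

#' Leaf message of subtree distribution propagation
#'
#' The base case of the upward sweep for a degree-1 node: `pA(0,0) = 1 -
#' Rc(1)`, `pA(1,0) = R(1)`, `pA(1,1) = R(0)`, `pI(0,0) = 1 - R(0)`,
#' `pI(1,1) = R(0)`, all other entries 0.
#'
#' @param r A `response_function` with degree 1.
#' @return A subtree message: list with matrices `pI`, `pA` (rows `t = 0,1`,
#'   columns state 0/1).
#' @export
leaf_message <- function(r) {
  stopifnot(inherits(r, "response_function"))
  if (r$degree != 1L) abort(sprintf("leaf message requires degree 1, got %d", r$degree))
  pA <- matrix(c(1 - r$Rc[2], r$R[2], 0, r$R[1]), 2, 2)
  pI <- matrix(c(1 - r$R[1], 0, 0, r$R[1]), 2, 2)
  msg_check(new_message(pI, pA))
}

#' Combine child messages by 2-D convolution
#'
#' Convolves the `pI` tables (and separately the `pA` tables) of a node's
#' children pairwise in increasing support order: subtree counts add along
#' `t`, the child state/trigger indicators add along the second axis. The
#' empty input yields the identity element (all mass at `(0, 0)`), which
#' also serves degenerate single-node trees.
#'
#' @param messages List of subtree messages.
#' @return A list with matrices `I`, `A` indexed by `(t, a)` and the lattice
#'   `step`.
#' @export
convolve_children <- function(messages) {
  if (length(messages) == 0L) {
    one <- matrix(1, 1, 1)
    return(list(I = one, A = one, step = 1))
  }
  steps <- vapply(messages, function(m) m$step, numeric(1))
  step <- max(steps)
  messages <- lapply(messages, function(m) {
    if (m$step < step) new_message(rebin_mat(m$pI, m$step, step),
                                   rebin_mat(m$pA, m$step, step), step)
    else m
  })
  ord <- order(vapply(messages, function(m) nrow(m$pI), integer(1)))
  messages <- messages[ord]
  I <- messages[[1]]$pI
  A <- messages[[1]]$pA
  for (m in messages[-1]) {
    I <- conv2d(I, m$pI)
    A <- conv2d(A, m$pA)
  }
  list(I = I, A = A, step = step)
}

# weights derived from the node's response function; `a` runs over the
# columns of the convolved-children tables
node_weights <- function(r, amax, root) {
  a <- 0:amax
  if (root) {
    if (r$degree != amax) {
      abort(sprintf("degree/response mismatch at root: degree %d vs %d children",
                    r$degree, amax))
    }
    list(i0 = 1 - r$Rc[a + 1L], a0 = r$Rc[a + 1L])
  } else {
    if (r$degree != amax + 1L) {
      abort(sprintf("degree/response mismatch: degree %d vs %d children + parent",
                    r$degree, amax + 1L))
    }
    list(i1 = 1 - r$Rc[a + 2L],   # 1 - Rc(a+1)
         r1 = r$R[a + 2L],        # R(a+1)
         rc = r$Rc[a + 1L],       # Rc(a)
         i0 = 1 - r$Rc[a + 1L])   # 1 - Rc(a)
  }
}

#' Internal-node message
#'
#' Applies the node's response function to the convolved child tables:
#' `pA(t,0) = sum_a I*(t,a)(1 - Rc(a+1)) + sum_a A*(t-1,a) R(a+1)`,
#' `pA(t,1) = sum_a A*(t-1,a) Rc(a)`, `pI(t,0) = sum_a I*(t,a)(1 - Rc(a))`,
#' `pI(t,1) = pA(t,1)`. With the identity convolution (zero children) this
#' reduces exactly to [leaf_message()].
#'
#' @param cc Convolved children, as returned by [convolve_children()], built
#'   from the `d - 1` children of a degree-`d` node.
#' @param r The node's `response_function` (degree `d`).
#' @param node Optional node id for error messages.
#' @return A subtree message; normalization is asserted (tolerance `1e-9`),
#'   not imposed.
#' @export
internal_message <- function(cc, r, node = NULL) {
  w <- node_weights(r, ncol(cc$I) - 1L, root = FALSE)
  iPart <- drop(cc$I %*% w$i1)
  aPart <- shift_mass(drop(cc$A %*% w$r1), cc$step)
  pA0 <- c(iPart, numeric(length(aPart) - length(iPart))) + aPart
  pA1 <- shift_mass(drop(cc$A %*% w$rc), cc$step)
  pI0 <- c(drop(cc$I %*% w$i0), 0)
  msg_check(new_message(cbind(pI0, pA1, deparse.level = 0),
                        cbind(pA0, pA1, deparse.level = 0),
                        cc$step),
            node = node)
}

#' Close the sweep at the root
#'
#' `P(T_r = t) = sum_a I*(t,a)(1 - Rc(a)) + sum_a A*(t-1,a) Rc(a)` over the
#' convolution of all `d_r` child messages.
#'
#' @param cc Convolved children over all root children.
#' @param r The root's `response_function`.
#' @param n_nodes Tree size `N` (defaults to the support found).
#' @param resolution Grid resolution label carried into the result.
#' @return A [cascade_distribution()].
#' @export
root_distribution <- function(cc, r, n_nodes = NULL, resolution = NULL) {
  w <- node_weights(r, ncol(cc$I) - 1L, root = TRUE)
  iPart <- drop(cc$I %*% w$i0)
  aPart <- shift_mass(drop(cc$A %*% w$a0), cc$step)
  p <- c(iPart, numeric(length(aPart) - length(iPart))) + aPart
  t_vals <- (seq_along(p) - 1) * cc$step
  if (is.null(n_nodes)) n_nodes <- round(max(t_vals))
  if (cc$step == 1 && length(p) < n_nodes + 1L) {
    p <- c(p, numeric(n_nodes + 1L - length(p)))
    t_vals <- 0:n_nodes
  }
  while (length(p) > 1L && p[length(p)] == 0 && t_vals[length(p)] > n_nodes) {
    p <- p[-length(p)]
    t_vals <- t_vals[-length(t_vals)]
  }
  cascade_distribution(p, t = t_vals, n_nodes = n_nodes,
                       method = "sdp", resolution = resolution)
}

#' Exact final-size distribution on a tree
#'
#' Runs subtree distribution propagation: a single postorder sweep computing
#' one message per non-root node and the final-size distribution at the
#' root. Exact on any tree, for any response functions. With `resolution =
#' C`, messages whose `t`-support exceeds `C + 1` points are re-binned onto
#' the equidistant grid `{0, N/C, ..., N}` by mean-preserving two-point
#' splitting, bounding work per node at the cost of an approximation (the
#' distribution mean is preserved); with `C >= N` the grid never engages and
#' the result is the exact one.
#'
#' @param edges Edge tibble describing a tree.
#' @param model A [cascade_model()]; ignored when `responses` is given.
#' @param root Root node id, or `NULL` for the automatic center choice (the
#'   root affects run time only, never the distribution).
#' @param resolution Optional integer grid resolution `C`.
#' @param responses Optional named list of `response_function`s keyed by node
#'   id (overrides `model`); must match node degrees.
#' @return A [cascade_distribution()] over `t = 0..N`.
#' @export
#' @examples
#' d <- run_sdp(gen_star(3), cascade_model("icm", p = 0.2))
#' tidy(d)
run_sdp <- function(edges, model = NULL, root = NULL, resolution = NULL,
                    responses = NULL) {
  net <- build_network(edges, nodes = edges_node_set(edges))
  if (is.null(responses)) {
    if (is.null(model)) abort("either `model` or `responses` must be supplied")
    responses <- stats::setNames(
      lapply(seq_len(net$n), function(i) build_response(model, net$deg[i],
                                                        node = net$nodes[i])),
      net$nodes)
  } else {
    missing <- setdiff(net$nodes, names(responses))
    if (length(missing) > 0) {
      abort(sprintf("no response function for node(s): %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    for (i in seq_len(net$n)) {
      if (responses[[net$nodes[i]]]$degree != net$deg[i]) {
        abort(sprintf("degree/response mismatch at node '%s': degree %d vs response %d",
                      net$nodes[i], net$deg[i], responses[[net$nodes[i]]]$degree))
      }
    }
  }
  run_sdp_net(net, responses, root = root, resolution = resolution)
}

run_sdp_net <- function(net, responses, root = NULL, resolution = NULL) {
  n <- net$n
  root_idx <- if (is.null(root)) NULL else {
    ri <- match(as.character(root), net$nodes)
    if (is.na(ri)) abort(sprintf("root '%s' is not a node of the tree", root))
    ri
  }
  rooted <- root_tree_int(net, root_idx)
  C <- resolution
  if (!is.null(C)) {
    C <- as.integer(C)
    stopifnot(C >= 1L)
  }
  h <- if (is.null(C)) Inf else n / C
  msgs <- vector("list", n)
  for (v in rooted$postorder) {
    if (v == rooted$root) next
    kids <- rooted$children[[v]]
    cc <- convolve_children(msgs[kids])
    if (length(kids) > 0) msgs[kids] <- list(NULL)  # free combined messages
    m <- internal_message(cc, responses[[net$nodes[v]]], node = net$nodes[v])
    if (!is.null(C) && m$step == 1 && nrow(m$pI) > C + 1L && h > 1) {
      m <- new_message(rebin_mat(m$pI, 1, h), rebin_mat(m$pA, 1, h), h)
    }
    msgs[[v]] <- m
  }
  cc <- convolve_children(msgs[rooted$children[[rooted$root]]])
  root_distribution(cc, responses[[net$nodes[rooted$root]]], n_nodes = n,
                    resolution = C)
}
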
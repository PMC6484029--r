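#' Cascade size distribution objects
#'
#' A `cascade_distribution` holds the probability of each final active count
#' `t` (equivalently the final fraction `rho = t / N`). Exact computations
#' live on the integer support `t = 0..N`; the grid-resolution mode of
#' [run_sdp()] produces a distribution on the equidistant grid
#' `{0, N/C, ..., N}`.
#'
#' @param prob Probability vector.
#' @param t Support values (defaults to `0..length(prob)-1`).
#' @param n_nodes Network size `N`.
#' @param method Short label of the producing algorithm.
#' @param resolution Grid resolution `C`, or `NULL` for exact support.
#' @return An object of class `cascade_distribution`.
#' @export
cascade_distribution <- function(prob, t = NULL, n_nodes, method = "unknown",
                                 resolution = NULL) {
  if (is.null(t)) t <- seq_along(prob) - 1
  stopifnot(length(t) == length(prob))
  if (any(prob < -1e-10)) abort("negative probability in distribution")
  prob <- pmax(prob, 0)
  s <- sum(prob)
  if (abs(s - 1) > 1e-9) {
    abort(sprintf("distribution not normalized: sum = %.17g", s))
  }
  structure(list(t = as.numeric(t), prob = as.numeric(prob),
                 n_nodes = as.integer(n_nodes), method = method,
                 resolution = resolution),
            class = "cascade_distribution")
}

#' @export
print.cascade_distribution <- function(x, ...) {
  cat(sprintf("<cascade_distribution> N = %d (%s%s)\n", x$n_nodes, x$method,
              if (is.null(x$resolution)) "" else sprintf(", grid C = %d", x$resolution)))
  cat(sprintf("  mean final size %.6g (rho = %.6g), P(t = 0) = %.6g\n",
              cascade_mean(x), cascade_mean(x) / x$n_nodes, x$prob[1]))
  invisible(x)
}

#' @describeIn cascade_distribution Tibble with columns `t`, `rho`,
#'   `probability`.
#' @param x A `cascade_distribution`.
#' @param ... Unused.
#' @export
tidy.cascade_distribution <- function(x, ...) {
  tibble(t = x$t, rho = x$t / x$n_nodes, probability = x$prob)
}

#' @describeIn cascade_distribution One-row summary: size, mean, mode count.
#' @export
glance.cascade_distribution <- function(x, ...) {
  tibble(n_nodes = x$n_nodes,
         mean_size = cascade_mean(x),
         mean_rho = cascade_mean(x) / x$n_nodes,
         n_modes = n_local_modes(x),
         method = x$method)
}

#' @describeIn cascade_distribution Probability mass against the final
#'   fraction `rho`.
#' @param object A `cascade_distribution`.
#' @export
autoplot.cascade_distribution <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$rho, y = .data$probability)) +
    geom_line() +
    geom_point(size = 0.6) +
    labs(x = expression(rho), y = "probability",
         title = sprintf("Final cascade size distribution (%s)", object$method))
}

#' Mean final cascade size
#'
#' @param x A `cascade_distribution`.
#' @return `sum(t * P(t))`, the expected number of finally active nodes.
#' @export
cascade_mean <- function(x) sum(x$t * x$prob)

#' Count local modes of a distribution
#'
#' A support point is a local mode when its probability exceeds both
#' neighbors' (boundaries compare one-sided) and clears `min_prob`.
#'
#' @param x A `cascade_distribution`.
#' @param min_prob Noise floor below which maxima are ignored.
#' @return Integer count of local maxima.
#' @export
n_local_modes <- function(x, min_prob = 1e-8) {
  p <- x$prob
  n <- length(p)
  if (n == 1L) return(1L)
  up <- c(TRUE, p[-1] > p[-n])
  down <- c(p[-n] > p[-1], TRUE)
  sum(up & down & p > min_prob)
}

#' Total variation distance between two distributions
#'
#' Supports are aligned by their `t` values; missing support points count as
#' zero mass.
#'
#' @param x,y `cascade_distribution` or `empirical_distribution` objects.
#' @return Total variation distance in `[0, 1]`.
#' @export
total_variation <- function(x, y) {
  px <- as_prob_tbl(x)
  py <- as_prob_tbl(y)
  m <- merge(px, py, by = "t", all = TRUE)
  m[is.na(m)] <- 0
  sum(abs(m$p.x - m$p.y)) / 2
}

as_prob_tbl <- function(x) {
  if (inherits(x, "cascade_distribution")) {
    data.frame(t = x$t, p = x$prob)
  } else if (inherits(x, "empirical_distribution")) {
    data.frame(t = x$t, p = x$counts / x$reps)
  } else if (is.numeric(x)) {
    data.frame(t = seq_along(x) - 1, p = x / sum(x))
  } else {
    abort("cannot interpret object as a distribution")
  }
}

#' Read / write the distribution TSV
#'
#' All distribution producers share one schema: a tab-separated table with
#' header `t  rho  probability`. Probabilities are printed with 17
#' significant digits so a write/read round trip is bit-stable.
#'
#' @param x A `cascade_distribution`.
#' @param path File path.
#' @return `read_distribution()` returns a `cascade_distribution`;
#'   `write_distribution()` returns `path` invisibly.
#' @export
write_distribution <- function(x, path) {
  stopifnot(inherits(x, "cascade_distribution"))
  lines <- c("t\trho\tprobability",
             sprintf("%.17g\t%.17g\t%.17g", x$t, x$t / x$n_nodes, x$prob))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distribution
#' @param n_nodes Network size; recovered from the last support point when
#'   omitted (the full support `0..N` is always written).
#' @param method Label for the loaded distribution.
#' @export
read_distribution <- function(path, n_nodes = NULL, method = "file") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_nodes)) n_nodes <- round(max(d$t))
  cascade_distribution(d$probability, t = d$t, n_nodes = n_nodes, method = method)
}
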
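# Shared fixtures: tiny networks and model shortcuts, built in code.

icm <- function(p = 0.2) cascade_model("icm", p = p)
tmod <- function(mu = 0.5, sigma = 0.5) cascade_model("threshold_normal", mu = mu, sigma = sigma)

tri_edges <- function() tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"))

cycle_edges <- function(n) {
  ids <- as.character(seq_len(n))
  tibble::tibble(from = ids, to = c(ids[-1], ids[1]))
}

# a random model with moderate parameters, deterministic in `i`
random_model <- function(i) {
  if (i %% 2L == 0L) {
    cascade_model("icm", p = 0.05 + 0.55 * ((i * 37) %% 100) / 100)
  } else {
    cascade_model("threshold_normal",
                  mu = 0.2 + 0.6 * ((i * 13) %% 100) / 100,
                  sigma = 0.2 + 0.6 * ((i * 29) %% 100) / 100)
  }
}

# exact per-node activation probabilities by exhaustive enumeration
enum_marginals <- function(edges, model, nodes = NULL) {
  bf <- brute_force_distribution(edges, model)
  attr(bf, "marginals")
}
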
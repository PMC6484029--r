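---
title: "Final-size distributions of network cascades: models, algorithms, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Final-size distributions of network cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadedist)
```

## The cascade framework

A cascade spreads a binary state (active/failed/infected) over a fixed
undirected network $G = (V, E)$ with $N$ nodes. The dynamics are monotone:
once active, a node stays active. Everything a model needs to say about a
node $i$ of degree $d_i$ is captured by its *response function*:

* $R_i(a)$ — the probability that $i$ activates exactly when $a$ of its
  neighbors are active, while $a - 1$ would not have been enough
  ($a = 0$ means $i$ seeds the cascade, $a = d_i + 1$ collects the mass of
  never activating), and
* $R_i^c(a) = \sum_{l \le a} R_i(l)$ — the probability that $i$ is active
  whenever $a$ neighbors are, with the normalization
  $\sum_{a=0}^{d_i+1} R_i(a) = 1$.

Two standard models are built in:

* **Threshold contagion (TM).** Node $i$ draws a fractional threshold
  $\theta_i \sim F_i$ once and activates when the active fraction of its
  neighborhood reaches it: $R_i^c(a) = F_i(a / d_i)$; negative thresholds
  seed. The default is a Normal CDF, pluggable to any tabulated CDF
  (evaluated as a right-continuous step function). For an isolated node the
  fraction $a/d$ is undefined; we define $R^c(0) = F(0)$ (the $a = 0$ value
  for every degree), so a degree-0 node activates iff $\theta \le 0$.
* **Independent cascade model (ICM).** Seeding and transmission both happen
  with probability $p$: $R_i(a) = p(1-p)^a$, $R_i(d_i+1) = (1-p)^{d_i+1}$,
  $R_i^c(a) = 1-(1-p)^{a+1}$. Its final outcome coincides with bond
  percolation at density $p$, which gives an independent sampler to test
  against.

The package is restricted to monotone cumulative responses ($R^c$
nondecreasing); non-monotone responses (e.g. opinion models where additional
active neighbors inhibit adoption) are out of scope.

The summary object of interest is the full distribution of the final
cascade size, $p_\rho(t/N) = \mathbb{P}(T = t)$ — not just its mean. On
heterogeneous networks this distribution is often strongly multi-modal (one
mode per hub that may or may not fire), so the mean alone is a poor risk
summary. `run_sdp(gen_star(11), cascade_model("threshold_normal", mu = 0.5,
sigma = 0.5))` is bimodal already.

## Exact tree sweep (subtree distribution propagation)

On a tree rooted at $r$, each node $n$ sends one message to its parent: a
pair of 2-D tables over (subtree active count, a binary state),

* $p_{I_n}(t, s)$ — the joint mass of $T_n = t$ and $s_n = s$ given the
  parent never activates toward $n$, and
* $p_{A_n}(t, r_n)$ — given an active parent, with the artificial trigger
  indicator $r_n = 1$ meaning "$n$ activated before its parent and counts
  toward the parent's activation".

Children are independent conditional on the connecting node, so their
tables combine by 2-D convolution — subtree counts add along $t$, the child
indicators add along the second axis — after which the node's response
function produces its own message (the `internal_message()` equations). At
the root all $d_r$ children are convolved and the sweep closes with the
final-size distribution. One bottom-up pass computes the exact
distribution; correctness is checked in the test suite against an
independent brute-force oracle (exhaustive enumeration of integer-threshold
assignments) on hundreds of random trees, and against Monte Carlo.

Numerical choices:

* Children are combined pairwise in increasing support order; the order
  affects speed only (result invariance is tested to $10^{-12}$).
* 1-D convolutions switch from the direct sum-product to FFT once the
  output support exceeds 256 points. FFT round-off can produce tiny
  negative masses: anything below $-10^{-12}$ aborts, smaller glitches are
  clipped to zero and the mass rescaled to the exact product of input
  masses.
* Message normalization is asserted (tolerance $10^{-9}$), never silently
  imposed.
* The default root is a tree center (midpoint of a diameter path, ties to
  the first node in input order). Placing the root centrally keeps
  subtrees balanced and convolutions small; any explicit root gives the
  identical distribution.

### Grid resolution

The exact sweep costs $O(\sum_n d_n |T_n| \log |T_n|)$. When only a fixed
resolution of $\rho$ is needed, `resolution = C` re-bins any message whose
$t$-support exceeds $C + 1$ points onto the equidistant lattice
$\{0, N/C, \dots, N\}$, splitting each mass between the two bracketing
lattice points so the mean is preserved exactly. Convolutions then operate
on at most $O(C)$ points per node. Two properties follow by construction
and are tested: with $C \ge N$ the lattice never engages and the output is
bit-identical to the exact sweep, and the distribution mean is preserved to
$10^{-9}$ regardless of $C$. The cost is local smearing of the
distribution, and the support can overshoot $N$ by a few lattice steps
(each re-binned child rounds its support up to the next lattice point);
the overshoot mass is part of the approximation and is reported as-is
rather than clamped, which would bias the mean. Grid mode is therefore
labelled approximate and off by default.

The test suite exercises the sweep at $N = 5{,}000$ (full resolution) and
$N = 50{,}000$ ($C = 256$); both complete in well under a minute on one
core.

## Loopy networks: belief propagation + spanning tree + ghosts

On a network with cycles the tree sweep does not apply directly. The
approximation pipeline (`run_tda()`) has four steps:

1. **Belief propagation.** For every directed edge, $p_{ij} =
   \mathbb{P}(s_i = 1 \,\|\, s_j = 0)$ — the probability that $i$ activates
   with $j$'s influence removed — satisfies a fixed-point system in which
   the neighbors of $i$ (minus $j$) activate independently. The sum over
   neighbor states is computed exactly as $\mathbb{E}[R_i^c(S)]$ with $S$
   Poisson-binomial, by convolving Bernoulli masses (divide-and-conquer
   with the FFT backend for high degrees). We initialize $p_{ij} = R_i(0)$
   and run a fixed 50 synchronous (Jacobi) sweeps — on all test systems the
   updates contract quickly; the largest final-sweep update is reported so
   a caller can detect non-convergence, which is deliberately not fatal. An
   in-place (asynchronous) schedule is available behind a flag; on trees
   both reach the same fixed point, which is provably exact once the sweep
   count exceeds the diameter (tested against enumeration).
2. **Spanning forest.** A minimum spanning forest with i.i.d. uniform
   random edge weights (seeded, hence reproducible) removes one edge per
   independent cycle. Weighting by endpoint degree sums is available to
   prefer cutting hub–hub edges. Each node records its deleted neighbors.
3. **Ghost update.** A deleted neighbor $n$ of node $i$ is replaced by an
   independent *ghost* that is initially active with probability $p_{ni}$
   from step 1. Ghosts influence $i$'s response but are not counted in the
   cascade size. Averaging over the Poisson-binomial count $S$ of active
   ghosts gives the reduced-degree response
   $\tilde R_i^c(a) = \mathbb{E}[R_i^c(a + S)]$, $\tilde R_i(a) =
   \mathbb{E}[R_i(a + S)]$ for $a \ge 1$, and — the one place where a
   design decision was genuinely open — the seeding entry
   $\tilde R_i(0) = \mathbb{E}[R_i^c(S)]$. Under the integer-threshold
   semantics a node with threshold $k$ starts the tree cascade active iff
   $k \le S$, which has probability $R_i^c(S)$; taking
   $\mathbb{E}[R_i(S)]$ instead would undercount ghost-triggered seeding
   and break $\sum_a \tilde R_i(a) = 1$. The adopted form preserves
   normalization and the cumulative-sum identity exactly (tested), and
   commutes with adding inert ghosts.
4. **Tree sweep per component.** The exact sweep runs on each forest
   component with the updated responses; component sizes are independent,
   so the per-component distributions are convolved into the final
   distribution over $t = 0..N$. (Disconnected inputs are thus handled for
   free; a `largest_component()` helper is available when analysis should
   be restricted to one component, as is common for real networks.)

On a tree, steps 2–3 degenerate (nothing is deleted) and the pipeline is
bit-identical to `run_sdp()` — the reduction is asserted byte-for-byte in
the tests. On loopy graphs the result is an approximation whose quality
improves with local tree-likeness. The stress test in the suite uses a
power-law configuration model ($N = 200$, exponent $2.5$, degrees in
$[1, 25]$) — small enough to retain short loops, which makes the task
harder — and finds a total-variation distance to a $10^5$-replicate Monte
Carlo reference around $10^{-2}$ for both models, two orders of magnitude
better than summarizing the same reference by a point mass at its mean. On
deliberately loop-dense graphs the bias is visible: on the triangle with
ICM $p = 0.2$ the ghost-averaged seeding inflates $P(T>0)$ and the
total-variation distance to the 64-case enumeration is about $0.07$. That
is the price of treating ghosts as independent; small dense motifs are the
worst case for the method, and the junction-tree style generalization that
would fix them is out of scope.

## Ground truth machinery

Three independent routes validate the message-passing code:

* **Exhaustive enumeration** (`brute_force_distribution()`): every node's
  response is equivalent to drawing an integer threshold $k_i$ with
  $\mathbb{P}(k_i = a) = R_i(a)$; enumerating all assignments with their
  product probabilities and running each cascade to its fixed point gives
  the exact distribution (and exact node marginals) on any graph, at cost
  $\prod_i (d_i + 2)$, guarded by a configurable limit.
* **Monte Carlo** (`monte_carlo_distribution()`): the same coupling,
  sampled. The simulation is vectorized across replicates (sparse
  adjacency multiply per synchronous step; the fixed point is reached in at
  most $N$ steps by monotonicity and is schedule-independent for monotone
  responses, so the synchronous choice is innocuous).
* **Bond percolation** (`icm_bond_percolation_mc()`): for the ICM only,
  seeds and occupied edges at density $p$, final set = reachable from
  seeds. Agreement of all three within binomial sampling error is an
  acceptance-level test.

## Synthetic generators and what they do (not) emulate

`gen_star()`, `gen_path()`, `gen_uniform_tree()` (uniform labeled trees via
the Prüfer construction), `gen_hub_tree()` (a path of hubs with pendant
leaves — a minimal model of the hub-dominated trees where multi-modality is
starkest; when more nodes are requested than the hub degrees imply, the
extras are attached as chains below leaves, round-robin, preserving hub
degrees), and `gen_power_law_config()` (i.i.d. degrees from a truncated
power law $p(d) \propto d^{-\gamma}$, parity fixed by resampling one
degree, uniform stub matching, then self-loops dropped and multi-edges
collapsed, with the distortion reported). Defaults used throughout the
tests are the study conditions: TM with $\mu = \sigma = 0.5$, ICM with
$p = 0.2$ — a deliberately uncritical regime away from phase transitions —
50 BP sweeps, and degree exponent $2.5$ with $d_{\max} = 25$.

These generators produce graphs without degree–degree correlations,
clustering beyond what finite size induces, or community structure. Passing
tests on them show the algorithms are correct (trees) and accurate on
locally tree-like topologies; they do not certify accuracy on highly
clustered real networks, where the spanning tree deletes many edges and the
independence assumption on ghosts bites harder. Real networks can be loaded
through the same `read_edge_list()` path.

## Known limitations

* No node recovery (no SIR third state) and no time-resolved trajectories —
  only final sizes.
* Non-monotone response functions are rejected by construction.
* Grid mode's support overshoot (above) and its smearing are uncorrected.
* BP uses a fixed sweep count, not a convergence criterion; pathological
  fixed-point cycles would only be visible through the reported final
  delta.
* The spanning forest is randomized; different `mst_seed`s give (slightly)
  different approximations on loopy graphs. This sensitivity is reported,
  not averaged away.
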
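---
title: "Methods: maximum-entropy replicas of collective ant foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy replicas of collective ant foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the questions

`hexforage` analyses collective foraging of ant colonies (*Aphaenogaster
senilis* scale) on a hexagonal channel arena: a Teflon plate in which 5 cm
channels form a honeycomb whose vertices are ternary "Y-maze" decision
nodes. A colony of roughly 750 workers connects to the arena through a
nest orifice at the bottom centre, forages for 12 food items placed on the
vertices of two hexagon faces, and is filmed for 3 hours at 2 Hz. The
full 2 m × 2 m plate tiles into 572 hexagons; each colony explores a
2 m × 1 m half with 286 hexagons.

Three questions organise the package. How is foraging structured in time
(the exploration / exploitation / relaxation phases bounded by the first
item discovered, TP1, and the last item collected, TP2)? How is it
structured in space (pairwise mutual information between the binary
occupancies of nodes)? And what functional consequences does that spatial
correlation structure have — measured by training pairwise maximum-entropy
("inverse Ising") *replicas* of a colony and running in-silico
food-detection experiments on them?

# The occupancy representation

Every node $i$ carries a binary variable $I_i(t) \in \{0,1\}$: occupied by
at least one ant at frame $t$ or not. A trial is the matrix of all
$I_i(t)$, and its spin representation is $\sigma_i = 2I_i - 1$. With
$N = 620$ active nodes in the half arena the state space holds
$2^{620} \approx 10^{186}$ configurations, which rules out any exact
treatment of the joint distribution and motivates both the pairwise MI
summary and the pairwise model.

# Mutual information

`pairwise_mi()` uses the plug-in estimator: empirical 2×2 joint
frequencies per node pair over a frame window, with $0 \log 0 = 0$.
Estimates are reported in bits (a `base` switch gives nats); the log base
is a reporting convention that rescales every figure identically.
`average_mi()` averages over the $N(N-1)/2$ unordered pairs — reading the
sum over $i \neq j$ with the $2/(N(N-1))$ prefactor as the mean pairwise
MI; the ordered-pair reading would merely double every value. No bias
correction is applied by default: the plug-in bias is common to every
window of equal length, so it shifts, but does not reshape, the windowed
series. Windowed averages default to a 15-minute window moved in
2.5-minute steps; both are configurable because reasonable window choices
between 15 and 20 minutes trade noise against temporal resolution.

Lag times relate MI turning points to the transition points: the series is
smoothed by a 3-point moving mean, the fall onset is the global maximum
after TP1, the rise onset is the minimum between the start and that
maximum, and `T1`/`T2` are the signed offsets of those onsets from
TP1/TP2 (negative = anticipatory). The onset rule is a package decision —
any rule needs a convention for noisy series, and extremum-based onsets
are reproducible and parameter-free beyond the smoothing width.

# The synthetic colony generator

No deposited tracking data ships with the package, so `simulate_trial()`
and `simulate_series()` generate trials whose *population-level* structure
matches the experimental description: three phases with a 5–10-fold
activity rise after TP1, group recruitment of 3–5 nestmates per collected
item, relaxation to 5–10 resident ants with departure bursts, trail
memory that persists across trials in the deterministic condition and is
erased (cleaning) in the stochastic one, and positive spatial occupancy
correlations concentrated along nest-to-food paths.

The micro-rules are a minimal stand-in, not a claim about real ants:

* **Movement.** One channel per 4 frames (2 s per 5 cm, ~2.5 cm/s).
  At each node the next channel is drawn by a softmax over three
  log-weights: persistence (0.6) for not reversing, the candidate node's
  trail score (weight 1, capped at 8 for numerical stability), and a
  thigmotaxis bonus (0.6) for boundary nodes.
* **Emission.** Scouts leave the nest at 0.0075 s⁻¹; a steady-state
  cohort is released when the nest opens so exploration starts at its
  stationary level. Group *waves* — a leader with 2–4 followers stepping
  into the node their predecessor just left — depart at 1/230 s⁻¹ and are
  the dominant collective movement mode; the follower train is what
  produces same-frame co-occupancy of nearby nodes away from trails, the
  correlation structure on which the replica analysis depends.
* **Food.** A scout stepping on a food node notices the item with
  probability 0.05 per visit (the item is a small prey piece in a 7 mm
  channel); it spends 300 s handling it, returns by the shortest path
  reinforcing the trail, and on arrival 3–5 recruits are dispatched
  towards nodes that still hold items. After TP1 both solo and wave
  emissions are multiplied by 7, chosen so the arena population rises
  5–10-fold between the exploration mean and the exploitation peak.
* **Memory.** The trail is a per-node scalar, +1 per food-carrying
  traversal, decaying at 1/7200 s⁻¹; deterministic series carry half of
  it to the next trial. A fraction 0.3 of scouts in later deterministic
  trials are *experienced foragers* that head straight back to remembered
  food nodes (site fidelity) — the individual-level mechanism behind
  colony preconditioning, visible as a non-increasing median TP1 across
  trials.
* **Relaxation.** After the last item is collected, emission falls to the
  level that sustains 5–10 residents net of Poisson departure bursts
  (rate 1/900 s⁻¹, 4 ants).

What the generator does **not** emulate: individual heterogeneity beyond
the scout/recruit/follower roles, pheromone chemistry, load transport
dynamics, or the fine statistics of real trajectories. Tests that pass on
generator data therefore validate the *pipeline* under data with the
stated population-level structure, not conclusions about real colonies.

# The pairwise maximum-entropy replica

`fit_replica()` fits
$$P(\mathbf I) = \frac{1}{Z}\exp\Big[\beta\Big(\sum_i h_i \sigma_i +
\sum_{i<j} J_{ij}\sigma_i\sigma_j\Big)\Big]$$
with symmetric couplings and zero diagonal; the pair sum is over unordered
pairs (the ordered reading only rescales $J$ by 2). Training always runs
at $\beta = 1$; $\beta$ is kept as a post-fit occupancy knob because
scaling $(h, J)$ by $c$ and $\beta$ by $1/c$ leaves the distribution
invariant.

**Estimator.** Exact likelihood is intractable at $N$ in the hundreds, so
couplings are estimated by node-wise logistic pseudolikelihood with an L2
penalty (`lambda` = 0.01 per-sample scale) and symmetrised by averaging
the two directed estimates. Conditionals are smoothed by appending one
all-occupied and one all-empty pseudo-frame, which keeps fields finite
for never-occupied nodes (and gives the closed-form null model its
Laplace-smoothed means). The null ("independent") model forces
$J \equiv 0$ and solves $\langle\sigma_i\rangle = \tanh(\beta h_i)$
directly.

**Coupling support.** For colony data the pipeline restricts couplings to
node pairs within two channels of each other (`adjacency_pairs()`).
This is a deliberate design choice: at desk-scale training sizes
(a few thousand frames), an unrestricted fit converts common-mode
activity fluctuations into a dense carpet of small positive couplings
whose row sums dominate the dynamics — the sampled model then fails to
reproduce the very occupancies it was trained on. The spatial
correlations of this system are local (trains and trails), and the
lattice-neighbourhood support recovers them while keeping the inverse
problem well-conditioned; with it, sampled node occupancies correlate
with the data at $r > 0.98$. The unrestricted fit remains available
(`pairs = NULL`) and is what the parameter-recovery tests exercise on
data actually generated by a pairwise model.

`recalibrate_fields()` additionally pins equilibrium node means to the
data by stochastic approximation with a persistent Glauber chain. It is
exported for fit diagnostics; the efficiency pipeline does not apply it,
because the comparison design (below) equalises *overall* occupancy via
$\beta$ rather than per-node marginals.

**Sampling.** `sample_replica()` implements single-site heat-bath
(Glauber) dynamics in compiled code: one sweep updates all $N$ sites once
in fresh random order; local fields are cached and updated incrementally
on flips. Randomness comes from R's RNG, so a seed fully determines the
output. Glauber is used rather than Metropolis because the efficiency
experiments interpret Monte Carlo time directly.

**Validation.** `exact_distribution()` enumerates models up to
$N \le 20$ and is the oracle for the sampler (all first and second
moments within Monte Carlo error) and for the inference tests
(parameter recovery $r \ge 0.9$ for fields, $\ge 0.8$ for couplings at
$2\times10^4$ samples). `goodness_of_fit()` compares per-node means and
per-pair connected correlations between data and model samples.
`pairwise_fraction()` quantifies how much of a small node subset's total
multi-information survives in the best pairwise model (iterative
proportional fitting on the enumerated joint, ≤ 200 iterations,
tolerance 1e-8): exactly 1 for any 2-node subset, exactly 0 for pure
parity, and typically high for occupancy data.

# In-silico efficiency experiments

`detection_time()` starts a replica from the all-empty state and counts
Glauber sweeps until every food node has been occupied at least once
(the all-nodes metric; a first-node variant is a switch). The empty-state
start matches the task's framing as a 0→1 first-passage problem; time is
left in sweeps because nothing in the training maps Monte Carlo time to
seconds. Runs are censored at `max_sweeps` (default 10⁴) and censoring is
handled explicitly: survival curves place censored mass above the cap,
and the nearest-rank 90th percentile refuses to answer if the rank falls
among censored realisations.

`scenario_suite()` compares four replicas — trained on the deterministic
or stochastic condition, each with a full and a $J = 0$ null variant —
under the trained conditions, under a `p`-mixture of deterministic and
random placements, and under radially constrained random placements.
Food draws and dynamics seeds are shared across models within a scenario,
so comparisons are paired; orderings carry bootstrap confidence
intervals. Before comparison the null replicas' $\beta$ is calibrated by
bisection so their overall occupancy matches the corresponding full
replica's (the full replicas stay at $\beta = 1$); this is the
occupancy-fairness control, and with our fits the calibrated values land
close to 1 on either side.

At the package's study scale the suites reproduce the comparative
findings they are designed to probe: the deterministic-trained replica is
far faster under its own food condition than the stochastic-trained one
under its; its advantage collapses by an order of magnitude as the
placement probability `p` falls from 1 to 0, while the stochastic
replica's percentile moves by only a small factor; and under fully random
food the stochastic replica *without* correlations decays more slowly
than its full counterpart. One scaling caveat: with three training trials
per condition, the stochastic replica's coverage of remote arena corners
is thinner than in multi-week experimental data sets, so its response to
`p` is a small increase rather than strictly no change; the assertion is
therefore comparative (its degradation factor is a fraction of the
deterministic replica's).

# Problem sizes, numerical choices, degenerate inputs

* Study scale: the 2000 × 1000 mm half arena (642 constructed nodes),
  3 trials per condition, exploitation-phase training pools subsampled to
  2500 frames; efficiency suites use 200 realisations per cell with a
  2×10⁴-sweep cap. These sizes are stated here as the package's chosen
  study conditions for tests and examples.
* Smaller honeycombs (500 × 400 mm) serve geometry and estimator tests;
  the tiling convention (pointy-top, half-width row offset, equal-length
  rows, maximal whole-hexagon fit) reproduces the 572/286 face counts of
  the experimental plates exactly. Published node tallies for those
  plates (1192/1240 full, 596/620 half) are stored as dataset constants
  for ingesting external data rather than asserted against the
  constructed lattice: the constructed full plate does carry 1240 nodes
  in total, but with a different interior/peripheral split (1142/98
  versus the published 1192/48), and the half-arena tallies are not
  reproduced by a clean honeycomb cut at all. Geometry is therefore
  validated by the Euler relation and the degree structure instead.
  The number of active occupancy variables
  is always taken from the data at hand.
* Node ids are 1-based integers (R indexing); serialised artifacts carry
  the ids verbatim.
* MI windows need at least 2 frames; constant columns have zero entropy
  and contribute zero MI. Empty track tables binarise to all-zero
  matrices. Zero-emission configurations are legal but warn.
* Bisection for `calibrate_beta()` assumes occupancy decreases in
  $\beta$ over the bracket (guaranteed well away from phase-transition
  regimes of strongly coupled models) and stops within an occupancy
  tolerance of 0.005.
* All stochastic entry points take explicit integer seeds and restore the
  caller's RNG state on exit; identical seeds give bit-identical results,
  including through the compiled samplers.

# Known limitations

The generator's micro-rules are calibrated to population-level facts
only; its correlation structure, while qualitatively right (local,
positive, trail-concentrated), is weaker than real colonies'. Pairwise
replicas ignore triplet and higher-order structure by construction.
Pseudolikelihood with local support is a pragmatic estimator choice, not
an equivalence claim with exact maximum likelihood. Detection times are
Monte Carlo sweeps, not seconds, so only orderings and shapes — not
physical durations — are interpretable.
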
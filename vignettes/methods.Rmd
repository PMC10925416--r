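---
title: "Methods: differential affinities, tensor components, and weighted-SBM communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential affinities, tensor components, and weighted-SBM communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The inference problem

Input: activity traces for $n$ neurons over $T$ samples in each of $W$
animals, on a shared neuron namespace and a shared time axis (stimulus
protocols give the axes a common meaning across animals). Output: a set of
*components*, each naming a time interval, a set of animals, and a weighted
network over neurons, together with a community partition of that network —
a transient functional circuit.

The pipeline deliberately separates non-linear similarity computation
(stage 1) from multi-linear summarization (stage 2): affinities are
computed per pair and per time point first, so the tensor factorization
never has to linearize the comparison between raw traces.

## Stage 1 — local differential affinity

**Model.** Traces are Gaussian-smoothed (bandwidth $\sigma$, reflective
boundaries) and differentiated by central differences, giving $d_i(t)$ in
activity units per second. Maximal runs where $|d_i|$ exceeds a zero band
with constant sign, lasting at least `minDuration`, are *monotone
segments*. For $t$ inside a monotone segment of both $i$ and $j$,

$$a_{ij}(t) = \frac{\min(|d_i|,|d_j|)}{\max(|d_i|,|d_j|)}
  \left(1 - e^{-\max(|d_i|,|d_j|)/\kappa}\right),$$

otherwise $a_{ij}(t) = 0$. The ratio term measures agreement of the rates
of change; the gate suppresses coincidences of near-zero derivatives.
Absolute values make the measure sign-blind, so inhibitory (anti-correlated)
partners are linked as strongly as excitatory ones. The functional form
lives in one function (`differentialAffinity`) so an alternative kernel can
be swapped without touching the rest of the pipeline.

**Assumptions.** (i) Interacting neurons change activity *simultaneously* —
we require segment overlap at exactly the same samples, with no lag
tolerance. (ii) Circuit activity is temporally sparse: most samples of most
neurons carry only noise-level change.

**Parameters.**

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma` | 4 samples (`4*dt`) | s | suppress sample-scale noise before differencing |
| `zeroBand` | 75th percentile of $|d|$, per animal | activity/s | a *noise-scale* band under assumption (ii); derivatives inside it carry no evidence of monotone change |
| `minDuration` | 3 samples | s | a monotone run shorter than this is indistinguishable from smoothed noise |
| `kappa` | 90th percentile of $|d|$ | activity/s | only clearly supra-noise derivative coincidences pass the gate at full strength |

The quantile choices matter. An early variant used the 5th percentile for
the zero band and the median for $\kappa$; with Gaussian-smoothed
observation noise, constant-sign derivative runs of length $\sim\sigma$ are
common, so almost nothing was excluded and unrelated neuron pairs acquired
a substantial affinity floor that propagated into every later stage. The
75th/90th percentiles estimate the noise scale itself (valid when activity
is sparse in time); on data where most neurons are active most of the time
they would over-prune, and should be set explicitly from a quiescent
recording period. All four parameters are recorded in the result object and
in the pipeline's resolved configuration.

Missing neurons are carried as a mask (`observedPairs`), never as zeros: a
zero is a measured absence of co-variation, a masked entry is no
measurement. The tensor stage excludes masked entries from its objective
and imputes them, which is also how affinity matrices with missing neurons
get "completed".

## Stage 2 — non-negative CP decomposition by HALS

Each $A^{(t)}$ is vectorized to its $n(n-1)/2$ upper triangle
(row-lexicographic over $i<j$, 1-based; `pairIndex` is the bijection) and
stacked into a $T \times W \times P$ tensor. The rank-$R$ CP model
$\tilde{T} = \sum_r \lambda_r\, f_t^{(r)} \circ f_w^{(r)} \circ f_a^{(r)}$
minimizes $\frac12\|T-\tilde{T}\|^2$ over non-negative factors,
by hierarchical alternating least squares: cyclic closed-form updates of
one factor column at a time, clipped at zero, using matricized
tensor-times-Khatri-Rao products.

Numerical choices:

* **Initialization**: factors i.i.d. uniform, scaled so the initial
  reconstruction matches the observed mean; HALS is initialization-
  sensitive, so `nRestarts = 10` seeded restarts are run and the best
  objective kept. Fits are deterministic given the seed.
* **Missing data**: EM-style — masked cells are imputed with the current
  reconstruction at the top of each outer iteration. The imputed objective
  majorizes the observed-entry objective, so the reported history is
  non-increasing; masked cells provably never influence the fit (tested by
  perturbing them).
* **Convergence**: relative objective change below `tol = 1e-7`, cap
  `maxIter = 500`.
* **Canonical form**: CP models are scale/permutation-indeterminate; we
  normalize every factor column to unit Euclidean norm, fold the scale into
  $\lambda_r$, and sort components by decreasing $\lambda_r$. A dead column
  (zero Gram diagonal) is set to zero rather than dividing by it.
* **Degenerate inputs**: an all-zero tensor returns the exact zero model
  with objective 0; a rank exceeding a tensor dimension warns and proceeds.

Rank selection is diagnostic, not automatic: `selectRank` reports, per
candidate rank, the best objective over restarts and a stability score (the
mean pairwise factor congruence between restarts, where congruence matches
components by the permutation maximizing mean absolute cosine across the
three modes). Overfit ranks split components inconsistently across restarts
and score low.

## Stage 3 — weighted SBM with description-length MCMC

Each affinity factor, rescaled to peak weight 1 and reshaped by
`factorToMatrix`, defines a weighted graph (entries below `wMin` dropped;
default 0 — sparsification is an explicit user choice). The generative
model, for a partition $c$ with $B$ occupied blocks:

* **Adjacency**: per block pair $(r,s)$, edges are Bernoulli with the
  density integrated out under a flat conjugate prior, giving the
  microcanonical count $\ln(N_{rs}+1) + \ln\binom{N_{rs}}{e_{rs}}$. A
  maximum-likelihood plug-in without this parameter cost would drive the
  optimum to all-singleton partitions.
* **Weights**: edge weights lie in $(0,1]$ and are modeled per block pair
  as $\mathrm{Beta}(\theta_{rs}, 1)$ — equivalently $-\ln w \sim
  \mathrm{Exponential}(\theta_{rs})$ — with $\theta_{rs}$ integrated out
  under a Gamma(1,1) prior: $(e_{rs}+1)\ln(1+s_{rs}) -
  \ln\Gamma(e_{rs}+1)$ with $s_{rs} = \sum -\ln w$. This family matches
  the bounded support and separates weight groups far better than an
  exponential on $w$ itself (for group means 0.7 vs 0.3, the per-edge KL
  divergence is about 0.87 vs 0.28 nats); with the plain exponential, the
  description length preferred fused blocks on benchmark instances whose
  planted structure is otherwise easy. A quantized-categorical model would
  be more flexible still, at a higher per-block-pair prior cost.
* **Partition prior**: three nested uniforms — over the number of groups
  $1..n$, over size compositions, over labelings given sizes.

The description length $\mathcal{L}(c) = -\ln P(G|\hat\theta,c) - \ln
P(\hat\theta,c)$ (nats) is exactly label-permutation invariant and is
minimized; $P(c|G) \propto e^{-\mathcal{L}}$ justifies model averaging.

**Sampler.** Metropolis–Hastings over labelings with (a) single-node moves
proposed preferentially toward a random neighbor's block (probability
`pNeighbor = 0.9`, remainder uniform over blocks plus one fresh block, with
the exact proposal-ratio correction), and (b) merge-split "multi-flip"
moves (merge two random blocks / split one by random bisection, with
Hastings corrections). The schedule is: burn-in and sampling at $\beta=1$
(label marginals are collected from canonical relabelings, so they sum to
one per node), a geometric anneal $1 \to \beta_{\text{final}} = 5$, then a
deterministic greedy polish. Block statistics $(n_r, e_{rs}, s_{rs})$ are
maintained incrementally; an instrumented mode recomputes $\mathcal{L}$
from scratch after every accepted move and reports the largest discrepancy
(the suite requires agreement to $10^{-9}$).

The polish needed care. Greedy agglomeration from singletons can fuse two
true communities, and a random bisection essentially never proposes the
exact split needed to undo that ($2^{-k}$ chance). Splits are therefore
*trial moves*: a candidate bisection is adopted tentatively, relaxed by
true-$\Delta\mathcal{L}$ node moves, and kept only if the relaxed state
beats the pre-split description length. Candidate bisections come from
(i) the sign pattern of the second eigenvector of the block's deflated
normalized adjacency (power iteration, deterministic), (ii) growth from
the least-cosine-aligned pair of weight profiles, (iii) two random seed
pairs. Plain similarity-driven growth alone suffers rich-get-richer
absorption — weakly attached nodes join whichever side is already larger —
which single-node relaxation cannot undo; the spectral proposal does not.
`mcmcPartition` additionally runs `nRestarts = 3` independent searches
(singletons-plus-agglomeration, then random initial partitions) and keeps
the minimum-$\mathcal{L}$ state; equal-$\mathcal{L}$ ties resolve to the
lexicographically smallest canonical labeling.

**Scope.** This is a single-level, non-degree-corrected weighted SBM. The
nested hierarchical variant (communities of communities) and degree
correction are out of scope; a one-level refinement can be emulated by
re-running `mcmcPartition` on the block multigraph. The flat partition
prior costs roughly $n H(\text{sizes})$ nats, so at small $n$ the model is
deliberately conservative: it refuses splits whose evidence does not cover
that cost, where descriptive methods (modularity) still report structure.
This is the intended behavior — guarding against spurious aggregation of
noisy affinities — but it means fewer, larger communities than a nested
model would report on the same data.

## The synthetic-data generator

`simulateTraces` plants transient circuits: within a circuit's window and
its participating animals, member neurons share one latent drive scaled by
a per-member polarity ($\pm 1$; by default one member per circuit is
negative, exercising sign-blindness). The default drive is a single
monotone triangle excursion — rise to mid-window, fall back, constant
absolute slope — i.e. exactly one shared monotone excursion per window,
the cleanest form of the structure the affinity stage is designed to
detect; a double-exponential bump train (rise 1 s, decay 5 s,
calcium-indicator-like kinetics, onsets every 8 s, jittered amplitudes) is
available as `driveShape = "bumps"`. An earlier default used the bump
train everywhere, but superposed bumps create multiple apexes whose
zero-derivative crossings fragment the monotone segments — an artifact of
the drive's construction, not a property of noisy data — so the monotone
excursion is the default and the bump train the robustness variant.
Outside windows, neurons follow independent baseline drift (smoothed random
walk, default off) plus i.i.d. Gaussian observation noise.

What the generator does *not* emulate: sensor kinetics asymmetries,
bleaching and motion artifacts, lagged interactions, overlapping circuits
sharing members within a window (allowed but only flagged), and animal-
to-animal amplitude heterogeneity. Passing tests on these simulations
therefore demonstrates correctness of the inference machinery under the
stated model, not robustness to everything real recordings contain.

Study conditions used by the heavier tests (chosen as realistic desk-scale
sizes): 24 neurons × 5 animals × 400 samples at dt = 0.25 s, two planted
5-neuron circuits in disjoint 20 s windows, noise at 5% of drive
amplitude; tensors of size 20×10×50 for planted-rank recovery; graphs of
6–8 nodes for exhaustive enumeration (203–4140 partitions), 60 nodes for
planted-partition recovery.

## The weighted benchmark

`lfrGenerate` builds planted-community networks in the
Lancichinetti–Fortunato–Radicchi style: truncated power-law degrees
(exponent `tau1`, matched to `avgDeg`), power-law community sizes
(`tau2`, within `[minComm, maxComm]`), each node wiring a fraction
$1-\mu_{\text{topo}}$ of its degree inside its community through a
rejection-based configuration model (retry cap 100 per stub; unplaceable
stubs are dropped, so the degree sequence is honored approximately —
a documented deviation from the original edge-swap implementation).
Weights are Beta-distributed with mean $1-\mu_w$ within and $\mu_w$
between communities.

The default nine-network grid crosses $\mu_{\text{topo}} \in \{0.15, 0.30,
0.45\}$ (each row with its own community-size profile, one of them skewed)
with $\mu_w \in \{0.1, 0.5, 0.9\}$. The weight axis deliberately spans the
full heterogeneity range: assortative weights, uninformative weights, and
*inverted* weights ($\mu_w > 0.5$, between-community edges heavier than
within). Inverted weights are a legitimate weighted-network structure that
descriptive modularity cannot represent — maximizing weighted modularity
actively merges across such communities — while a generative weighted
blockmodel simply fits a different block-pair weight pattern. Grids
restricted to assortative weights were considered and rejected: there,
weighted greedy agglomeration is near-perfect and the comparison
degenerates into measuring the flat SBM's conservatism rather than either
method's ability to use weights. NMI uses the arithmetic-mean-of-entropies
normalization ($0\ln 0 := 0$; two single-cluster partitions agree by
convention), cross-checked in the tests against an independent
implementation.

## Known limitations

* Strict temporal coincidence: affinities ignore lagged coupling entirely.
* The affinity defaults assume temporally sparse activity (see above).
* The flat SBM's resolution is limited at small $n$; many small communities
  in large graphs are better served by the nested variant this package
  does not implement.
* The MCMC's merge-split Hastings corrections make the sampled marginals
  approximate near the proposal boundaries; the minimum-description-length
  state and its exhaustive-enumeration agreement are unaffected.
* LFR wiring drops unplaceable stubs instead of re-wiring, slightly
  biasing the realized degree sequence at extreme parameter settings.
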
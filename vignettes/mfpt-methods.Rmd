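---
title: "Mean first-passage times on stochastic networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean first-passage times on stochastic networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfptnet)
```

## The model

A discrete-state stochastic network is a directed multigraph of states
$0 \dots N-1$. Each edge from state $l$ to $l'$ carries a per-step jump
probability $u_{l'l}$ and a local time $\tau_{l'l} \ge 0$, the time cost of
that move. Self-loops are *waiting* probabilities $u_{ll}$ — residence in a
state before the next attempt — and both $u$ and $\tau$ may be asymmetric
between the two directions of a link. For every state with at least one exit
the probabilities sum to one, so a step of the walk is: draw one uniform
number, pick the edge whose cumulative-probability interval contains it, pay
that edge's local time, move.

The mean first-passage time (MFPT) from an initial state to a final state —
or to *any* member of a final set — is the expected accumulated local time
until first arrival. The package computes it three ways:

* **First-step analysis** (`mfpt_linear()`): the exact linear system
  $t_l = s_l + \sum_{l' \notin F} u_{l'l}\, t_{l'}$, $t_f = 0$ on the final
  set, where $s_l = \sum_{l'} \tau_{l'l} u_{l'l}$ is the mean step time of
  state $l$ (waiting included). This is the reference oracle the other two
  routes are tested against; it is itself a dense direct solve, practical to
  a few thousand states.
* **The Hill combinatorial route** (`mfpt_hill()`): the MFPT equals the
  reciprocal one-way stationary flux in a *modified* network in which every
  transition into the final set is redirected back to the initial state and
  the finals are deleted. The stationary occupations of the modified network
  are obtained from directed spanning trees: for each node $l$, the weight
  $W_l$ sums, over all spanning trees of the support, the product of rates
  oriented toward $l$, and $p^{st}_l = W_l / \sum_n W_n$. Rates come from
  $w_{l'l} = u_{l'l} / s_l$, so local times enter the Hill picture through
  the mean step time; self-loops contribute residence time but no rate edge.
* **Monte Carlo simulation** (`mfpt_mc()`): ensembles of independent
  walkers stepped in compiled code, with the per-simulation mean structure
  and error estimates described below.

## Numerical and algorithmic choices

**Tree enumeration.** Spanning trees are generated as lexicographically
ordered edge subsets of the undirected support and filtered by a union-find
acyclicity check. Parallel directed edges between the same pair of states
are merged into pair-level forward/backward rate sums first; tree weights
are multilinear in parallel-edge rates, so the merged enumeration yields
identical occupations while keeping the tree count equal to the matrix-tree
determinant of the simple support (the cross-check used in the tests).
Re-rooting a tree toward every node costs $O(N)$ per tree (divide by the
rate toward the old root, multiply by the rate toward the new one, with
explicit zero-factor bookkeeping so one-way edges work). When the number of
candidate subsets $\binom{E}{N-1}$ exceeds a budget (default $10^7$) the
enumeration refuses with an explicit error: trees and near-trees are cheap
(a tree has exactly one maximal tree), but cycle-rich networks such as
higher hypercubes belong to the Monte Carlo route.

**Multiple finals.** The modification merges every final into the initial
simultaneously; edges between two finals vanish (absorption happens at
first contact). This generalization is validated against the first-step
oracle and satisfies the monotonicity
$\tau(i \to F_1 \cup F_2) \le \min(\tau(i \to F_1), \tau(i \to F_2))$.

**Accessibility.** If no directed path reaches the final set the result is
the sentinel value `Inf`, written as the literal `Infinity (not accessible)`
in output files. A subtler case is a path that exists while absorption is
not almost sure (the walker can fall into a region that cannot reach the
finals): the MFPT is then genuinely infinite and is reported as `Inf` with
`accessible = TRUE`.

**Monte Carlo contract.** The stepper is defined per walker (one uniform
draw per step; a draw exactly on a cumulative boundary selects the latter
interval; zero-time edges add nothing; a walk starting on a final state
takes at least one step, giving return times). The compiled batch loop is
required by a test to replay the pure-R reference walker bit-for-bit on a
shared seed. R's default Mersenne-Twister generator drives both. With
`simulations > 1` the reported `std` is the standard deviation of
per-simulation means; independently, `se` is the walker-level standard
error of the grand mean, pooled over all walkers. The `se` is the quantity
used in 3-standard-error comparisons: with a handful of simulations the
simulation-level spread has so few degrees of freedom that a
3-standard-error gate on it has a several-percent false-alarm rate (a
$t_3$ tail), while the walker-level error has effectively Gaussian
calibration. `max_steps` (default $10^9$) aborts loudly rather than
truncating, to distinguish astronomically slow passages from unreachable
ones.

**Rational probabilities.** Tokens like `1/3` are kept as exact
numerator/denominator pairs through parsing, validation (row sums of
fraction-typed rows must be *exactly* one; decimal rows within $10^{-9}$)
and writing, so files round-trip bit-identically. Hill tree weights are
accumulated in doubles; on the network sizes the enumeration can handle,
agreement with the exact first-step solve is at the $10^{-14}$ level,
comfortably inside the $10^{-9}$ tolerance the tests demand.

## The chemo-chemical machine

`gate_system()` couples two reversible reactions through a conformational
network. Internal transitions out of state $l$ each get probability $p/k_l$
($k_l$ the degree), so detailed balance gives the equilibrium occupation
$p^{eq}_l = k_l / \sum k$. Reaction $l \in \{1, 2\}$ passes through a gate
pair: forward exit $l'' \to l'$ with probability
$v_{+l} = p / (\tau_l p^{eq}_{l''})$ and backward exit $l' \to l''$ with
$v_{-l} = p\, e^{-\beta A_l} / (\tau_l p^{eq}_{l'})$, where $\tau_l$ is the
external transition time and $\beta A_l$ the dimensionless force whose
Boltzmann factor breaks detailed balance. The unit probability $p$ is
pinned by requiring $p + v = 1$ at the gate with the largest external
transition probability (ties broken toward the smallest equilibrium
occupation, overridable); every other state receives a waiting self-loop
completing its row to one. Machine local times are all 1 — time is counted
in walker steps; conversion to physical time is the caller's affair.

One-way fluxes use the first-passage construction: append an absorbing
node `*`, redirect the chosen external transition into it, and take the
reciprocal MFPT from the opposite gate. The decomposition
$\tau(l' \to *) = \tau(l' \to l'') + (v_{+l}\, p^{st}_{l''})^{-1}$ — with
the MFPT and the stationary occupation both computed on the network in
which the redirected transition is closed into a self-loop — separates the
conformational and gate-kinetic contributions, and is enforced to
$10^{-6}$ relative in the tests. The degree of coupling is
$\varepsilon = J_2 / J_1$ of net fluxes; the efficiency
$\eta = -J_2 A_2 / (J_1 A_1)$ is reported as *undefined* (not zero) when
the output force vanishes.

The `gated_tree()` fixture places the gate pairs at leaves near opposite
ends of the tree diameter, oriented so that the two reaction cycles share
the backbone with aligned circulation. This is what makes the driving
reaction drag the driven one ($\varepsilon > 0$); scattering the gates
(placement `"random"`) typically decouples the reactions, and a reversed
orientation flips the sign of $\varepsilon$ — both behaviours are easy to
demonstrate empirically with `machine_fluxes()`.

## The binding-funnel analysis

`assign_transition_probabilities()` turns per-state energies into exit
probabilities: downhill moves score 1, uphill moves $e^{-\Delta E}$ with
$\Delta E = E_{\text{neighbour}} - E_{\text{state}} > 0$ (so uphill scores
are always below one — the sign convention is fixed here because the
verbal rule alone is ambiguous). Moves into states with ligand RMSD above
6 Å are zeroed (a flag switches the rule to moves *out of* such states,
the other reading of the rule); rows are normalized, transitions below
$10^{-6}$ pruned, and rows re-normalized — pruning after normalization
keeps rows stochastic, which the original prose leaves unspecified.
States left with no exit are recorded as absorbing dead ends, not errors:
walkers genuinely get stuck in funnels. CAPRI quality labels
(high/medium/acceptable/incorrect) follow the standard fnat/LRMSD/IRMSD
threshold clauses evaluated from best to worst.

Favourable paths minimize *summed MFPTs*: `mfpt_weighted_graph()` keeps an
edge wherever a finite MFPT exists, and `shortest_path()` runs Dijkstra
(via igraph, enumerating all shortest paths and returning the
lexicographically smallest node sequence so ties are deterministic; a
brute-force path enumeration is the test oracle on small graphs).

## What the generators emulate — and what they do not

`generate_network()` builds the benchmark families: hypercubes, Sierpinski
gaskets, Bethe lattices, random trees, cycles, and fractal scale-free
trees grown by hub-repulsion preferential attachment (a preferential
target is chosen, then with repulsion probability 0.7 the new leaf slides
to one of its neighbours, so hubs grow yet do not link to each other; only
the topological contract — a tree whose top hub degree is at least three
times the median — is asserted, since the published topology is cited
without a recipe). `figure1_style()` produces a 9-node, 9-edge network
with exactly one cycle, at least one waiting self-loop, and asymmetric
exact-rational probabilities and decimal times — the *structure* of the
small worked example; its exact published numbers live in a supplementary
archive that is not redistributed here, so tests assert structure and
solver agreement, not the printed MFPT values.

Synthetic fixtures exercise every code path — waiting, parallel edges,
zero-time edges, multigraph asymmetry, disconnection — but they are small
(3–200 states) and their randomness is tame. Passing tests therefore
demonstrate correctness of the machinery, not performance or ergodicity on
the knotted, dead-end-ridden networks real docking funnels produce; the
published funnel matrix itself took cluster-scale walltime and is loaded,
not recomputed, when available.

## Problem sizes used by the test-suite

The routine suite runs small: random networks of up to 8 states for the
oracle-equivalence ensembles (200 networks, $10^5$ walkers each), the
closed-form cycle family to $N = 12$, and gated trees of 10–40 states. The
benchmark block compares Hill and Monte Carlo at $10^7$ walkers on the
smallest fixtures (hypercubes to $d = 3$, a first-order gasket, a Bethe
lattice, a random tree) and falls back to $10^6$ walkers against the exact
first-step reference — numerically the same quantity Hill computes — on the
cycle-rich fixtures whose tree enumeration exceeds the budget
(hypercube $d = 4$, second-order gasket). These sizes were chosen as the
smallest that exercise every claim meaningfully.
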
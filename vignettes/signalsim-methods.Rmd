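---
title: "Simulating signaling-network activity data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating signaling-network activity data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalsim)
```

## Why simulate signaling data

Evaluating a network-inference method needs data whose generating network is
known. Real phosphoproteomics time courses never come with that guarantee,
so `signalsim` inverts the problem: the user specifies the network — nodes
are proteins (or distinct forms of a protein: phospho-forms and splice
variants should be separate nodes), edges are typed interactions — and the
package generates replicate activity time-series from it. Inference methods
run on the simulated data are then scored against the network that produced
it.

## The dynamical model

**State.** Every node holds an activity in [0, 100] %, the fraction of the
protein pool that is functionally active. This matches how laboratory
signaling measurements are reported (normalized to baseline), and is
deliberately not an abundance. Unperturbed nodes start at approximately the
50 % homeostatic steady state; "approximately" is realized as a uniform
jitter of ±2.5 around 50, seeded per replicate, and can be overridden
exactly by a user baseline profile (`sim_config(baseline = ...)` or a
`node,activity` CSV).

**Interactions.** The seven vocabulary terms map to signed weights:
activation positive, inhibition negative, with strength classes weak = 0.5,
standard = 1.0, strong = 1.5, and `binds` = 0 for physical association
without an activity effect. Terms outside the vocabulary are replaced by
`activates` and reported — a forgiving default for hand-edited edge tables.
Matching is case-insensitive, whitespace-tolerant, and accepts underscore
forms. The weight values are exposed via `interaction_vocabulary()`.

**Net input.** The signal into node $j$ at a step is
$x_j = \sum_{i \to j} w_{ij} \, a_i / 50$, summed over all incoming edges
(parallel edges and self-loops each contribute independently). The division
by 50 calibrates the scheme so that a single edge whose source sits at
baseline delivers exactly its class weight — the single-input signal range
is then 0.5 to 1.5 — and so that a fully inhibited source (activity 0)
delivers nothing, which is what lets an upstream clamp propagate downstream.
The model needs some rule for how source activity scales an edge's score;
this linear-in-activity choice is the simplest one consistent with both
requirements.

**Response.** Activity changes by the sigmoid
$\Delta a_j = 100/(1 + e^{-k x_j}) - 50$ with $k = 0.15$ by default
(user-changeable; units: per unit signal). Sigmoidal stimulus-response
curves are the standard phenomenological form for graded, reversible
signaling — multistep cascades, zero-order ultrasensitivity and positive
feedback all produce them. The curve is odd, strictly increasing and bounded
in (−50, +50) per step. Because responses are continuous and reversible, the
model intentionally cannot represent one-way switches such as cell-cycle
checkpoints, and it has no spatial compartments.

**Update scheme.** All nodes update synchronously from the previous step's
state (a Jacobi iteration). The alternative — sequential updates in node
order — would make results depend on the order nodes happen to be listed in;
the synchronous scheme is order-independent and reproducible. Activities are
clipped to [0, 100] after every update, not merely at export, so no internal
state can leave the biological range. Time points are numbered 1..T and the
initial state is emitted as time point 0, giving T+1 recorded rows per
replicate and node.

**Noise.** The stochasticity knob perturbs the input–output relationship:
after the response is computed, a zero-mean Gaussian deviate with standard
deviation $(\text{noise\%}/100) \times 50$ is added. The scaling against the
±50 half-range of the response curve makes the percentage interpretable:
10 % noise means deviations of order one tenth of the largest possible
per-step response. At 0 % (the default) the path is exactly deterministic
given the seed. The Gaussian form is one reasonable choice for aggregate
fluctuation of many stochastic molecular events; other noise models could
sit behind the same `apply_noise()` contract.

**Decay.** Optionally, each node also loses activity by
$100/(1 + e^{k d_j}) - 50$ per step, with a decay rate $d_j$ drawn once per
node per replicate from U(0, 5) — different proteins turn over at different,
but individually constant, rates. Decay is unregulated (independent of the
network), requires a time series of at least two points, and acts only on
the second half of the series (step index $> \lfloor T/2 \rfloor$), so a
stimulated system first responds and then relaxes back toward homeostasis.
Sampling the rate once per node-replicate (rather than per step) is a
documented modeling choice: it reads as a per-protein turnover constant.
The rates are drawn during initialization whether or not decay is enabled —
they are simply inert when it is off — which guarantees that a decay-on run
and a decay-off run under the same seed agree exactly on the first half of
the time series.

**Perturbations.** External inhibition or activation (a drug, a knockdown)
clamps a node at 0 or 100 for as long as the perturbation is active. If a
release step is given, the clamp is lifted after that time point and the
node's activity is restored to its recorded baseline, after which it evolves
freely. Restoration (rather than leaving the node wherever the clamp held
it) is needed for recovery to be possible at all: a clamped source node has
no incoming edges driving it, so without restoration its activity would stay
at the clamped value forever and downstream nodes could never rejoin their
unperturbed behaviour. Under a shared seed at zero noise, a released node's
trajectory coincides exactly with its counterpart in an unperturbed copy of
the network — a property the test suite checks on the twin three-node
chains of `perturbation_demo_networks()`. Whether a clamp should sit at
exactly 0/100 or near them is a judgment call; exact pinning was chosen for
its crisp semantics.

## Randomness and reproducibility

One master seed governs everything. Replicate $r$ runs on the stream seeded
with $(\text{seed} + r \cdot 1000003) \bmod (2^{31}-1)$, so adding
replicates never reshuffles existing ones. Within a replicate the draw
order is fixed: baseline jitter for every node, then a decay rate for every
node, then one noise deviate per node per step whenever noise is positive
(deviates for clamped nodes are drawn and discarded). Drawing for *every*
node regardless of profiles, clamps or the decay flag is what keeps streams
aligned across configurations that differ only in those options, making
paired comparisons (decay on/off, perturbed/unperturbed) exact rather than
statistical.

## Scoring and benchmarking

`edge_confusion()` compares a predicted edge list with the ground-truth
network over unique edges: precision = TP/(TP+FP), recall = TP/(TP+FN)
(reported under both names — "sensitivity" is the same quantity), F1 their
harmonic mean. `binds` edges record undirected association and match either
orientation even in directed mode; `strict = TRUE` additionally requires the
predicted effect sign to agree. An empty prediction has undefined precision
and is reported as `NaN` with a warning, never silently as 0.

`score_against_reference()` correlates replicate-mean trajectories with a
reference time course, mapping simulated step $t$ to reference time
$t \times \text{time\_scale}$ (real stimulation experiments sample in
minutes; a scale of 0.5 means one step per half minute). Per-node scores are
Pearson coefficients over matched pairs; the overall score pools all matched
pairs into a single Pearson coefficient. Pooling was chosen over averaging
per-node coefficients because it weights nodes by their number of matched
time points and keeps the overall score a genuine correlation; users wanting
the other convention can average `per_node` themselves. Correlation of a
zero-variance series is an error, not 0.

## The generators

`strength_demo_network()` (one source, six graded edges) exists to make the
strength classes visible: at zero noise with equal baselines the trajectory
ordering is strong > standard > weak activation above baseline, mirrored
below it by the inhibitions, and the weak pair is an exact reflection about
50. `perturbation_demo_networks()` provides twin three-node chains for the
clamp-and-release behaviour. `egfr_demo_network()` loads a small EGF-receptor
network shipped as an editable SIF; only the weak EGFR→STAM2 and strong
EGFR→Shc1 strengths are anchored in published activation dynamics, the rest
are illustrative defaults (the file is labelled synthetic for that reason).
`random_signaling_network()` draws seeded Erdős–Rényi-style directed
networks with a user mix over the vocabulary, for stress tests and
benchmarking at scale; self-loops are off by default so feedback is always
an explicit modeling decision.

## What the simulations do and do not show

The generator emulates: graded sigmoidal responses, replicate-to-replicate
variability from baseline jitter and input–output noise, per-protein decay,
and drug-like clamping with release. It does not emulate: mass-action or
Michaelis–Menten kinetics with real rate constants, spatial localization,
switch-like irreversibility, transcriptional feedback on the time scales of
signaling, or measurement error models specific to a platform. A method
that performs well on these data has shown it can recover the topology of a
system whose dynamics follow this sigmoidal discrete-step map under Gaussian
input noise — a necessary bar, not proof it will work on any particular
experimental dataset.

## Numerical and testing choices

Tolerances: the response and decay curves are checked against independently
coded closed forms at 1e−12; paired shared-seed properties (mirror symmetry,
decay-window inertness, perturbation equivalence) are checked at 1e−12 or
bitwise. Degenerate inputs are errors, not silent coercions: empty networks,
empty interaction terms, baselines outside [0, 100], decay rates outside
[0, 5], decay with fewer than two time points, zero-variance correlations.
Ties in vocabulary matching cannot arise (the map is a lookup). The test
suite runs the stress batteries at reduced size — bounds on 1,000 random
networks of up to 20 nodes with up to 50 % noise simulated for 6 steps at
one replicate, oracle equivalence of the synchronous step on 200 networks of
up to 10 nodes, and 500 random confusion-matrix cases — sizes chosen to
exercise the property space densely while keeping the default test run
quick.

## Known limitations

Saturation at the [0, 100] clip is absorbing under sustained input, so
long simulations of strongly driven networks end pinned at the boundary;
choose time-series lengths on the scale of the transient of interest.
Net input is linear in source activity; cooperative or saturating edge
transfer would need a different contribution rule behind `net_input()`.
The decay window (second half of the series) is a fixed convention, not
user-tunable. The CLI writes CSV only.
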
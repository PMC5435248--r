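# signalsim

Simulation of cell-signaling network activity data for benchmarking network
inference.

Network-inference methods for signaling data are hard to evaluate because the
true wiring of a real pathway is never fully known. `signalsim` solves this
the standard way: the user writes down a directed signaling network with
typed interaction strengths, the package simulates replicate time-series of
per-protein percentage activity from it, and any inference method run on
those data can then be scored against the network that generated them —
precision, recall/sensitivity and F1 for predicted edges, and Pearson
correlation for trajectories against reference time courses. It is aimed at
computational biologists developing or comparing inference methods, and at
experimentalists who want bespoke in-silico data for a pathway of interest
(perturbation screens, noise-robustness studies, pilot power analyses).

## The model

Each node carries an activity in [0, 100] %, interpreted as the fraction of
the protein pool that is functionally active (data normalized to baseline,
not abundance). Unperturbed nodes start near the 50 % homeostatic baseline
(a U(−2.5, +2.5) jitter around 50, or a user-supplied baseline profile).
Edges come from a seven-term controlled vocabulary —
`activates`, `weakly activates`, `strongly activates`, `inhibits`,
`weakly inhibits`, `strongly inhibits`, `binds` — mapped to signed weights
w ∈ {±0.5, ±1.0, ±1.5, 0}; any other term falls back to `activates` and is
reported.

At each discrete step every node updates synchronously. The net input
("signal") into node *j* is

    x_j = Σ_edges (i→j)  w_ij · a_i / 50

so a single edge whose source sits at baseline contributes exactly its class
weight, and a fully inhibited source contributes nothing. The change in
activity is the sigmoidal signal-response curve

    Δa_j = 100 / (1 + exp(−k·x_j)) − 50 ,   k = 0.15 by default,

optionally plus a zero-mean Gaussian noise term with sd = (noise % / 100)·50,
and — when the decay option is on and the step lies in the second half of the
time series — plus the stochastic decay term

    Δa_j^decay = 100 / (1 + exp(k·d_j)) − 50 ,   d_j ~ U(0, 5) per node,

modeling unregulated protein turnover. Activities are clipped to [0, 100]
after every step. Perturbations clamp a node at 0 % (inhibition) or 100 %
(activation), optionally released after a chosen time point. Each replicate
("experimental repeat") runs on its own seeded stream, so results are exactly
reproducible.

## Worked example

```r
library(signalsim)

net <- strength_demo_network()   # one source with six graded edges
net
#> Signaling network: 7 nodes, 6 edges
#>   nodes: A, B, C, D, E, F, G
#>   A weakly inhibits B (w = -0.5)
#>   A inhibits C (w = -1.0)
#>   A strongly inhibits D (w = -1.5)
#>   A weakly activates E (w = +0.5)
#>   A activates F (w = +1.0)
#>   A strongly activates G (w = +1.5)

cfg <- sim_config(n_replicates = 10, n_timepoints = 20, noise_pct = 5, seed = 7)
ts  <- simulate(net, config = cfg)
summary(ts)
#> Trajectory set: 10 replicates x 21 time points (incl. initial) x 7 nodes
#>   activity range: [ 0.00 , 100.00 ] %
#>   replicate-mean final activities:
#>     A: 50.01%
#>     B: 13.69%
#>     C: 0.00%
#>     D: 0.32%
#>     E: 90.01%
#>     F: 99.81%
#>     G: 99.95%
```

The source A has no inputs, so it stays at baseline; the strongly activated
node G saturates fastest, the weakly activated E slowest, and the inhibited
nodes mirror them downward — the graded response the strength classes are
for. Scoring a (here hand-made) predicted edge list against the ground
truth:

```r
pred <- data.frame(source = c("A", "A", "B"), target = c("G", "B", "A"))
edge_confusion(net, pred)
#> Edge prediction metrics (directed):
#>   TP = 2, FP = 1, FN = 4
#>   precision = 0.6667
#>   recall (sensitivity) = 0.3333
#>   F1 = 0.4444
```

Two of the three predicted edges exist in the truth network (A→G, A→B); the
reversed edge B→A does not, and four true edges were missed.

The same workflow is available from a shell:

```sh
exec/signalsim simulate --network inst/extdata/strength_demo.sif \
    --replicates 10 --timepoints 20 --noise 5 --seed 7 --out run1
exec/signalsim benchmark --truth inst/extdata/strength_demo.sif --pred pred.csv
exec/signalsim score --trajectories run1_long.csv --reference ref.csv --time-scale 0.5
```

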
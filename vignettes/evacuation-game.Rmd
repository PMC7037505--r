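---
title: "Modelling evacuation decision diffusion as an evolutionary game on a small-world network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evacuation decision diffusion as an evolutionary game on a small-world network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evacgame)
```

## The problem

When a typhoon is forecast, households in the threatened zone face a binary
protective decision: **evacuate** to a safe zone, or **stay** at home. Both
choices are costly — evacuating means abandoning fixed assets and paying
congestion, transport and accommodation costs; staying means emergency
supplies, housing reinforcement, and exposure to the hazard itself. The
choices interact: every household that stays frees road and shelter capacity
for evacuees, and every household that leaves frees emergency supplies for
stayers. Government policy enters through subsidies and logistics that
reduce either side's costs. Finally, people do not optimise in isolation:
they imitate the apparently successful decisions of kin and friends, so the
population-level evacuation response emerges from decision diffusion on a
social network.

`evacgame` implements this system at three levels: a two-player payoff
matrix, its mean-field replicator dynamics, and a stochastic imitation
dynamic on a Watts–Strogatz small-world graph.

## The payoff matrix

Two groups of households play the symmetric-form bimatrix game with
strategies {Evacuate, Stay}. Group *i* is characterised by total assets
$P_i$, abandoned fixed assets $C_i$ (of which $C_i'$ is recoverable through
government action), evacuation-process cost $D_i$ and stay cost $E_i$, all
on one abstract value scale (no currency or discounting is modelled; payoffs
are single-shot per round). Six dimensionless parameters modulate them:

| parameter | meaning | range |
|---|---|---|
| $\alpha$ | perceived strike probability | $[0,1]$ |
| $\beta$  | evacuation-cost reduction when the counterpart stays | $[0,1]$ |
| $\theta$ | stay-cost reduction when the counterpart evacuates | $[0,1]$ |
| $\delta$ | government reduction of the evacuation-process cost | $[0,1]$ |
| $\epsilon$ | government stay-cost coefficient when exactly one party stays | $[0,1]$ |
| $\eta$ | government stay-cost coefficient when both parties stay | $[0,1]$ |

With subscript order (Group 1's strategy, Group 2's strategy), Group 1's
cells are

$$
\begin{aligned}
U_{11} &= P_1 - \alpha(C_1 - C_1') - (1-\delta)D_1 &
U_{12} &= P_1 - \alpha(C_1 - C_1') - (1-\delta)(1-\beta)D_1\\
U_{21} &= (1-\alpha)P_1 - \epsilon(1-\theta)E_1 &
U_{22} &= (1-\alpha)P_1 - \eta E_1
\end{aligned}
$$

and Group 2's cells $V_{ab}$ take the same four expressions with subscript-2
quantities, arranged so that identical economics yield a fully symmetric
game ($U_{ab} = V_{ba}$). `compute_payoff_matrix()` enforces the type
invariants (all parameters in range, $C' \le C$) at construction.

Note on subscript conventions: publications in this literature are not
always consistent about whether the first subscript of the column player's
cells refers to the row player's strategy or the column player's own. We fix
the Table-style convention above (first index = Group 1's strategy)
everywhere; with it, Group 2's expected evacuation payoff mixes $V_{11}$ and
$V_{21}$, and the linear-coefficient identity below holds exactly. A
property test pins this reading.

## Mean-field replicator dynamics

Let $x$ and $y$ be the evacuating fractions of Groups 1 and 2. The payoff
advantage of evacuating is linear in the opposing share,

$$U_{E1}-U_{S1} = A_1 y + A_2, \qquad U_{E2}-U_{S2} = B_1 x + B_2,$$

with

$$A_1 = (\delta-1)\beta D_1 + E_1\big[(1-\theta)\epsilon - \eta\big], \qquad
  A_2 = \alpha P_1 - \alpha(C_1-C_1') - (1-\delta)(1-\beta)D_1 + \eta E_1,$$

and $B_1, B_2$ analogously for Group 2. The bracket placement in $A_1$ is
the unique reading under which $A_1 y + A_2$ expands exactly to
$U_{E1}-U_{S1}$ from the cell formulas; the package enforces this identity
to $10^{-10}$ in its test suite rather than trusting either form alone.
The replicator system is

$$\dot x = x(1-x)(A_1 y + A_2), \qquad \dot y = y(1-y)(B_1 x + B_2).$$

`find_equilibria()` returns the four corner rest points, plus the interior
point $(x^*, y^*) = (-B_2/B_1, -A_2/A_1)$ whenever both slopes are non-zero
and both coordinates are strictly inside $(0,1)$ (strictness margin
$10^{-9}$, so corners are never double-counted; a zero slope is reported as
a reason code, not an error). Stability is classified from the Jacobian

$$J = \begin{pmatrix} (1-2x)(A_1y+A_2) & x(1-x)A_1\\
                       y(1-y)B_1 & (1-2y)(B_1x+B_2)\end{pmatrix}$$

as saddle ($\det J<0$), stable node ($\det J>0$, $\operatorname{tr}J<0$),
unstable node ($\det J>0$, $\operatorname{tr}J>0$), center
($\det J>0$, $\operatorname{tr}J=0$) or degenerate ($\det J=0$). Sign
comparisons use the tolerance $10^{-9}\max(|A_1|,|A_2|,|B_1|,|B_2|)^2$, so
classification is scale-aware. The off-diagonal entries are the true
partial derivatives — some published variants of this table carry a
transcription error there, and another in the sign of the trace at $(1,1)$;
we validate all four entries against central finite differences at random
parameter draws, which settles both. Two consequences worth knowing:

* At the interior point $A_1 y^* + A_2 = B_1 x^* + B_2 = 0$, so the diagonal
  vanishes and $\operatorname{tr}J = 0$ identically: the interior point is
  never asymptotically stable in the mean field (it is a saddle when
  $\det J = -x^*y^*(1-x^*)(1-y^*)A_1B_1 < 0$, i.e. when $A_1 B_1 > 0$).
* At $(1,1)$ the trace is $-[(A_1+A_2)+(B_1+B_2)]$: all-evacuate attracts
  exactly when both groups keep a positive evacuation advantage at full
  evacuation.

`integrate_replicator()` integrates the field with fixed-step classical
4th-order Runge–Kutta (default step 0.01, via `deSolve`). The unit square is
invariant analytically; numerically we clip only accumulated round-off below
$10^{-12}$ and abort on anything larger or non-finite.

```{r equilibria}
econ <- group_economics(P = 10, C = 8, Cprime = 1, D = 4, E = 2)
pol  <- policy_params(alpha = 0.5, beta = 0.45, theta = 0.45,
                      delta = 0.3, epsilon = 0.7, eta = 0.5)
find_equilibria(field_coefficients(econ, econ, pol))
```

## The networked imitation dynamic

The mean field ignores who talks to whom. The agent-based layer places one
household per node of a Watts–Strogatz small-world graph — the canonical
model for kin networks, combining high clustering with short paths. The
construction (`generate_small_world()`) rings $N$ nodes, joins each to
$K/2$ neighbours per side, and rewires each edge with probability $p$,
forbidding self-loops and multi-edges so the edge count $NK/2$ is conserved.
A disconnected draw would silently bias the diffusion, so it is discarded
and redrawn with an incremented seed (logged, at most 100 attempts).

Each round, every household $i$:

1. earns the payoff-matrix cell against each neighbour, aggregated over the
   neighbourhood (sum by default; mean is available and equals sum/degree);
2. draws one neighbour $j$ uniformly (`neighbor_choice_distribution()`
   normalises adjacency weights, which is uniform for the unweighted graphs
   shipped; a weighted hook is retained but no weighting scheme is shipped);
3. keeps its strategy if $pr_i \ge pr_j$, and otherwise adopts $j$'s
   strategy with the Fermi probability
   $W = 1/\big(1+\exp[(pr_i-pr_j)/k]\big)$, where $k>0$ is the noise
   intensity.

The Fermi rule is used in its standard orientation — adoption becomes more
likely the better the neighbour does. The opposite sign convention
occasionally appears in print; it contradicts the gating condition in step
3 (one would almost never copy a much more successful neighbour), so it is
available only as `fermi_variant = "as_printed"` for fidelity experiments.
Updates are synchronous by default (all comparisons use the round-start
state); an asynchronous random-permutation scheme is provided. Payoffs are
recomputed from the current profile each round — nothing accumulates.
Consensus is absorbing under both schemes: adopting the strategy of a
like-minded neighbour changes nothing, even when degrees (and hence summed
payoffs) differ.

`run_ensemble()` repeats the whole run (fresh random initial strategies,
default Bernoulli(0.5)) `n_reps` times on one fixed graph, and reports the
per-round mean and standard deviation of the evacuation response rate — the
fraction of nodes playing Evacuate — plus the final-round ensemble mean.
Per-repetition child seeds are derived from the master seed by a
multiplicative-congruential counter scheme, so individual repetitions are
independently reproducible and two scenarios run under the same master seed
share their randomness (common random numbers). The one-round transition
law is verified against exhaustive enumeration of the (neighbour choice ×
Fermi coin) lottery on small graphs; this is the core correctness test of
the update rule.

## Default study conditions and calibration

The packaged defaults (`default_config()`) describe a stylised coastal
evacuation: $N = 200$ households, $K = 4$, $p = 0.1$ (the network size is a
standard choice for this model class; $K$ and $p$ are canonical small-world
settings and are recorded in every output), $T = 20$ rounds, 200
repetitions, neutral noise $k = 1$, $\alpha = 0.5$, and economics
$P = 10$, $C = 8$, $C' = 1$, $D = 4$, $E = 2$ — elicitation-style round
numbers placing evacuation cost at 40% and stay cost at 20% of total
assets.

Policy sweeps vary one lever over its grid ($\beta, \theta$ over
0.05–0.85; $\delta$ over 0.1–0.5; $\epsilon, \eta$ over 0.5–0.9) while the
others sit at a fixed baseline. For the baseline we take the grid midpoints
for $\beta, \theta, \delta, \epsilon$, and $\eta = 0.5$. The $\eta$ choice
is a deliberate calibration: the baseline should sit in the interior regime
(so every lever has room to move the response in both directions) while
still letting the two documented extremes emerge — with $\eta = 0.5$,
weak resource sharing ($\beta = 0.05$) makes staying strictly dominant
($A_2 < 0$ with $A_1 < 0$) and the system empties of evacuators, while
strong government evacuation support ($\delta = 0.5$) makes evacuating
dominant ($A_1 + A_2 > 0$) and the system fills. At the mid-grid
$\eta = 0.7$ the first extreme is unreachable for any $\beta$ (the stay
subsidy alone keeps $A_2 > 0$), which would make the weak-$\beta$ regime
qualitatively different from the one the model is meant to exhibit.
All five response directions — increasing in $\beta$, $\delta$,
$\epsilon$, $\eta$; decreasing in $\theta$ — hold at this baseline, each
assessed as an endpoint difference exceeding twice its pooled standard
error under common random numbers.

```{r sweep, eval = FALSE}
sw <- run_sweep(sweep_spec("beta"))
sw$table
#>  value final_rate final_sd
#>   0.05     0.1524  0.06008
#>   0.25     0.3863  0.06726
#>   0.45     0.6816  0.06971
#>   0.65     0.7932  0.05392
#>   0.85     0.8972  0.03272
```

## What the simulations do and do not show

The generator emulates the *structure* of the problem: cost-driven binary
choice, local imitation, small-world mixing, policy levers entering
multiplicatively through costs. Passing tests show the implementation is
faithful to that model and that the model's comparative statics are as
described. They do not show that real evacuation behaviour follows the
model: the economics are stylised scores, not measured quantities; the
network is synthetic (no household sizes, no spatial correlation with the
hazard, no media broadcast); all households share one parameter set; and
the government is a fixed parameter vector, not an adaptive player.
Mobility, mortality and within-event timing are out of scope.

## Numerical and design choices

* **Tolerances.** Equilibrium classification: $10^{-9}$ scaled as above.
  Coefficient identity: $10^{-10}$. Jacobian finite-difference check:
  $10^{-5}$ at step $10^{-6}$.
* **Degenerate inputs.** $A_1 = 0$ or $B_1 = 0$ → interior reported absent
  with reason code `zero_slope_coefficient`. Equal payoffs in the Fermi
  rule give $W = 1/2$, but the $pr_i \ge pr_j$ gate keeps the strategy, so
  ties never cause churn.
* **Aggregation.** Neighbourhood payoffs default to `sum` (conventional in
  network games; near-equivalent to `mean` here since Watts–Strogatz degrees
  are nearly homogeneous). Both are exposed.
* **Group roles.** All nodes read the matrix as the row player — exact for
  the symmetric default economics. A `groups` argument assigns
  column-player roles for asymmetric experiments.
* **Problem sizes.** The shipped tests run the full study scale
  ($N = 200$, $T = 20$, 200 repetitions, five sweeps) in a few minutes on
  one CPU; the transition-law enumeration uses 50,000 one-round replicates
  on a 4-node path.

## Limitations

The mean-field analysis and the network simulation answer different
questions and need not agree quantitatively: the network dynamic is a
single population of row players, whose rest point tracks
$-A_2/A_1$ only approximately, with the gated Fermi rule adding drift near
payoff ties. The stability table classifies the two-group mean field, not
the simulation. Equilibrium selection under bistability depends on the
initial fraction (0.5 by default) and on network realisations; conclusions
about basins of attraction should come from `integrate_replicator()` phase
portraits plus ensembles over several initial fractions, not from single
runs.
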
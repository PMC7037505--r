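# evacgame

Evolutionary-game modelling of evacuation decisions under a predictable
disaster such as a typhoon. Households facing an evacuation warning choose
between **Evacuate** and **Stay**; their payoffs trade asset risk against
evacuation and sheltering costs, modulated by government policy levers, and
their decisions spread through a small-world social network by
payoff-driven imitation. The package is aimed at emergency-planning
researchers who want to explore how policy instruments (traffic guidance,
asset protection, emergency-supply guarantees) shift the population-level
*evacuation response rate*.

## The model

Group *i* has total assets `P_i`, abandons fixed assets `C_i` when
evacuating (`C_i'` recoverable through government action), pays evacuation
cost `D_i` or stay cost `E_i`. With strike probability `α`, cost-sharing
rates `β` (stayers free resources for evacuees) and `θ` (evacuees free
supplies for stayers), and government coefficients `δ` (evacuation-cost
reduction), `ε` and `η` (stay-cost multipliers with partial / full
guarantee), the row player's payoff cells are

    U11 = P1 − α(C1 − C1′) − (1−δ)D1          (both evacuate)
    U12 = P1 − α(C1 − C1′) − (1−δ)(1−β)D1     (evacuate alone)
    U21 = (1−α)P1 − ε(1−θ)E1                  (stay alone)
    U22 = (1−α)P1 − ηE1                       (both stay)

The payoff advantage of evacuating is linear in the opposing group's
evacuating share: `UE1 − US1 = A1·y + A2` with
`A1 = (δ−1)βD1 + E1[(1−θ)ε − η]` and
`A2 = αP1 − α(C1−C1′) − (1−δ)(1−β)D1 + ηE1`. The mean-field replicator
system `ẋ = x(1−x)(A1 y + A2)`, `ẏ = y(1−y)(B1 x + B2)` is analysed by
Jacobian sign classification of its (up to five) rest points. The networked
layer plays the same game on a Watts–Strogatz graph with a gated Fermi
imitation rule: a household copies a randomly drawn neighbour only when the
neighbour out-earns it, with probability `1/(1 + exp[(pr_i − pr_j)/k])`.

See the methods vignette (`vignettes/evacuation-game.Rmd`) for assumptions,
parameter semantics, numerical choices and limitations.

## Worked example

```r
library(evacgame)

econ <- group_economics(P = 10, C = 8, Cprime = 1, D = 4, E = 2)
pol  <- policy_params(alpha = 0.5, beta = 0.45, theta = 0.45,
                      delta = 0.3, epsilon = 0.7, eta = 0.5)
pm <- compute_payoff_matrix(econ, econ, pol)
pm
#> Payoff matrix (row = Group 1; 1 = Evacuate, 2 = Stay):
#>             Evacuate              Stay
#>   Evacuate  U11=3.7     V11=3.7     U12=4.96    V12=4.23
#>   Stay      U21=4.23    V21=4.96    U22=4       V22=4

find_equilibria(field_coefficients(econ, econ, pol))
#> Equilibria of the replicator system (5 points):
#>         x        y      detJ   trJ         label
#>  0.000000 0.000000  0.921600  1.92 unstable_node
#>  0.000000 1.000000  0.508800 -1.49   stable_node
#>  1.000000 0.000000  0.508800 -1.49   stable_node
#>  1.000000 1.000000  0.280900  1.06 unstable_node
#>  0.644295 0.644295 -0.116606  0.00        saddle

res <- run_ensemble(network_spec(200, 4, 0.1, seed = 1), pm,
                    sim_config(rounds = 20, n_reps = 200, master_seed = 2020))
res
#> Ensemble of 200 repetitions, 20 rounds, N=200 nodes
#>   initial rate 0.503 -> final evacuation response rate 0.691 (sd 0.066)
```

Reading the output: under the baseline policy, evacuating alone (4.96)
beats evacuating together (3.70) because stayers free road capacity, and
staying alone (4.23) beats staying together (4.00) only via the government
guarantee — so neither pure convention dominates. The mean field has an
interior rest point at an evacuating share of 0.644 (a saddle of the
two-group system), and the 200-household network ensemble settles at a
final evacuation response rate of about 0.69: partial compliance, the
regime most sensitive to policy.

Policy sweeps quantify each lever's effect with common random numbers:

```r
sw <- run_sweep(sweep_spec("beta"))   # β ∈ {0.05, 0.25, 0.45, 0.65, 0.85}
sw$table
#>  value final_rate final_sd
#>   0.05     0.1524  0.06008
#>   0.25     0.3863  0.06726
#>   0.45     0.6816  0.06971
#>   0.65     0.7932  0.05392
#>   0.85     0.8972  0.03272
```

A command-line wrapper is installed at `exec/evacgame` inside the package
(subcommands `payoff`, `stability`, `simulate`, `sweep`, `network`), e.g.

```sh
Rscript inst/exec/evacgame stability
Rscript inst/exec/evacgame sweep --param beta --seed 7 --out sweep_beta.csv
```

Every output embeds the fully resolved configuration and master seed.

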
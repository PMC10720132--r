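# coopcell

Social-fitness statistics and evolutionary-game models of altruistic
cooperation among cancer cells.

A minority of breast cancer cells can behave altruistically under
chemotherapy: they secrete diffusible factors (IGFBP2, CCL28) that protect
neighbouring cells from taxane exposure, while paying a proliferation cost
themselves through cell-cycle arrest. coopcell is for researchers who want
to quantify that behaviour in tagged co-culture competition assays and to
explore, in simulation, why such a costly minority can persist. The
package implements:

* **Social-fitness statistics** for tagged co-cultures — relative survival
  and relative fitness with the 1:1 homogeneous-well normalization,

  RS_α = (normalized control survivors beside altruists) /
  (control survivors beside controls),
  RF_α = (normalized control-derived progeny) / (altruist-derived progeny)
  in the regrown heterogeneous population —

  plus the Hamilton-style social-behaviour matrix (altruism / mutual
  benefit / selfishness / spite / neutral), percentage benefit
  PB(x) = 100·(R(x) − R(0))/(R(50) − R(0)), marginal benefit
  MB = (PB(y) − PB(x))/((y − x) + 1) at category (x+y)/2 with
  linear-vs-quadratic shape selection, and the rescue / viability-change /
  reporter-reduction / CRISPRi-effect percentage formulas.
* **A well-mixed public-goods game** with others-only saturating benefit
  V(x) = B·x^h/(k^h + x^h): producer fitness W_A = s_A(τ)(1 − c), defector
  fitness W_D(x) = σ0(τ) + (1 − σ0(τ))·V(x), replicator dynamics,
  equilibrium finding with stability, and therapy sweeps.
* **A lattice agent-based tumor model** contrasting genetic inheritance of
  the altruist state (extinction) with epigenetic best-response
  regeneration (a stable producer minority, re-established from either
  sorted extreme).
* **A secrete-and-sense lateral-inhibition model** reproducing
  salt-and-pepper patterning at contact range (d = 1) and sparse altruist
  spacing at longer range (d > 1), including the antibody-truncation
  scenario.
* **A seeded synthetic-data generator** for co-culture counts, benefit
  titrations and reporter-fluorescence populations, so the whole chain is
  testable offline.

## Worked example

Simulate the tagged co-culture experiment (altruism active: benefit
B = 0.5, producer cost c = 0.3, producer drug tolerance s_A = 0.9, 5%
measurement noise), then compute the social-fitness report:

```r
library(coopcell)

counts <- simulate_coculture(
  coculture_design(doses = c(0, 2), replicates = 3),
  truth_params(B = 0.5, c = 0.3, s_A = 0.9, noise_cv = 0.05),
  seed = 1)
social_fitness(counts)
#> # A tibble: 2 x 8
#>   dose_nM rs_alpha rs_alpha_sd rs_beta rf_alpha rf_alpha_sd n_replicates label
#>     <dbl>    <dbl>       <dbl>   <dbl>    <dbl>       <dbl>        <int> <chr>
#> 1       0     1.01      0.0534    1.02     2.34      0.337             3 altruism
#> 2       2     2.60      0.124     4.28     1.47      0.0884            3 altruism
```

At 2 nM drug, control cells beside altruists survive 2.6× better than
beside other control cells (RS_α = 2.60 > 1: the partners are protected),
yet the regrown population is dominated by control-derived cells
(RF_α = 1.47 > 1: the altruists paid a fitness cost) — benefit to the
recipient, cost to the actor: the matrix classifies the interaction as
altruism. Without drug (dose 0) there is no survival effect (RS_α ≈ 1)
but the growth cost remains visible in RF_α.

The game model explains why the altruists nonetheless persist in a
well-mixed population under therapy:

```r
find_equilibria(public_goods_game(tau = 1))
#> Public-goods game equilibria
#>   x* = 0.220000 (stable)
#>   boundaries: x=0 unstable, x=1 unstable
```

Because the benefit is concave (saturating), defector fitness falls as
producers become rare, and the population settles at a stable polymorphic
equilibrium with producers at a 22% minority. And the patterning model
shows how diffusible (rather than contact-bound) inhibition spaces those
altruists out:

```r
pattern_stats(simulate_pattern(50, inhibition_rules(d = 5), seed = 1))
#> # A tibble: 1 x 3
#>   high_fraction lag1_autocorr mean_nn_distance
#>           <dbl>         <dbl>            <dbl>
#> 1        0.0248       -0.0254             6.00
```

A sparse 2.5% altruist scatter spaced ~6 cell diameters apart — versus the
~40% alternating checkerboard the same model produces at contact range
(`d = 1`).

A command-line front end is installed at `inst/cli/coopcell`
(subcommands `simulate-coculture`, `metrics`, `benefit-curve`,
`game-equilibria`, `game-sweep`, `spatial-run`, `pattern`), driven by a
YAML config with `--seed`/`--out`/`--set` overrides; every run writes a
manifest with the config hash and seed.

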
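---
title: "Models and methods behind coopcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coopcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

coopcell quantifies altruistic cooperation among cancer cells: a minority
of "producer" (altruist) cells secretes diffusible factors that protect
neighbouring non-producer ("defector") cells from chemotherapy, while the
producers themselves pay a proliferation cost. The package covers four
linked pieces: the social-fitness statistics measured in tagged co-culture
competition assays, a well-mixed evolutionary public-goods game, a lattice
agent-based tumor model, and a secrete-and-sense lateral-inhibition
patterning model — all exercised on a seeded synthetic-data generator, so
that every statistic and every qualitative model prediction is testable
without any external data.

```{r setup}
library(coopcell)
library(dplyr)
```

## The saturating benefit

All four pieces share one functional assumption: the survival benefit that
non-producers draw from the secreted public good is *saturating* in the
producer frequency $x$. We fix it as a Hill curve,

$$V(x) = B\,\frac{x^h}{k^h + x^h},$$

with maximal benefit $B \in [0,1]$, half-saturation $k$, and shape $h$.
For $h \le 1$ the curve is concave on $[0,1]$ (checked numerically at
construction). The defaults $k = 0.05$, $h = 1$ put the steepest gains at
producer fractions of a few percent, so the benefit is near-maximal by the
time producers reach ~30% of the population — the regime in which a small
altruist minority can already protect the bulk of the population. The
benefit is *others-only*: producers are insensitive to their own secreted
product (in the biological circuit, the miR-125b-high state suppresses
GAB1 and with it the receiving arm of the pathway), which is what makes
the behaviour genuinely altruistic rather than mutually beneficial.

## The synthetic co-culture generator

`simulate_coculture()` emulates the tagged 1:1 co-culture design: a
*homogeneous* mixture (tagged control cells + untagged control cells) and
a *heterogeneous* mixture (control cells + altruist-mimicking cells, with
reciprocal tagging available), drug-treated, counted four days later, then
regrown to confluency. Survival probabilities are

* producers: $\sigma_0(D) + (1 - \sigma_0(D))\,s_A$,
* defectors: $\sigma_0(D) + (1 - \sigma_0(D))\,V(x)$,

where $x$ is the altruist fraction of the well, $\sigma_0(D) =
2^{-D/D_{1/2}}$ is the baseline survival at dose $D$ (half-kill dose
`dose_half = 0.9` nM, giving ~0.21 at the 2 nM assay dose and near-zero at
20 nM), and $s_A$ is the fraction of the drug kill that producers evade
through intrinsic tolerance. Writing the producer term this way (rather
than as a bare constant) makes the no-drug limit exact — at $D = 0$
everyone survives — and makes the symmetric null (`truth_null()`: $B = 0$,
$c = 0$, $s_A = 0$) give *identical* survival for both fractions at every
dose, which is what anchors relative survival and relative fitness at 1.

Regrowth compounds the producers' per-division cost $c$: defector lineages
double per round while producer lineages grow by $2^{1-c}$, and the
continuous round count is solved (by `uniroot`, tolerance $10^{-12}$) so
the well lands exactly on its confluency target (default $10^5$ cells,
i.e. ten times the seeded 10,000). A single proportional allocation round
would understate the cost — the competitive disadvantage accumulates over
every division of the expansion — and would not reproduce the observed
dominance of control-derived progeny in the regrown heterogeneous
population.

Measurement noise is multiplicative log-normal with a stated CV (default
5%), applied independently to every reported count: counts are positive
and cytometer/viability noise is roughly proportional to signal. With
`noise_cv = 0` every run is exactly reproducible and exactly equal to the
closed-form expectations, which is how the generator is tested.

What the generator does *not* emulate: docetaxel pharmacokinetics (the
dose acts as a single effective exposure), cell-cycle structure,
intermediate growth kinetics between the two timepoints, and
transcriptional state. Passing tests therefore show that the statistics
recover the generative social structure — not that they would be robust
to, say, density-dependent growth in real wells.

## Relative survival and relative fitness

`relative_survival()` and `relative_fitness()` implement the two
co-culture statistics. In both, the tagged:untagged ratio of the
homogeneous well is normalized to 1:1 and the *same* factor is applied to
the matched heterogeneous well, cancelling tag-specific artefacts.
RS$_\alpha$ then compares control-cell survivors beside altruists with
control-cell survivors beside controls (RS$_\alpha > 1$: the partners were
protected); RF$_\alpha$ compares control-derived with altruist-derived
progeny in the regrown heterogeneous population (RF$_\alpha > 1$: the
altruists paid a fitness cost). Both are invariant to which fraction
carries the tag and to rescaling all counts of a treatment group.

RS$_\beta$ — the altruist-side mirror — is referenced against the same
channel of the homogeneous well, because the experimental design contains
no altruist-only homogeneous well. **This reference is a convention of
this package**; treat RS$_\beta$ as "altruist survival relative to the
control baseline", not as a second independently normalized quantity.

`classify_social_behavior()` maps the pair onto the Hamilton-style matrix
(recipient effect from RS$_\alpha$, actor effect from RF$_\alpha$):
cost to actor + benefit to recipient = altruism, benefit/benefit = mutual
benefit, benefit/cost = selfishness, cost/cost = spite. Ratios within a
tolerance band of 1 (default 0.05) are neutral; with replicate values a
one-sample t-test against 1 at $\alpha = 0.05$ can replace the fixed band.
A zero altruist-derived count yields an `Inf` sentinel with a warning
rather than an error, because high doses legitimately extinguish a
fraction.

## Benefit titration: percentage and marginal benefit

For the altruist-titration assay (altruists at 0, 1, 10, 30, 50% of the
well), `percentage_benefit()` rescales viability readouts between the 0%
and 50% anchors, so $PB(0) = 0$ and $PB(50) = 100$ identically, and
`marginal_benefit()` applies

$$MB = \frac{PB(y) - PB(x)}{(y - x) + 1}$$

between consecutive studied percentages, reported at the category value
$(x+y)/2$. The $+1$ in the denominator is part of the assay's definition
and is kept verbatim. `fit_benefit_curve()` fits degree-1 and degree-2
polynomials by ordinary least squares and selects between them with the
nested-model F-test at $\alpha = 0.05$; the original analysis named the
comparison but not the criterion, and the F-test is the standard choice
for nested OLS models. A preferred quadratic with negative curvature is
the operational signature of saturation. For realistic degrees of freedom,
`percentage_benefit(per_replicate = TRUE)` computes one curve per
replicate against that replicate's own anchors (a 5-point design fitted on
means alone leaves the F-test with two residual degrees of freedom and
essentially no power).

The linear-mixing expectation used by `expected_mixture_viability()` — a
mixture's null viability is the fraction-weighted mean of the pure
cultures — is applied to both the no-drug and the drug case; the
functional form of the drug-case null was not specified beyond the
comparison itself, and linear mixing is the natural additive null in both.
An observed mixture significantly *above* that expectation under drug is
the population-level fingerprint of cooperative protection.

## The well-mixed public-goods game

`public_goods_game()` fixes the two strategy fitnesses as

$$W_A = s_A(\tau)\,(1 - c), \qquad
  W_D(x) = \sigma_0(\tau) + (1 - \sigma_0(\tau))\,V(x),$$

with therapy intensity $\tau$ entering through the default response curves
$\sigma_0(\tau) = 1 - 0.9\tau$ (defectors are drug-sensitive) and
$s_A(\tau) = 1 - 0.05\tau$ (producers are relatively tolerant). This
explicit parameterization is the package's own construction, chosen to be
consistent with the qualitative structure of the modelled system:
frequency-dependent defector fitness, concave benefit, constant producer
fitness with a cost. At $\tau = 0$, $W_A = 1 - c < 1 = W_D$: costly
producers always lose without drug. Under therapy, concavity gives a
unique interior crossing $W_A = W_D(x^*)$ that is stable (producers invade
when rare, defectors when common) and — with the defaults — a *minority*
equilibrium, $x^* = 0.22$ at $\tau = 1$.

`find_equilibria()` brackets sign changes of the gain function
$G = W_A - W_D$ on a $10^4$-point grid and bisects to $10^{-10}$;
stability comes from the sign pattern of $G$ around each root, and
boundary stability from $G(0)$ and $G(1)$. `integrate_replicator()` uses a
fixed-step classical Runge–Kutta scheme on $\dot x = x(1-x)G(x)$ (default
$dt = 0.1$); both boundaries are exact fixed points of the map.
`therapy_sweep()` validates its monotonicity preconditions ($\sigma_0$
strictly decreasing, $s_A$ declining no faster) and returns the stable
equilibrium per $\tau$; under those preconditions the curve is
nondecreasing — more therapy, more cooperation. A group-sampled variant
($n < \infty$) replaces $V(x)$ with $E[V(j/(n-1))]$, $j \sim
\text{Binomial}(n-1, x)$, and converges to the mean-field game as $n$
grows (slowest near the sharp-curvature corner $x \approx k$).

## The lattice tumor model

`run_spatial()` advances an $L \times L$ torus (default 50, periodic
boundaries) of producers, defectors and empty sites. Per step: producers
secrete one unit of good at their site; the field diffuses by convolution
with a normalized kernel (contact kernel over the site and its four
neighbours at `d = 1`; truncated Gaussian for `d > 1`) and decays by a
fraction $\lambda = 0.15$; each cell survives with a type- and
benefit-dependent probability scaled by `death_scale`; empty sites are
filled by a fitness-weighted draw among occupied von Neumann neighbours
with producers down-weighted by $1 - c$. The death-birth order with a
synchronous diffusion substep avoids update-order artefacts dominating the
outcome while keeping the field physical (mass is conserved exactly under
$\lambda = 0$ and periodic boundaries).

The per-step survival defaults ($\sigma_0 = 0.3$, $s_A = 0.8$, $B = 0.9$,
$k_\text{field} = 0.3$, $c = 0.5$, `death_scale` 0.4) are chosen once to
put the lattice in the regime the spatial argument is about: the good
saturates near producer clusters, so *fully protected defectors match or
slightly exceed producer survival locally*, and the producers' growth cost
— not raw drug kill — decides the competition. These are per-step hazards
on the chronic timescale of the lattice, not the per-assay survival
fractions of the co-culture generator; the two parameterizations describe
the same biology at different time resolutions. The growth cost is set
high (0.5 per division) to reflect the strong cell-cycle impediment of the
altruistic state.

With *genetic* inheritance (offspring copy the parent), producers are
eliminated: their benefit accrues to adjacent defectors, which locally
out-reproduce them — on 50×50 grids the mean producer fraction after 1000
steps is below 0.01 across seeds. Removing the cost ($c = 0$) removes the
extinction, confirming that cost, not space alone, drives it. With
*epigenetic* inheritance, new and existing cells re-evaluate their fate
from the local good: a cell becomes (or switches to) producer with
probability $\pi(g) = 1/(1 + (g/\theta)^{m})$ — preferentially where the
good is scarce, a best-response rule — with a slow per-step
interconversion rate (0.02) for established cells. This regenerates the
producer minority wherever it is depleted: the long-run producer fraction
settles near 0.3 regardless of whether the run starts from 0%, 50% or
100% producers, mirroring the re-equilibration of FACS-sorted
reporter-high and reporter-low fractions. The acceptance conventions used
in the tests (< 0.01 for extinction, ±0.05 agreement between
re-equilibration bands) are module conventions, not measured quantities.

## Lateral inhibition and social-fate patterning

`simulate_pattern()` iterates a Collier-style discrete-time relaxation on
an $L \times L$ torus: each cell's inhibitory input is the kernel-weighted
secretion of *other* cells (self-weight zero — the secreting cell is
insensitive to its own product), and its promoter activity relaxes toward
$f(s) = 1/(1+(s/\theta)^m)$ at rate $r = 0.2$ per step, from initial
activity $0.5 \pm 0.05$. The binary social fate is $a > 0.5$. A
deterministic relaxation was chosen over a PDE solver because the
modelled patterns are lattice snapshots of discrete cells, and determinism
makes every pattern reproducible from its seed.

The signalling range `d` is interpreted as an interaction radius in cell
diameters: `d = 1` is the juxtacrine contact case (4-neighbour kernel, as
in Notch–Delta signalling), and `d > 1` uses a uniform disc kernel of
radius `d`. The disc (rather than a Gaussian) is deliberate: pattern
formation requires the uniform state to be unstable, and a broad Gaussian
kernel has essentially no negative Fourier components, so it relaxes to a
featureless state instead of a spot pattern. The defaults
$\theta = 0.01$, $m = 12$ make a single secreting cell sufficient to
suppress every cell within its range; the result at `d = 1` is the
salt-and-pepper alternation of contact-range lateral inhibition (negative
lag-1 join-count autocorrelation, high-fate fraction near 0.4), and at
`d = 5` a sparse scatter of singleton altruists spaced roughly `d` apart
(high-fate fraction ~0.03, mean nearest-neighbour distance ~6). The fate
threshold at $a = 0.5$ is the symmetric Hill midpoint and is exposed in
the statistics rather than hard-coded into the dynamics.

`antibody_scenario()` models neutralizing antibodies that cannot access
the tight cell–cell interface: the effective kernel of a long-range run is
truncated to the contact kernel, which restores the salt-and-pepper
signature and raises the high-fate fraction — the same reversal seen when
the secreted factors are neutralized experimentally.

`pattern_stats()` quantifies a pattern by its high-fate fraction, the
Pearson correlation of fate indicators over all 4-neighbour pairs
(periodic wrap; $-1$ on a perfect checkerboard, ~0 for i.i.d. fates), and
the mean toroidal nearest-neighbour distance among high-fate cells
($\sqrt 2$ on a checkerboard). Degenerate inputs (uniform fates, fewer
than two high cells) yield `NA` sentinels rather than errors.

## Numerical and design choices, in brief

* Root finding: grid bracketing ($10^4$ points) + bisection ($10^{-10}$);
  the $10^6$-point scan is kept as an independent oracle in the tests.
* Replicator integration: fixed-step RK4, clipped to $[0,1]$; boundary
  states are exact fixed points.
* Noise: multiplicative log-normal, mean exactly 1 at every CV.
* Ties and degenerate inputs: typed conditions
  (`coopcell_error_param`, `coopcell_error_degenerate`,
  `coopcell_error_pairing`) rather than generic errors; infinite relative
  fitness is a sentinel, not an exception.
* Problem sizes: the test-suite and acceptance runs use 50×50 lattices,
  1000 steps and 5–10 seeds for the spatial model; 100 seeds for the
  end-to-end recovery checks; 50 seeds for the benefit-shape selection;
  these sizes give stable statistics for every property checked while
  keeping a full run in the minutes range on one core.
* The command-line front end (`coop_cli()`, `inst/cli/coopcell`) writes a
  manifest (config hash, seed, package version) beside every artifact;
  identical config + seed reruns are byte-identical.

## Known limitations

* RS$_\beta$ rests on the package's own reference convention (above).
* The game's payoff coefficients are a consistent construction, not fitted
  values; conclusions should be read qualitatively (existence, stability
  and minority position of the equilibrium; monotone therapy response),
  not as calibrated frequencies.
* The lattice and patterning models share a torus geometry and ignore
  mechanics, adhesion and 3-D structure.
* The generator's two-timepoint design cannot inform kinetics between
  treatment and confluency.
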
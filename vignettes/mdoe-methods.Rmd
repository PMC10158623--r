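---
title: "Model-assisted design of microcarrier expansion cultures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-assisted design of microcarrier expansion cultures: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdoecarrier)
```

## The problem

Adherent cell lines used for viral vaccines, gene therapy and cell
therapeutics must be expanded on a growth surface. In stirred or shaken
vessels that surface is supplied by microcarriers (MC), small beads whose
concentration `c_MC` (g/L) sets the total attachable area per volume.
Developing such a process from scratch is expensive: every candidate
combination of carrier concentration and medium composition is a multi-week
shake-flask culture. Model-assisted Design of Experiments (mDoE) replaces
most of that screening with simulation: a kinetic model is calibrated on a
handful of cultures, its parameter uncertainty is quantified, and candidate
experimental designs are then *evaluated in silico* before anything is
pipetted. This package implements that loop end to end, together with a
synthetic data generator so the whole chain is testable without laboratory
data.

## The kinetic model

Eight states are integrated over batch time: total cells `X_t`, attached
viable cells `X_V`, suspension cells `X_Sus` (all cells/mL), glucose,
glutamine, lactate, ammonia (mmol/L), and an *unobserved limiting substrate*
`c_LS` (arbitrary units). The limiting substrate lumps everything that
actually stops growth in serum-containing medium (e.g. serum factors) when
glucose and glutamine demonstrably do not; its initial value is normalized
to 1 per 100% fresh medium, and its kinetic constants are expressed on that
scale.

Growth is Monod in `c_LS` and proportional to the free-space fraction on
the carriers:

$$\mu = \mu_{max}\,\frac{c_{LS}}{c_{LS}+K_{S,LS}}\cdot
  \frac{X_{V,max}-X_V}{X_{V,max}},$$

with carrying capacity
$X_{V,max} = c_{MC}\cdot a\cdot \rho_{max}$ (carrier area per gram $a$,
maximum areal density $\rho_{max}$, converted to cells/mL). Death is
$\mu_d = \mu_{d,min} + \mu_{d,max}\,c_{LS}/(c_{LS}+K_{d,LS})$; suspension
cells attach to free surface at rate `k_att` during an initial attachment
window (`t < t_att`, default 20 h) and not at all afterwards. Glucose and
glutamine uptake are growth-coupled (`mu`/yield, with their own saturation
terms and a second free-space factor), limiting-substrate uptake is plain
Monod, and lactate/ammonia production are strictly proportional to glucose/
glutamine uptake. Two exact consequences are used as test oracles:
`c_Lac(t) - c_Lac(0) = Y_Lac_Glc (c_Glc(0) - c_Glc(t))` at every time, and
pure exponential growth `X_V(0) e^{(\mu-\mu_d)t}` in the unlimited regime.

Three printed-form quirks are implemented deliberately and are worth
knowing about:

* **Death-rate orientation.** As written, the death rate *rises* with the
  limiting substrate and falls to `mu_d_min` when it is depleted. That is
  biologically unusual (one would expect death to rise as the medium is
  exhausted), so `death_mode = "inverse"` provides the inverse-Monod form;
  the default keeps the printed orientation.
* **Doubled space factor.** The uptake rates of glucose and glutamine carry
  the free-space factor although `mu` already contains it, so the factor
  enters those rates twice. It is kept exactly as printed.
* **Lysis of non-attached cells.** `K_Lys` acts on `X_t - X_V`, which early
  in the culture is mostly the still-unattached inoculum, not debris. In
  the default parameter region growth outweighs this and `X_t >= X_V`
  holds along all simulated trajectories (asserted in the tests), but very
  large `K_Lys` with slow attachment can violate it.

### Numerics

The right-hand side is smooth except for the `k_att` switch at `t_att`, so
integration uses an adaptive Dormand-Prince 5(4) scheme (implemented in
C++ in this package, since no ODE solver is available in the target
environment) with the integration *segmented* at `t_att`; the
discontinuity is never inside a step, so no event handling and no order
loss. Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; calibration
and design evaluation relax to `1e-6`/`1e-8`, which changes the target
metric by far less than the Monte-Carlo noise. Concentrations are clamped
at zero inside rate laws, and the free-space fraction to `[0, 1]`, which
keeps trajectories non-negative and `X_V <= X_V,max` without projection
steps.

## Calibration

All experiments are fitted simultaneously by weighted least squares:
residuals are divided by `rel_error * mean(|obs|)` per observable per
experiment, so cell counts (~1e5-1e6) and metabolites (~1-60) contribute
comparably — the weighting follows the measurement model (multiplicative
error) rather than the units. Optimization is in log-parameter space
(positivity by construction) under box bounds (`init/50`, `init*50` by
default) with `nlminb` and multi-start. The default free set is
`mu_max, K_S_LS, mu_d_min, q_LS_max, Y_X_Glc, Y_X_Gln, Y_Lac_Glc,
Y_Amm_Gln`; the glucose/glutamine half-saturations, attachment and lysis
constants and the death-curve shape are weakly identifiable from a batch
grid whose substrates never limit growth, and are held at their initial
values unless explicitly freed. The limiting substrate is unobservable: its
initial value is fixed at 1 by normalization and only its kinetic constants
are estimated.

Parameter uncertainty is quantified by *perturb-and-refit* Monte Carlo:
each replicate multiplies every observation by independent
`Normal(1, 0.15)` factors (truncated at zero) and refits from the point
estimate. The reference workflow uses 1000 replicates at 15% error; that is
the function default, and desk-scale runs (tests, the acceptance script)
use 20-100 and say so. A direct parameter-jitter mode exists for cheap
smoke tests; it does not reflect the model's sensitivity structure and is
never the default. Replicate fits that fail are dropped and counted;
more than 20% failures aborts the distribution.

## Experimental designs

Six generators over a bounded factor space (defaults: glucose 5-60 mmol/L,
glutamine 2-12 mmol/L, carriers 1-20 g/L): central composite (2^k cube +
axial + centres), Box-Behnken (edge midpoints + centres), Latin hypercube,
D-optimal, I-optimal, and an LHS-seeded D-optimal. The classical presets
that reproduce the reference run counts are CCD with 6 centre points (20
runs) and BBD with 12 centre points (24 runs); the optimal designs default
to 16 runs. The rotatable CCD axial distance `(2^k)^{1/4}` leaves the
coded cube, and axial points are clipped to the bounds by default because
carrier concentrations below 1 g/L are outside the stated space
(face-centred behaviour at the boundary).

The optimal designs use first-improvement Fedorov exchange over a finite
candidate set (default: 5-level full factorial, 125 candidates for k = 3)
on the full quadratic model (10 columns for 3 factors), maximizing
`log det(X'X)` (D) or minimizing the average prediction variance
`tr((X'X)^{-1} W)` over a quadrature grid (I). Exchange scans candidates
in fixed order and accepts the first improvement, so results are exactly
reproducible under a seed; the accepted-criterion path is stored and is
monotone by construction. On tiny instances the exchange is tested against
exhaustive enumeration of all candidate multisets.

## Design evaluation and recommendation

Every design row defines a culture setup (factors override `c_Glc`,
`c_Gln`, `c_MC` of a template). Each row is simulated `n_sim` times with
parameter vectors drawn with replacement from the Monte-Carlo
distribution — the distribution is reused, not refitted per draw — and the
target metric recorded: the maximum of attached viable cells per cm^2 of
carrier surface (per-mL by switch). Per point the mean, the 10% and 90%
quantiles and their difference (the spread) are kept.

Desirability is Derringer-Suich style: a larger-is-better ramp between
anchors `L` and `T` for the mean, a smaller-is-better ramp between `S_max`
and 0 for the variability, combined as a geometric mean. Anchors
self-scale to the 5th/95th percentiles of the evaluated outcomes (pooled
across designs when designs are compared, so their scores are
commensurable). **The variability entering the ramp is the relative spread
(spread/mean) by default.** This is a deliberate design choice: the target
metric spans roughly an order of magnitude over `c_MC` in 1-20 g/L and its
Monte-Carlo spread scales with its mean, so a self-scaled *absolute*
penalty would assign near-zero desirability precisely to the
highest-yield points and the scalarization would fight its own target.
Relative spread penalizes genuinely noisy predictions without that
artifact; `spread_type = "absolute"` restores the raw `q90 - q10`.

A full quadratic response surface is then fitted to desirability in coded
units by ordinary least squares (rank deficiency is an error, not a
warning), predictions are clipped to `[0, 1]`, and the optimum is located
by dense grid search (50 points per factor by default) — robust on
clipped, flat or boundary-optimal surfaces where gradient methods would
need safeguarding, and trivially reproducible. Recommendations report each
design's surface argmax, ranked.

## The synthetic world

The generator simulates the eight-culture grid (six modelling experiments
at `c_MC` = 20, 20, 10, 10, 10, 5 g/L with varying substrate levels; two
held-out verification cultures at 3 and 1 g/L), samples every 24 h up to
120 h and every 48 h thereafter, and applies independent multiplicative
`Normal(1, 0.15)` noise (truncated at zero) to every observation. The
limiting substrate is never emitted. The ground-truth parameter set is a
documented fixture, chosen once so that the simulated world reproduces the
qualitative biology the analysis assumes: exponential-phase growth around
0.02-0.03 1/h, peak attached-cell densities between ~100 and ~310 h
(later at lower `c_MC`), growth terminated by limiting-substrate depletion
while glucose and glutamine remain measurable, multiplication factor ~8 at
10 g/L, and a per-area yield that decreases monotonically in `c_MC` with
the 1 g/L culture approaching the areal capacity of the carrier. It makes
no claim to be the (unpublished) fitted parameter set of any real L929
culture, and quantitative agreement with any published growth curve is out
of scope by construction.

What a green test therefore establishes: the estimator recovers the
parameters of the data-generating model (1% noise-free, 25% at 15% noise
for the identifiable subset); uncertainty propagates monotonically; the
design generators are correct against closed-form counts and brute-force
enumeration; and the full loop applied to this world recommends the
low-carrier boundary — the structural result that lower `c_MC`
concentrates the volumetric cell yield onto less area. What it does not
establish: anything about assay biases, carrier-type differences, the
lactate metabolic shift (deliberately not modelled), or fed-batch/transfer
operation.

## Known limitations

* The printed death-rate orientation makes the death phase *slowest* right
  after substrate depletion; use `death_mode = "inverse"` to explore the
  conventional behaviour.
* With all substrates in excess the glucose/glutamine half-saturations,
  `k_att_max`, `K_Lys` and the death-curve shape are practically
  unidentifiable; freeing them inflates the Monte-Carlo spread without
  improving fit.
* Degenerate setups (`c_MC = 0`) are valid simulation inputs (nothing
  grows) but are rejected by per-area metrics and the growth-rate law,
  which report the degeneracy explicitly.
* The exchange algorithms optimize over a finite candidate grid; a finer
  grid improves the criterion at linear cost in candidates.
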
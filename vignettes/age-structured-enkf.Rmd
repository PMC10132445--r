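---
title: "Age-structured overdose mortality modelling with an ensemble Kalman filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured overdose mortality modelling with an ensemble Kalman filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`agemort` models a population with substance use disorder (SUD) as a density
$n(a,t)$ over age $a$ and time $t$ (persons per year of age), transported
along the aging direction with a mortality sink and an influx source:

$$\left[\partial_a + \partial_t\right] n(a,t) = -\mu(a,t)\,n(a,t) + p(a,t),$$

with initial density $n(a,t_0)=\rho(a)$ and a zero boundary at age 0 (no
newborns carry an addiction). Along characteristics $a - t = \text{const}$
the equation becomes an ODE, which yields a closed-form solution in two
branches: characteristics older than the simulation (they start on the
initial-time axis, $a \ge t - t_0$) carry the decayed initial condition plus
accumulated influx; younger characteristics start at age 0 with zero density
and carry accumulated influx only. `characteristic_solution()` evaluates
these branches by nested adaptive quadrature for arbitrary coefficient
functions and serves as the oracle against which all closed-form evaluators
are tested.

Two specializations are built in.

**Toy model** (`toy_density()` and friends): constant mortality $\mu$,
influx $p(a) = a e^{-\lambda a}$, $\rho \equiv 0$. The solution is fully
closed-form; its time derivative $(a-t)e^{-\lambda(a-t)-\mu t}$ (zero for
$a<t$, where the profile is already stationary) is what the filter
integrates. The age of the density maximum moves along
`peak_trajectory()`, with small-$t$ limit $1/\lambda$, the age at which the
influx peaks.

**SUD model** (`sud_density()`, `sud_rate_of_change()`): people enter the
SUD pool at an age-dependent addiction rate $r(a)$ applied to the non-SUD
population, and die of overdose at constant rate $\mu$. Substituting
$\mu \to \mu + r(a)$ and $p \to r(a)N(t)$ maps it onto the general model.
The influx shape is a two-component gamma mixture
$r(a) = \tfrac{r_0}{2}\left[f_1(a;\alpha_1,\beta_1)+f_2(a;\alpha_2,\beta_2)\right]$
— two peaks capture the double-humped age profile of overdose deaths, and
$r_0$ (the integral of $r$ over all ages) is the base addiction rate. The
total population is linear, $N(\text{year}) = N_0 + \Delta N\,(\text{year}-2000)$
with $N_0 = 274.9\times 10^6$ and $\Delta N = 2.3\times 10^6$/yr, a fit to
the quasi-linear US population growth anchored at calendar year 2000 and
extrapolated linearly back to the 1998 simulation start (the anchor year is
a modelling choice; the growth is so slow that anchoring at 1998 instead
changes $N$ by under 2%). Cumulative overdose deaths per year of age,
$\tilde D(a_j,t) = \int_0^t \mu\, n(a_j,t')\,dt'$, are accumulated alongside
the density and are what the data constrain.

Because the model is linear with state-independent coefficients, the time
derivative of the closed-form solution depends only on $(a, t)$ and the
parameters, not on the current density. The filter exploits this: each
ensemble member integrates the closed-form rate at its *own* parameter
values, with no age-derivative discretization. For whole-grid evaluation the
per-member survival integrals are computed as running trapezoid sums on the
age grid (`sud_filter_model()`), accurate to $O(\Delta a^2)$; the pointwise
evaluators use adaptive quadrature with closed-form gamma CDFs inside the
exponent and are the reference implementation.

## The ensemble Kalman filter

`run_enkf()` implements the perturbed-observation EnKF with state
augmentation. The state stacks the density block, (for the SUD pipeline)
the cumulative-death block, and the unknown parameters stored as
logarithms, so Gaussian updates always back-transform to positive rates.
One cycle is:

1. **Forecast**: one explicit-Euler step per member using the member's own
   untransformed parameters, plus a process-noise draw. Parameters have no
   deterministic drift — they evolve only through noise and updates.
2. **Update** (on the observation schedule): predicted observations
   $h(\chi_i)$, innovation covariance $P_{zz}$ (sample covariance plus $R$,
   with the $M-1$ denominator), cross covariance $P_{xz}$, gain
   $K = P_{xz}P_{zz}^{-1}$ (solved, not inverted), and a perturbed
   observation per member. The reported posterior covariance is
   $P^- - K P_{zz} K^\top$.

Explicit Euler is retained deliberately: the forecast map is then exactly
the linear-Gaussian discrete system the update assumes, and the scalar
linear-Gaussian test can compare against the textbook Kalman recursion with
no discretization slack. The cost is $O(\Delta t)$ bias in the physical
trajectories; at $\Delta t = 0.1$ yr this is about 1% of the toy density
(and is shared by truth-generating and filtering runs in twin tests only
for the SUD generator, which instead integrates the closed form).

### Process-noise structure

The reference configuration sets the process covariance magnitude to
$10^{-4}$ and the observation covariance to $R = \operatorname{diag}(10^{-4})$.
Two structures are available via `process_noise()`: independent entries
(`"diag"`, the default) and a fully correlated rank-one covariance
$10^{-4}J$ with $J$ the all-ones matrix (`"ones"`), realized as a single
scalar draw per member added to every state entry. The rank-one variant has
a structural defect for joint parameter estimation: it perturbs both
log-parameters by the same amount, so the ensemble never regenerates spread
in the *difference* of the parameters, and — because the same scalar also
enters the observed density block — the update can see and cancel the one
direction it does explore. In practice the toy twin then stalls a few tens
of percent from the truth. With independent noise of the same variance the
twin recovers both rates to a few percent, which is why `"diag"` is the
default; the choice is a config switch, not a constant.

### Initialization scales

The initial state of the toy twin is $10^{-5}$ in every density cell with
prior variance 0.5, and initial parameter guesses of $0.1$/yr. Parameter
entries live on the log scale, so the guesses are stored as
$\log 0.1 \approx -2.3$ and the prior parameter variance 1 is a broad
log-normal prior (roughly a factor-$e$ spread). Reading the printed $0.1$
as the log-state value directly (initial natural guess $e^{0.1}\approx 1.1$/yr)
was also tested and converges equally well; the natural-scale reading is
the default because it keeps the guess interpretable as a rate.

## Observation pipelines

**Toy twin** (`run_toy_twin()`): the truth density is evaluated on the grid
at $\mu = 0.08$/yr, $\lambda = 0.2$/yr; i.i.d. $N(0, 10^{-4})$ noise is
added; every age cell is observed every 5 forecast steps (0.5 yr). Problem
sizes: 1000 age cells on $[0,120]$ yr, $\Delta t = 0.1$ yr to $t = 10$ yr,
$M = 500$ members — about 6 s per run.

**SUD assimilation** (`run_sud_assimilation()`): observations are the 22
CDC WONDER age bins (widths 1, 4, nineteen 5-yr bins, and 20 yr for 100+).
The measurement operator integrates the cumulative-death block over each
bin (piecewise-linear in age, with cells split across bin edges apportioned
linearly so the bins sum exactly to the total) and divides by $10^3$ to
work with $O(1)$ numbers; $R = \operatorname{diag}(10^{-4})$ on that scale
corresponds to a standard deviation of 10 deaths per bin. Annual counts are
assimilated as running (cumulative) sums at the beginning of the following
year — assimilating annual increments with the previous observed cumulative
subtracted is algebraically the same update, so cumulative totals are the
single implementation, and annual figures are reported as year-over-year
differences of predictions (`annual_predictions()`, `forecast_annual()`).

**Synthetic WONDER data** (`generate_cdc_like_counts()`): the generator
integrates the closed-form SUD solution (not the filter's Euler path),
coarse-grains yearly, differences to annual counts, adds Gaussian noise
with standard deviation 10 deaths (the low end of the 10–100 range the
measurement model assumes) and rounds to non-negative integers. Its default
parameters are the reference SUD configuration: $\mu = 7\times10^{-4}$/yr,
$r_0 = 0.04$/yr, both gamma components with shape 15 and rate $1/3$ (mean
age 45 yr). What it emulates: bin structure, magnitudes (tens of thousands
of deaths per year), suppressed-cell dialect via `write_wonder()`. What it
does not: integer overdispersion, reporting delays, ICD-code revisions,
age-dependent baseline mortality, and any non-stationarity of $r(a)$ —
passing twin tests therefore demonstrates internal consistency of model +
filter + pipeline, not fidelity of the model to real overdose data.

### The SUD twin and identifiability

The SUD twin test generates 20 years of synthetic bins at the reference
parameters and starts the filter from the same reference values (a
self-consistency twin): the filter must track the known truth through 20
yearly updates without corrupting it, with $M = 2000$ members (a
sampling-error compromise; the real-data default is $10^4$). A twin started
far from the truth would not be informative for $\mu$ and $r_0$ separately:
to leading order the death counts constrain only the product $\mu r_0$
(deaths $\approx \mu \cdot r_0 \cdot$ population $\cdot$ shape), with the
split resolved only by $O(\mu a, r_0)$ nonlinearities — a genuine
limitation of death-count-only assimilation. The gamma *means*, by
contrast, are identified by the age profile, and a separate test confirms
they are pulled back from a deliberately mis-specified initial guess.

## Numerical choices

- Degenerate influx/mortality rates: the closed forms divide by
  $(\lambda-\mu)^2$; below $|\lambda-\mu| = 10^{-6}$/yr a second-order
  series in $(\lambda-\mu)$ is evaluated instead. The filter explores
  parameter space and can hit near-degenerate members, so this is a
  correctness requirement, not polish.
- Quadrature: `stats::integrate` (adaptive Gauss–Kronrod) with abs/rel
  tolerance $10^{-10}$ by default, exposed as arguments; non-convergence is
  an error naming the offending $(a,t)$.
- Grid convention: ages are cell left edges, values are point evaluations
  of the density. The last cell ($[119.88, 120]$ on the default grid) is
  integrated with constant extrapolation.
- Death accumulation: rectangle rule $\tilde D \mathrel{+}= \Delta t\,\mu\,
  \max(n,0)$; clipping guards against transiently negative densities under
  filter noise.
- Ties and degenerate inputs: $t = 0$ returns the (zero) initial condition
  everywhere; $r_0 = 0$ gives identically zero density and deaths; gamma
  shapes below 1 would make $r(0)$ infinite, so the age-0 cell of the
  influx is pinned to zero (consistent with the zero boundary).
- RNG: each runner seeds R's generator once; initialization, observation
  noise, process noise and update perturbations draw from that single
  stream in a fixed order, so a seed reproduces a run bit for bit.

## Known limitations

- Age-independent $\mu$ and $N$; no cohort structure in the population
  model, no drug-class stratification.
- Weak $\mu$–$r_0$ identifiability from death counts alone (above).
- The Gaussian observation model is kept even though real counts are
  integers and censored below 10 ("Suppressed" cells are masked on input
  and contribute zero to cumulative counts, slightly biasing affected bins
  downward).
- No inflation or localization; with $M = 500$ members and 1000 observed
  cells the toy update is rank-deficient and relies on the process noise to
  regenerate spread.
- Pure forward filtering; no smoothing passes, so early-time parameter
  trajectories are not revised in the light of later data.
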
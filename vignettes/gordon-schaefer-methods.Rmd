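---
title: "Methods: surplus-production bioeconomics in gordonschaefer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surplus-production bioeconomics in gordonschaefer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gordonschaefer)
```

## The model and its assumptions

The package implements the Gordon-Schaefer bioeconomic model of a single
fish stock. Biomass $x$ (tonnes) grows logistically with intrinsic rate $r$
(1/yr) toward a carrying capacity $K$ (tonnes), and is harvested in
proportion to fishing effort $E$ (boats) through a catchability
coefficient $q$ (1/boat-year):

$$\frac{dx}{dt} = rx\left(1 - \frac{x}{K}\right) - qEx.$$

The assumptions this buys, and their price, are the classical ones:

* **No age structure.** Surplus production aggregates recruitment, growth
  and natural mortality into one curve; it cannot represent recruitment
  lags or size-selective gear.
* **Proportional catchability.** CPUE ($H/E$, tonnes/boat) is assumed an
  unbiased index of biomass, $CPUE = qx$. Effort creep, hyperstability of
  schooling species (a real concern for sardine and mackerel) and
  technology trends violate this silently.
* **Equilibrium economics.** Price $p$ (OMR/t) and unit effort cost $c$
  (OMR/boat-year) are constants; rent is evaluated on the sustainable-yield
  parabola, not along transient paths.

Because annual ministry statistics are annual, the continuous dynamics are
discretised as the standard annual difference equation

$$B_{t+1} = B_t + rB_t(1 - B_t/K) - C_t,$$

which is also the recursion the estimator uses, so simulation and fitting
are exactly consistent with each other. `step_biomass()` floors the stock
at $10^{-6}K$ and flags the state `collapsed` instead of letting it go
negative: the log-normal likelihood needs a strictly positive predicted
catch, and a clamped-and-flagged collapse is more informative than an
arithmetic failure.

## Estimation

`fit_dynamic_schaefer()` estimates $(K, q, r)$ by minimising the
log-normal observation-error sum of squares

$$\sum_t \left[\ln C_t - \ln(qE_t\hat B_t)\right]^2,
\qquad \hat B_1 = IP\cdot K,$$

where $IP$ is the *initial proportion*, first-year catch over maximum
catch (`compute_ip()`). Two points deserve emphasis:

* **The IP convention.** The initial-depletion slot of the recursion is
  $B_1/K$, a biomass ratio, while IP is a catch ratio. The package follows
  the established assessment workflow for these stocks and passes IP into
  that slot unchanged. The two ratios coincide only under special
  conditions; both interpretations are exposed (the `ip` argument is free),
  and the discrepancy is documented rather than resolved.
* **Conditioning.** By default the recursion is depleted with the
  *model-predicted* catch — the pure observation-error estimator implied by
  the log-normal error model. `conditioning = "observed"` switches to
  depletion by recorded catch for sensitivity analysis; on noise-free data
  the two agree.

**Optimiser.** The loss is smooth but can be flat along ridges (high $K$,
low $q$ trade-offs), so the package uses a seeded multi-start
(default 20) Nelder-Mead search. Parameters live in a log-spaced box —
$K \in [\max C, 100\max C]$, $q \in [10^{-8}, 10^{-2}]$,
$r \in [0.01, 2]$ — mapped to an unconstrained scale by a scaled logistic
transform, so no start can escape the box and no penalty terms distort the
surface. The best start is polished by a restarted Nelder-Mead at tight
tolerance. Estimates landing within 0.5% (log scale) of a box edge set the
`at_bounds` flag: a one-way-trip or contrast-free effort history genuinely
cannot identify all three parameters, and the package reports that rather
than returning a silent boundary solution. $R^2$ is computed on observed
versus predicted log catch, consistent with the loss.

The equilibrium alternative, `fit_equilibrium_cpue()`, is ordinary least
squares of CPUE on effort. Its $-a/(2b)$ effort optimum needs no $q$, but
it assumes every observation is an equilibrium point; it is provided as the
classical cross-check, not as the primary estimator. A non-negative slope
(CPUE not declining in effort) returns a flagged, `NA`-valued result.

## Reference points, optimal control, taxes

With $\theta = c/(pqK)$, all static reference points are closed forms
(`msy_point()`, `mey_point()`, `oae_point()`); `reference_table()`
assembles them with total revenue $pH$, total cost $cE$ and rent. At the
open-access equilibrium total cost is set equal to total revenue so the
zero rent is exact by construction, not a floating-point residual.
$\theta \ge 1$ (fishing never profitable) returns a structured
zero-effort point flagged infeasible instead of a negative effort.

The discounted optimum uses the singular-path closed form

$$x^* = \frac{K}{4}\left[\left(1+\theta-\frac{\delta}{r}\right) +
\sqrt{\left(1+\theta-\frac{\delta}{r}\right)^2 +
\frac{8\theta\delta}{r}}\right],$$

the stationary solution of the current-value Hamiltonian for linear-in-
harvest control with stock-dependent cost $c/(qx)$. It is pinned down by
its limits — $x^*(0)$ equals the MEY stock, $x^*(\delta\to\infty)$ the
open-access stock — and the test suite verifies it against an independent
numerical root of the golden-rule marginal condition
$F'(x) - c'(x)F(x)/(p - c(x)) = \delta$ across 1000 random parameter
draws. Present value is $\pi/\delta$; at $\delta = 0$ it is reported as a
flagged infinity, since the sustainable-rent interpretation of the optimum
remains meaningful there.

The default discount rate for the OSY regime is $\delta = 0.10$/yr, the
lower end of the 10–20% band conventionally recommended for these
fisheries; it is configurable everywhere it appears. Taxes are static
identities at the target equilibrium — $T = p - cE/H$ per tonne landed or
$T = pH/E - c$ per boat-year — chosen so the after-tax open-access
equilibrium lands exactly on the target effort; no phase-in dynamics are
modelled. Infeasible targets (beyond open access) return negative taxes
with a warning — a subsidy — rather than being clamped, so the
infeasibility is visible.

One known bookkeeping discrepancy: published open-access *biomass* entries
for these stocks are not consistent with $x_{OAE} = c/(pq)$ under the same
back-derived $p$ and $c$ that reproduce the open-access effort and harvest.
The package reports $c/(pq)$, the value implied by the model; the
open-access effort, harvest and zero rent are unaffected.

## The synthetic generator

`simulate_fishery()` produces series with exactly the statistical
structure the estimator assumes: annual logistic dynamics, proportional
catchability, and multiplicative log-normal observation error on catch,
$C^{obs}_t = qE_tB_t\,e^{\varepsilon_t - \sigma^2/2}$,
$\varepsilon_t \sim N(0,\sigma^2)$. Choices made once:

* **Bias correction.** The $-\sigma^2/2$ term makes the error factor
  mean-one, so simulated MSY is unbiased for recovery studies.
* **Observation error only.** The biomass is depleted by the *true* catch;
  noise enters observation only, matching the estimator's error model.
  Process error is deliberately out of scope.
* **Defaults.** 31 years (mirroring a 1990–2020 record);
  $\sigma = 0.2$, a typical log-catch observation error for national
  landing statistics; a "one-way-trip" effort history rising from 0.1× to
  1.5× the MSY effort, the contrast-rich development pattern a production
  model needs for identifiability; initial depletion equal to each stock's
  published IP.

`oman_like_scenarios()` packages four presets whose true parameters equal
the published Schaefer estimates (`oman_benchmarks()`). What passing
recovery tests on these data shows is that the estimator inverts its own
generating model correctly — it does **not** show that real Omani landing
statistics satisfy that model. Hyperstable CPUE, unrecorded effort
standardisation, process error and price dynamics are all absent from the
generator, and all present in real data.

## Problem sizes and numerics in the test suite

The suite checks closed forms against brute-force grid maximisation
(20,001-point grids), the optimal-stock formula against the golden-rule
root-finder at $10^{-6}$ relative tolerance over 1000 random draws,
noise-free parameter recovery to 0.5% on all four presets, and a 100-
replicate Monte-Carlo recovery study at $\sigma = 0.2$ requiring median
relative MSY error at or below 10%. These sizes were chosen as the
smallest that make the corresponding property stable under reseeding;
each fit takes a fraction of a second, the whole suite under two minutes.

## Known limitations

* Single-species, single-fleet; no technical interaction between the four
  fisheries that share boats in reality.
* Effort is an abstract "boats" unit; no standardisation across vessel
  classes or seasons.
* The equilibrium CPUE regression inherits all the classical biases of
  equilibrium assumptions on transient data.
* No uncertainty quantification on the fitted parameters (bootstrap or
  Bayesian posteriors would be the natural extension).
* Taxes are evaluated at equilibrium; enforcement costs, quota
  alternatives and distributional questions are not modelled.
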
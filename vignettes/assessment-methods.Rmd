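---
title: "Methods: a backwards SIR assessment of humpback whale recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a backwards SIR assessment of humpback whale recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the priors, the numerical choices and the
known limitations of the package. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The population model

Abundance follows a deterministic generalized logistic (Pella–Tomlinson)
recursion on an annual grid from 1830 (assumed equilibrium at carrying
capacity `K`, before exploitation began) to 2030:

$$N_{t+1} = N_t + N_t\, r_{\max} \left[1 - (N_t/K)^z\right] - C_t\,\mathrm{SLR}_{p(t)}.$$

Growth is applied first and the removal subtracted afterwards within each
year, exactly as the recursion is written; no mid-year mortality split is
attempted. The shape parameter `z` fixes the fraction of `K` at which
production peaks, $\mathrm{MSYL} = (1+z)^{-1/z}$: 60% for `z = 2.39` (the
reference case, the value conventionally used in whale assessments), 70%
for `z = 5.04` and 80% for `z = 11.22` (scenarios M-1, M-2). Raising `z`
delays density dependence, so the population grows at nearly `r_max` until
close to `K`.

Removals combine two eras. Pre-modern landings (1830–1924) are known only as
period totals with a minimum and maximum reconstruction; each period total
is spread uniformly over its years (the sources give no finer resolution),
and a single parameter $\theta \in [0,1]$ interpolates every year between
the minimum and maximum series, $C_t = C_{t,\min} + \theta\,(C_{t,\max} -
C_{t,\min})$. Modern catches (1904–1972) are annual, under four allocation
hypotheses for feeding-ground catches (Core; Core + Falkland; Fringe;
Overlap). Struck-and-lost rate (SLR) factors convert landings into total
kills: one scalar factor per era per draw, `N(1.71, 0.073^2)` pre-modern and
`N(1.0185, 0.0028^2)` modern (truncated below at 1, which is more than nine
standard deviations from either mean). Scenario C-4 replaces the modern
factor in 1904–1918 by `1 + lambda` with `lambda` half-normal, scale
`0.15/qnorm(0.975)` truncated to `[0, 0.30]`, so that the factor exceeds
1.15 with probability 0.05 and never exceeds 1.30. The window 1904–1918
(rather than through 1920) follows the scenario description in the source
narrative; the factor is applied to all modern catches in the window. The
pre-modern factor is applied to the whole pre-modern series including the
1894 pelagic catch, keeping the correction consistent within an era.

## Backwards parameterization and the solver

No prior is placed on `K`. Each draw carries a recent abundance
`n_recent ~ U[500, 40000]` anchored at 2008 (2012 in scenario D-1), and `K`
is defined implicitly as the value whose forward projection passes through
`n_recent` in that year. Because abundance in any year is strictly
increasing in `K` for fixed removals and growth parameters (verified
numerically on grids in the test suite), the solution is unique and a
bracketing root-finder is exact. The implementation brackets on
`[n_recent, 5e5]` — the upper bound an order of magnitude above any
plausible carrying capacity, with two four-fold expansions as a guard — and
uses an Illinois-damped regula falsi, accepting a candidate when the
projected abundance matches `n_recent` to 1e-9 relative, or when the
bracket narrows below 1e-12 of its upper end. Draws for which no valid
trajectory attains `n_recent` (or whose trajectory later crosses the
extinction floor of one whale) are marked infeasible and receive zero
weight rather than raising an error. A trajectory is invalid as soon as it
drops below one whale; the solver treats such projections as "below
target", which preserves the bracketing property because validity is itself
monotone in `K`.

The solver is compiled code and is iterated synchronously across draws (the
inner loop runs over draws within a year step) so that the expensive power
evaluations of independent draws pipeline; an R reference implementation
(`solve_carrying_capacity()`) is retained and the two are cross-checked to
about 1e-10 relative in the tests. One draw–for–draw subtlety motivated the
dual implementation: for near-extinction trajectories the recent abundance
is extremely sensitive to `K`, so convergence is judged on the projected
abundance itself, not only on the bracket width.

## Likelihood

Absolute abundance estimates (2008: 14,264, CV 0.084; 2012: 20,389, CV
0.071) contribute independent lognormal terms with
$\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$. Relative indices (feeding-ground
FG; breeding-ground BG1, BG2) observe `q * N_t` with lognormal error and
unknown catchability `q`. With a flat prior on `log q`, `q` integrates out
in closed form; writing $e_t = \log I_t - \log N_t$, $w_t = \sigma_t^{-2}$,
$W = \sum w_t$ and $\bar e = \sum w_t e_t / W$:

$$\log L = -\tfrac{n-1}{2}\log 2\pi - \sum_t \log\sigma_t - \tfrac12 \log W
  - \tfrac12 \sum_t w_t (e_t - \bar e)^2.$$

This form was re-derived from the stated assumptions and is verified against
numerical quadrature over `log q` (to 1e-6 relative, on randomized cases) in
both the unit and acceptance suites — so its correctness does not rest on
any particular constant convention in the cited literature. All additive
constants are retained, because Bayes-factor model averaging requires
likelihoods that are comparable across scenarios; scenarios entering the
average must carry an identical data signature (which series and years are
fitted), enforced at averaging time. A single-observation index carries no
information (the level is absorbed by `q`), and multiplying a whole series
by a positive constant leaves the marginal likelihood unchanged; both
properties are tested.

The genetic-floor scenarios (G-1, G-2) assign zero likelihood to
trajectories whose minimum falls below `N_floor` = 3 × (number of surviving
mtDNA haplotypes): 162 for the 54 total haplotypes, 15 for the 5 unique
ones. The reference case applies no floor.

## SIR, marginal likelihoods and model averaging

Each scenario draws 2e5 parameter vectors from the priors (`r_max ~
U[0, 0.118]`, or for D-7 an informative truncated normal on `[0, 0.118]`
with location 0.08796 and scale 0.01905, fitted once so that the prior mean
is 8.6%/yr and the central 95% interval is 5–11.4%/yr; `theta ~ U[0,1]`;
SLR factors per scenario), completes each draw (solve `K`, project to 2030
under zero future removals, evaluate the likelihood), importance-weights by
the likelihood and resamples 10,000 posterior draws with replacement
(plain multinomial). The prior-draw count is a package default chosen so
the Kish effective sample size comfortably exceeds the posterior size
(ESS is reported in `glance()`); the acceptance suite verifies that two
independent seeds give reference-case median `K` agreeing well within the
published tolerance. The marginal likelihood of a scenario is the prior
mean of the likelihood, computed by log-sum-exp; infeasible draws count as
zero likelihood and remain in the denominator.

Model averaging covers the nine scenarios with comparable likelihoods (RC,
D-1, D-7, C-4, C-5, C-6, C-7, M-1, M-2) with equal prior model
probabilities; posterior model probabilities are the softmax of the log
marginals. The averaged posterior pools entire parameter vectors: each
pooled draw first selects a scenario by its probability, then a draw from
that scenario's posterior. Scenarios fitting different data (D-2–D-6),
scenarios that discard plausible data for exploration (C-1–C-3), and the
floor scenarios (G-1, G-2, which duplicate the reference case almost
exactly) are excluded.

## Digitized inputs

Every input table ships as a versioned CSV and is validated at load time
against the printed column totals (pre-modern minimum 11,481 / maximum
34,708 / pelagic 257, and their sums 11,738 / 34,965; modern Core 31,170 /
Falkland 219 / Fringe 31,847 / Overlap 27,334); the pipeline refuses to run
if any total fails. A handful of multi-column rows of the modern table are
typographically ambiguous in the source rendering. They were reconciled
against the unambiguous total rows: three cells in small-catch years (the
1962 Falkland entry and the 1963 Fringe and Overlap entries, all 22 whales
or fewer) take reconciled values so that every column total is reproduced
exactly. These cells have negligible leverage: they are two orders of
magnitude smaller than the series totals and fall decades after the
population minimum. Index survey seasons spanning two calendar years
("1982/83") are assigned to their first year, following the source's own
convention. US pelagic pre-modern catches are assigned to 1840–1849 (28),
1860–1869 (181) and 1894 (48), consistent with the printed pelagic total.

## The synthetic-data generator

`synthetic_design()` defines a ground truth with the same statistical
structure the assessment assumes: a generalized-logistic trajectory under
the corrected reference-case removal template, observed through
mean-unbiased lognormal noise — an estimate with log-sd $\sigma$ is
$N\exp(\sigma\varepsilon - \sigma^2/2)$, so its expectation equals the
truth; the source does not state a bias convention for its estimates, and
mean-unbiasedness is the package's documented choice. Indices are scaled by
a true catchability. The default design mirrors the reference-case
observation years and CVs so parameter-recovery experiments exercise
exactly the likelihood paths used for the real data. The default truth is
`K = 30000`, `r_max = 0.08`, `theta = 0.5` with loss factors at their prior
means, which survives the corrected catch history with a bottleneck near
470 whales in the late 1950s — feasibility under the fully corrected
removals is knife-edge, and several otherwise plausible combinations (for
example `K = 27000` with the same settings) cross the extinction floor, so
the generator validates its design and refuses infeasible ones.

What passing recovery tests do show: with data of the assumed structure and
truths inside the prior support, the posterior medians are nearly unbiased
and the 95% intervals cover the truth at close to nominal rate (the
acceptance suite runs 50 replicates at 2e4 prior draws each). What they do
not show: robustness to process stochasticity, age/sex structure,
time-varying carrying capacity, correlated index errors or catch-record
biases outside the `theta` interval — none of which the generator, or the
model, represents.

## Numerical choices and degenerate inputs

- Quantiles use the inclusive linear-interpolation convention (R type 7).
- Trajectories and likelihoods are computed in double precision; the
  extinction floor is one whale.
- `theta` outside `[0, 1]`, non-positive CVs, negative haplotype counts,
  overlapping catch periods and empty weight vectors raise errors;
  infeasible draws never do (they are zero-weight data, not faults).
- All randomness flows through R's global RNG, so a single `set.seed()`
  makes any pipeline run reproducible.
- Problem sizes in the shipped tests: 2e5 prior draws per scenario for the
  assessment reproduction and scenario-direction checks; 2e4 per replicate
  for the 50-replicate recovery experiment; these are the package defaults
  and match the Monte-Carlo error the published intervals tolerate.

## Known limitations

The model is deterministic and age/sex-aggregated with constant `K`;
scenario uncertainty is discrete (a grid, not a continuous mixture);
catchabilities are assumed constant over each index's span; the
struck-and-lost factors are scalars per era, not time-varying; and the
krill-consumption arithmetic deliberately propagates no uncertainty from
the biomass estimate (a point estimate of 60.3 million tonnes is used, as
in the source analysis).
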
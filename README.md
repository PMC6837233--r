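# whalesir

Bayesian assessment of the recovery of western South Atlantic (WSA) humpback
whales (*Megaptera novaeangliae*) from two centuries of whaling, implemented
as a tested, reusable R package.

## The problem and the model

WSA humpback whales were hunted from about 1830 (Brazilian shore-based and US
pelagic "pre-modern" whaling) until 1972 (modern whaling centred on South
Georgia), and have since recovered strongly. The package reconstructs the
population trajectory with a deterministic generalized logistic
(Pella–Tomlinson) model,

```
N[t+1] = N[t] + N[t] * r_max * (1 - (N[t]/K)^z) - C[t] * SLR[p(t)]
```

where `K` is carrying capacity (the 1830 equilibrium), `r_max` the maximum
population growth rate, `z` the shape parameter setting the abundance at
which production peaks (MSYL = `(1+z)^(-1/z)` of `K`; 60% for `z = 2.39`),
`C[t]` the landed catch and `SLR` an era-specific struck-and-lost correction
factor. Pre-modern landings are only known to within a wide range; a
parameter `theta` interpolates between the minimum and maximum reconstructed
series. The model is fitted in a Bayesian framework to ship-survey estimates
of absolute abundance (2008, 2012) and to relative-abundance indices from
the feeding and breeding grounds whose unknown catchabilities are integrated
out analytically. Instead of a prior on `K`, a "backwards" scheme places a
uniform prior on a recent abundance and solves for the `K` whose projection
passes through it. Posterior draws come from sampling–importance–resampling
(SIR); a grid of sensitivity scenarios (data choices, catch allocations,
loss-rate assumptions, genetic floors, MSYL values) is combined by
Bayes-factor model averaging.

All inputs ship with the package as digitized tables whose column totals are
validated against the printed originals at load time.

## Worked example

```r
library(whalesir)
set.seed(42)

fit <- fit_scenario("RC", n_prior = 2e4, n_out = 2000)
fit
#> SIR fit for scenario RC
#>   prior draws: 20000, posterior draws: 2000, ESS: 758
#>   log marginal likelihood: -1.977
#>   median K: 29284, median r_max: 0.092
```

The posterior medians say the pre-exploitation population was about 29,000
whales and grew back at about 9% per year once whaling stopped; the
effective sample size (ESS) reports how many independent draws the
importance weights are worth. `tidy(fit)` gives the full summary table
(mean, median, 95% interval) for `K`, `r_max`, the trajectory minimum
`n_min`, predicted abundances and status (`N/K`) in 2006–2030;
`autoplot(fit)` draws the trajectory with 50% and 95% credible bands.

The full model-averaged assessment (nine comparable scenarios, 2e5 prior
draws each, a few minutes on one core):

```r
set.seed(20260923)
avg <- run_assessment(n_prior = 2e5, n_out = 1e4)
avg
#> Model-averaged assessment over RC, D-1, D-7, C-4, C-5, C-6, C-7, M-1, M-2
#>   pooled draws: 10000
#>   median K: 28402, median r_max: 0.089, median status 2019: 0.913
```

So the population bottomed out around 420 whales in the late 1950s
(`tidy(avg)` row `n_min`) and stood at roughly 91% of its pre-exploitation
size in 2019. The krill arithmetic converts the recovered abundance into
prey consumption:

```r
krill_consumption(24925, daily_rate = 497.23, season_days = 120) / 1e6
#> [1] 1.487215   # million tonnes per feeding season (low ingestion rate)
krill_fraction(krill_consumption(24925, 874.33, 120), biomass = 60.3e6)
#> [1] 4.336851   # percent of the Area 48 krill biomass (high rate)
```

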
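# Shared test utilities.

unit_loss <- function() {
  tibble::tibble(premodern_factor = 1, modern_factor = 1,
                 early_modern_factor = 1)
}

# An observation set carrying no data: all draws get equal weight, so the
# SIR posterior must reproduce the prior.
zero_data_obs <- function() {
  list(absolute = whale_abundance()[0, ], indices = list(),
       signature = "none")
}

# Catch tables with no removals at all (equilibrium toy problems).
zero_catches <- function() {
  list(
    periods = tibble::tibble(start_year = 1830L, end_year = 1830L,
                             brazil_min = 0, brazil_max = 0, pelagic = 0),
    modern = tibble::tibble(year = 1904L, core = 0, falkland = 0,
                            fringe = 0, overlap = 0)
  )
}

# Independent quadrature oracle for the marginalized-catchability index
# likelihood: integrate the lognormal likelihood over log-catchability with
# a flat prior, on a wide adaptive grid.
index_loglik_quadrature <- function(pred, obs) {
  N <- pred$abundance[match(obs$year, pred$year)]
  sig <- lognormal_sigma(obs$cv)
  e <- log(obs$estimate) - log(N)
  logdens <- function(q) sum(stats::dnorm(e, mean = q, sd = sig, log = TRUE))
  centre <- stats::weighted.mean(e, 1 / sig^2)
  peak <- logdens(centre)  # factor out the peak so the integrand is O(1)
  dens <- function(lq) vapply(lq, function(q) exp(logdens(q) - peak), numeric(1))
  width <- 12 * max(sig)
  int <- stats::integrate(dens, centre - width, centre + width,
                          rel.tol = 1e-10, subdivisions = 500L)
  peak + log(int$value)
}
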
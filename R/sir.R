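# Informative life-history prior on r_max: truncated normal on [0, 0.118]
# with parameters chosen to reproduce a mean of 8.6%/yr and a 95% interval
# of 5-11.4%/yr.
.rmax_informative <- list(mean = 0.087964, sd = 0.019052,
                          lower = 0, upper = 0.118)
.rmax_uniform <- list(lower = 0, upper = 0.118)
.nrecent_prior <- list(lower = 500, upper = 40000)

#' Sample parameter draws from the scenario priors
#'
#' The estimable parameters are the maximum growth rate `r_max` (uniform
#' U\[0, 0.118\] or, for D-7, an informative truncated-normal life-history
#' prior), the recent abundance `n_recent` (U\[500, 40000\], anchored at the
#' scenario's `recent_year`), the pre-modern catch interpolation `theta`
#' (U\[0, 1\]) and the era-specific struck-and-lost factors (see
#' [sample_loss_rates()]). Carrying capacity receives no prior; it is derived
#' per draw by [solve_carrying_capacity()].
#'
#' @param spec scenario, as [scenario_spec()].
#' @param n number of prior draws.
#' @return tibble with columns `r_max`, `theta`, `n_recent`,
#'   `premodern_factor`, `modern_factor`, `early_modern_factor`.
#' @examples
#' set.seed(1)
#' sample_parameter_priors(scenario_spec("RC"), 5)
#' @export
sample_parameter_priors <- function(spec, n) {
  r_max <- if (spec$rmax_prior == "informative") {
    p <- .rmax_informative
    lo <- pnorm(p$lower, p$mean, p$sd)
    hi <- pnorm(p$upper, p$mean, p$sd)
    qnorm(lo + runif(n) * (hi - lo), p$mean, p$sd)
  } else {
    runif(n, .rmax_uniform$lower, .rmax_uniform$upper)
  }
  loss <- sample_loss_rates(n, spec$slr_mode)
  tibble::tibble(
    r_max = r_max,
    theta = runif(n),
    n_recent = runif(n, .nrecent_prior$lower, .nrecent_prior$upper),
    premodern_factor = loss$premodern_factor,
    modern_factor = loss$modern_factor,
    early_modern_factor = loss$early_modern_factor
  )
}

# Years always reported by the engine (status years plus all data years).
.report_years <- function(observations) {
  sort(unique(c(2006L, 2008L, 2012L, 2019L, 2030L,
                observations$absolute$year,
                unlist(lapply(observations$indices, function(s) s$year)))))
}

#' Complete prior draws: solve K, project, and evaluate the likelihood
#'
#' For each draw the removal series is assembled, carrying capacity solved by
#' bisection so the trajectory passes through the drawn recent abundance, the
#' population projected to 2030 under zero future removals, and the
#' log-likelihood of the scenario's data computed (with the genetic-floor
#' indicator where applicable). Draws whose trajectory cannot attain the
#' drawn recent abundance, or that cross the extinction floor, are marked
#' infeasible and receive zero weight.
#'
#' @param spec scenario, as [scenario_spec()].
#' @param draws prior draws from [sample_parameter_priors()].
#' @param observations observation set from [observation_set()]; may contain
#'   empty `absolute` and `indices` for a prior-only (zero-data) run.
#' @param catches optional list with elements `periods` and `modern`
#'   overriding the packaged catch tables.
#' @return the draws tibble augmented with `K`, `feasible`, `n_min`,
#'   `year_min`, `loglik`, status columns (`status_2006` ... `status_2030`,
#'   `max_depletion`) and predicted abundances `N_2006` ... `N_2030`.
#' @export
evaluate_draws <- function(spec, draws, observations = observation_set(spec),
                           catches = NULL) {
  comp <- if (is.null(catches)) {
    .catch_components(spec)
  } else {
    .catch_components(spec, catches$periods, catches$modern)
  }
  years <- .report_years(observations)
  res <- .evaluate_draws_cpp(
    draws$r_max, draws$theta, draws$n_recent,
    draws$premodern_factor, draws$modern_factor, draws$early_modern_factor,
    spec$z, as.integer(spec$recent_year),
    spec$include_premodern,
    comp$premodern_min, comp$premodern_delta, comp$modern, comp$early_mask,
    1830L, 2030L, as.integer(years), 5e5, 1e-12
  )
  N <- res$N
  ll <- rep(-Inf, nrow(draws))
  ok <- res$feasible
  if (any(ok)) {
    ll[ok] <- .loglik_matrix(N[ok, , drop = FALSE], years, observations,
                             res$n_min[ok], spec$n_floor)
  }
  out <- draws
  out$K <- res$K
  out$feasible <- ok
  out$n_min <- res$n_min
  out$year_min <- res$year_min
  out$loglik <- ll
  for (y in c(2006, 2008, 2012, 2019, 2030)) {
    out[[paste0("N_", y)]] <- N[, match(y, years)]
  }
  out$max_depletion <- out$n_min / out$K
  for (y in c(2006, 2008, 2012, 2019, 2030)) {
    out[[paste0("status_", y)]] <- out[[paste0("N_", y)]] / out$K
  }
  out
}

#' Importance resampling
#'
#' Samples `n_out` draw indices with replacement, with probability
#' proportional to the importance weights.
#'
#' @param weights non-negative weights (zero for infeasible draws).
#' @param n_out number of posterior draws.
#' @return integer vector of indices into the prior draws.
#' @export
sir_resample <- function(weights, n_out) {
  if (length(weights) == 0 || all(weights <= 0) || any(!is.finite(weights))) {
    stop("no feasible draws: all importance weights are zero", call. = FALSE)
  }
  sample.int(length(weights), n_out, replace = TRUE, prob = weights)
}

#' Importance-weight diagnostics
#'
#' @param weights non-negative, finite weights.
#' @return tibble with `ess` (Kish effective sample size,
#'   `sum(w)^2 / sum(w^2)`) and `max_weight_share` (largest normalized
#'   weight).
#' @examples
#' sir_diagnostics(c(1, 1, 2)) # ess = 16/6
#' @export
sir_diagnostics <- function(weights) {
  if (length(weights) == 0) stop("empty weight vector", call. = FALSE)
  stopifnot(all(is.finite(weights)), all(weights >= 0))
  s <- sum(weights)
  tibble::tibble(ess = s^2 / sum(weights^2), max_weight_share = max(weights) / s)
}

#' Log marginal likelihood from prior-sample log-likelihoods
#'
#' Under prior sampling the marginal likelihood is the prior mean of the
#' likelihood; this returns `log(mean(exp(loglik)))` computed stably
#' (log-sum-exp). Infeasible draws enter with zero likelihood.
#'
#' @param loglik vector of per-draw log-likelihoods (`-Inf` allowed).
#' @return scalar log marginal likelihood estimate (`-Inf` if all zero).
#' @export
log_marginal_estimate <- function(loglik) {
  m <- max(loglik)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(loglik - m))) - log(length(loglik))
}

#' Fit one scenario by sampling-importance-resampling
#'
#' Draws `n_prior` parameter vectors from the scenario priors, completes them
#' with [evaluate_draws()], importance-weights them by the likelihood and
#' resamples `n_out` posterior draws.
#'
#' @param scenario scenario name (see [scenario_names()]) or a spec tibble.
#' @param n_prior number of prior draws (the default trades Monte-Carlo error
#'   against run time; the effective sample size is reported).
#' @param n_out number of posterior draws.
#' @param observations observation set; defaults to the scenario's packaged
#'   data. Pass the result of [observation_set()] on other data (e.g. a
#'   synthetic study), or a zero-data set to reproduce the prior.
#' @param catches optional catch-table override (list with `periods`,
#'   `modern`).
#' @return an object of class `sir_fit`: a list with elements `spec`,
#'   `posterior` (tibble of `n_out` resampled draws), `log_marginal`,
#'   `diagnostics`, `signature`, `n_prior`.
#' @examples
#' \donttest{
#' set.seed(1)
#' fit <- fit_scenario("RC", n_prior = 5000, n_out = 1000)
#' tidy(fit)
#' }
#' @export
fit_scenario <- function(scenario, n_prior = 2e5, n_out = 1e4,
                         observations = NULL, catches = NULL) {
  spec <- if (is.character(scenario)) scenario_spec(scenario) else scenario
  .assert_checksums()
  if (is.null(observations)) observations <- observation_set(spec)
  draws <- sample_parameter_priors(spec, n_prior)
  draws <- evaluate_draws(spec, draws, observations, catches)
  w <- exp(draws$loglik - max(draws$loglik[is.finite(draws$loglik)], -Inf))
  w[!is.finite(w)] <- 0
  if (all(w == 0)) {
    stop("no feasible draws for scenario '", spec$name, "'", call. = FALSE)
  }
  idx <- sir_resample(w, n_out)
  structure(
    list(spec = spec,
         posterior = draws[idx, ],
         log_marginal = log_marginal_estimate(draws$loglik),
         diagnostics = sir_diagnostics(w),
         signature = observations$signature,
         n_prior = n_prior),
    class = "sir_fit"
  )
}

#' @export
print.sir_fit <- function(x, ...) {
  cat("SIR fit for scenario", x$spec$name, "\n")
  cat(sprintf("  prior draws: %d, posterior draws: %d, ESS: %.0f\n",
              x$n_prior, nrow(x$posterior), x$diagnostics$ess))
  cat(sprintf("  log marginal likelihood: %.3f\n", x$log_marginal))
  cat(sprintf("  median K: %.0f, median r_max: %.3f\n",
              median(x$posterior$K), median(x$posterior$r_max)))
  invisible(x)
}
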
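# Quantities summarized in posterior reports.
.summary_quantities <- c("r_max", "K", "n_min",
                         "N_2006", "N_2008", "N_2012", "N_2019", "N_2030",
                         "max_depletion",
                         "status_2006", "status_2008", "status_2012",
                         "status_2019", "status_2030")

#' Posterior summary table
#'
#' Mean, median and equal-tailed 95% probability interval for each requested
#' quantity of a posterior draws tibble. Quantiles use the inclusive
#' linear-interpolation convention (`type = 7`).
#'
#' @param posterior tibble of posterior draws.
#' @param quantities character vector of column names to summarize.
#' @return tibble with columns `quantity`, `mean`, `median`, `pi_2_5`,
#'   `pi_97_5`.
#' @export
posterior_summary <- function(posterior, quantities = .summary_quantities) {
  missing <- setdiff(quantities, names(posterior))
  if (length(missing) > 0) {
    stop("unknown quantity: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(quantities, function(q) {
    x <- posterior[[q]]
    tibble::tibble(quantity = q, mean = mean(x), median = median(x),
                   pi_2_5 = quantile(x, 0.025, names = FALSE),
                   pi_97_5 = quantile(x, 0.975, names = FALSE))
  })
}

#' @export
tidy.sir_fit <- function(x, ...) posterior_summary(x$posterior, ...)

#' @export
tidy.sir_average <- function(x, ...) posterior_summary(x$posterior, ...)

#' @export
glance.sir_fit <- function(x, ...) {
  tibble::tibble(scenario = x$spec$name, n_prior = x$n_prior,
                 n_posterior = nrow(x$posterior),
                 ess = x$diagnostics$ess,
                 max_weight_share = x$diagnostics$max_weight_share,
                 log_marginal = x$log_marginal)
}

#' @export
glance.sir_average <- function(x, ...) {
  tibble::tibble(n_members = nrow(x$members),
                 n_posterior = nrow(x$posterior),
                 median_K = median(x$posterior$K),
                 median_r_max = median(x$posterior$r_max),
                 median_status_2019 = median(x$posterior$status_2019))
}

# Recompute full annual trajectories for a posterior draws tibble.
.posterior_trajectories <- function(posterior, specs) {
  if (!"scenario" %in% names(posterior)) {
    posterior$scenario <- specs[[1]]$name
  }
  pieces <- lapply(split(posterior, posterior$scenario), function(block) {
    spec <- specs[[block$scenario[1]]]
    comp <- .catch_components(spec)
    .trajectories_cpp(block$K, block$r_max, block$theta,
                      block$premodern_factor, block$modern_factor,
                      block$early_modern_factor,
                      spec$z, spec$include_premodern,
                      comp$premodern_min, comp$premodern_delta,
                      comp$modern, comp$early_mask, 1830L, 2030L)
  })
  do.call(rbind, pieces)
}

#' Posterior trajectory envelope
#'
#' Recomputes the annual abundance trajectory of every posterior draw and
#' returns year-wise quantiles: the median and the 50% and 95% probability
#' bands.
#'
#' @param fit a `sir_fit` or `sir_average` object.
#' @return tibble with columns `year`, `q2_5`, `q25`, `median`, `q75`,
#'   `q97_5`.
#' @export
trajectory_envelope <- function(fit) {
  specs <- if (inherits(fit, "sir_average")) {
    lapply(fit$fits, function(f) f$spec)
  } else {
    setNames(list(fit$spec), fit$spec$name)
  }
  M <- .posterior_trajectories(fit$posterior, specs)
  years <- 1830:2030
  qs <- apply(M, 2, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
              names = FALSE)
  tibble::tibble(year = years, q2_5 = qs[1, ], q25 = qs[2, ],
                 median = qs[3, ], q75 = qs[4, ], q97_5 = qs[5, ])
}

.plot_envelope <- function(env, title) {
  ggplot2::ggplot(env, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2_5, ymax = .data$q97_5),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Abundance (whales)", title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sir_fit <- function(object, ...) {
  .plot_envelope(trajectory_envelope(object),
                 paste("Posterior trajectory,", object$spec$name))
}

#' @export
autoplot.sir_average <- function(object, ...) {
  .plot_envelope(trajectory_envelope(object),
                 "Model-averaged posterior trajectory")
}

#' Krill consumption of the recovered population
#'
#' Seasonal prey consumption implied by an abundance estimate, a per-capita
#' daily ingestion rate and the length of the feeding season:
#' `population * daily_rate * season_days / 1000` tonnes.
#'
#' @param population number of whales.
#' @param daily_rate individual consumption (kg per whale per day).
#' @param season_days length of the feeding season (days).
#' @return consumption in tonnes.
#' @examples
#' krill_consumption(24925, 497.23, 120) / 1e6 # about 1.49 M tonnes
#' @export
krill_consumption <- function(population, daily_rate, season_days) {
  stopifnot(all(population >= 0), all(daily_rate > 0), all(season_days > 0))
  population * daily_rate * season_days / 1000
}

#' @param consumption seasonal consumption (tonnes).
#' @param biomass standing krill biomass (tonnes), > 0.
#' @return `krill_fraction()`: percentage of the biomass consumed.
#' @examples
#' krill_fraction(krill_consumption(24925, 874.33, 120), 60.3e6) # about 4.3
#' @rdname krill_consumption
#' @export
krill_fraction <- function(consumption, biomass) {
  if (any(biomass <= 0)) stop("biomass must be positive", call. = FALSE)
  100 * consumption / biomass
}
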
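#' Run the scenario grid
#'
#' Fits each named scenario by SIR with a fresh set of prior draws.
#'
#' @param names scenario names; defaults to the model-averaging set.
#' @param n_prior,n_out see [fit_scenario()].
#' @return named list of `sir_fit` objects.
#' @export
run_scenarios <- function(names = averaging_scenarios(),
                          n_prior = 2e5, n_out = 1e4) {
  fits <- lapply(names, fit_scenario, n_prior = n_prior, n_out = n_out)
  names(fits) <- names
  fits
}

#' Relative model probabilities from Bayes factors
#'
#' With equal prior model probabilities, the posterior probability of each
#' scenario is its marginal likelihood normalized over the set (a softmax of
#' the log marginals). The scenarios must fit identical data, which is
#' enforced through the observation-set signature.
#'
#' @param fits named list of `sir_fit` objects.
#' @return tibble with columns `scenario`, `log_marginal`, `probability`
#'   (summing to one).
#' @export
relative_model_probabilities <- function(fits) {
  sigs <- vapply(fits, function(f) f$signature, character(1))
  if (length(unique(sigs)) > 1) {
    stop("scenarios fit different data; marginal likelihoods are not ",
         "comparable: ", paste(unique(sigs), collapse = " | "), call. = FALSE)
  }
  lm <- vapply(fits, function(f) f$log_marginal, numeric(1))
  m <- max(lm)
  p <- exp(lm - m)
  p <- p / sum(p)
  tibble::tibble(scenario = names(fits), log_marginal = unname(lm),
                 probability = unname(p))
}

#' Bayes-factor model averaging
#'
#' Pools posterior parameter vectors across scenarios: each of the `n_out`
#' averaged draws first selects a scenario with probability equal to its
#' relative model probability, then samples a draw (with replacement) from
#' that scenario's posterior.
#'
#' @param fits named list of `sir_fit` objects (the averaging set).
#' @param probabilities optional tibble from
#'   [relative_model_probabilities()]; computed from `fits` if missing.
#' @param n_out number of pooled draws.
#' @return an object of class `sir_average`: list with `members`
#'   (probability tibble), `posterior` (pooled draws tibble with a `scenario`
#'   column), `fits`.
#' @export
model_average <- function(fits, probabilities = NULL, n_out = 1e4) {
  if (is.null(probabilities)) probabilities <- relative_model_probabilities(fits)
  stopifnot(abs(sum(probabilities$probability) - 1) < 1e-12)
  empty <- vapply(fits, function(f) nrow(f$posterior) == 0, logical(1))
  if (any(empty)) {
    stop("empty posterior for scenario(s): ",
         paste(names(fits)[empty], collapse = ", "), call. = FALSE)
  }
  pick <- sample(probabilities$scenario, n_out, replace = TRUE,
                 prob = probabilities$probability)
  counts <- table(factor(pick, levels = probabilities$scenario))
  pooled <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    k <- counts[[probabilities$scenario[i]]]
    if (k == 0) next
    f <- fits[[probabilities$scenario[i]]]
    rows <- f$posterior[sample.int(nrow(f$posterior), k, replace = TRUE), ]
    rows$scenario <- probabilities$scenario[i]
    pooled[[i]] <- rows
  }
  posterior <- dplyr::bind_rows(pooled)
  posterior <- posterior[sample.int(nrow(posterior)), ]
  structure(list(members = probabilities, posterior = posterior, fits = fits),
            class = "sir_average")
}

#' Full model-averaged assessment
#'
#' Convenience wrapper: runs the averaging scenario set and pools the
#' posteriors by Bayes-factor model averaging.
#'
#' @inheritParams run_scenarios
#' @return a `sir_average` object.
#' @export
run_assessment <- function(n_prior = 2e5, n_out = 1e4) {
  fits <- run_scenarios(averaging_scenarios(), n_prior, n_out)
  model_average(fits, n_out = n_out)
}

#' @export
print.sir_average <- function(x, ...) {
  cat("Model-averaged assessment over",
      paste(x$members$scenario, collapse = ", "), "\n")
  cat(sprintf("  pooled draws: %d\n", nrow(x$posterior)))
  cat(sprintf("  median K: %.0f, median r_max: %.3f, median status 2019: %.3f\n",
              median(x$posterior$K), median(x$posterior$r_max),
              median(x$posterior$status_2019)))
  invisible(x)
}
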
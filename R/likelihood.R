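#' Lognormal log-scale standard deviation from a coefficient of variation
#'
#' Survey estimates are assumed lognormally distributed about the model
#' abundance with a known coefficient of variation; the corresponding
#' log-scale standard deviation is `sqrt(log(1 + cv^2))`.
#'
#' @param cv coefficient of variation, > 0.
#' @return log-scale standard deviation.
#' @examples
#' lognormal_sigma(0.084) # about 0.0839
#' @export
lognormal_sigma <- function(cv) {
  if (any(cv <= 0)) stop("cv must be positive", call. = FALSE)
  sqrt(log(1 + cv^2))
}

#' Log-likelihood of absolute abundance estimates
#'
#' Each absolute estimate contributes a lognormal density term
#' `-log(sigma) - log(2*pi)/2 - (log(est) - log(N))^2 / (2*sigma^2)`,
#' where `N` is the model abundance in the estimate year. Constants are
#' retained so that likelihoods are comparable across scenarios fitting the
#' same data (required for Bayes-factor model averaging).
#'
#' @param pred trajectory tibble (`year`, `abundance`).
#' @param obs tibble of estimates (`year`, `estimate`, `cv`).
#' @return scalar log-density; `-Inf` if model abundance is non-positive at
#'   any estimate year.
#' @export
abs_abundance_loglik <- function(pred, obs) {
  N <- pred$abundance[match(obs$year, pred$year)]
  if (any(is.na(N)) || any(N <= 0)) return(-Inf)
  sig <- lognormal_sigma(obs$cv)
  sum(-log(sig) - 0.5 * log(2 * pi) -
        (log(obs$estimate) - log(N))^2 / (2 * sig^2))
}

#' Marginal log-likelihood of a relative abundance index
#'
#' An index observes `q * N_t` with lognormal error and unknown multiplicative
#' catchability `q`. With a flat prior on `log(q)`, `q` integrates out
#' analytically. Writing residuals `e_t = log(I_t) - log(N_t)`, weights
#' `w_t = sigma_t^-2`, `W = sum(w_t)` and the weighted mean `e_bar`, the
#' marginal log-likelihood is
#' `-(n-1)/2 * log(2*pi) - sum(log(sigma_t)) - log(W)/2 -
#'  sum(w_t * (e_t - e_bar)^2) / 2`.
#' Only deviations of residuals from their weighted mean inform the fit: the
#' overall level is absorbed by catchability, so a single-observation series
#' carries no information about the trajectory and the value is invariant to
#' rescaling the whole index series.
#'
#' @inheritParams abs_abundance_loglik
#' @return scalar log-density; `-Inf` if model abundance is non-positive at
#'   any index year.
#' @export
index_marginal_loglik <- function(pred, obs) {
  stopifnot(nrow(obs) >= 1)
  N <- pred$abundance[match(obs$year, pred$year)]
  if (any(is.na(N)) || any(N <= 0)) return(-Inf)
  sig <- lognormal_sigma(obs$cv)
  e <- log(obs$estimate) - log(N)
  w <- 1 / sig^2
  W <- sum(w)
  ebar <- sum(w * e) / W
  -(length(e) - 1) / 2 * log(2 * pi) - sum(log(sig)) - 0.5 * log(W) -
    0.5 * sum(w * (e - ebar)^2)
}

#' Genetic floor on minimum abundance
#'
#' The surviving mitochondrial haplotype diversity bounds the census size at
#' the population bottleneck: each haplotype requires at least one female,
#' and the count is multiplied by three to account for overlapping
#' generations, non-reproductive females and males (1:1 sex ratio). Model
#' trajectories whose minimum abundance falls below this floor receive zero
#' likelihood in the genetic-constraint scenarios.
#'
#' @param h number of distinct mtDNA haplotypes (non-negative integer).
#' @return `n_floor_from_haplotypes()`: minimum census size (whales).
#' @examples
#' n_floor_from_haplotypes(54) # 162
#' @export
n_floor_from_haplotypes <- function(h) {
  if (any(h < 0)) stop("haplotype count must be non-negative", call. = FALSE)
  3 * h
}

#' @param n_min trajectory minimum abundance (whales), > 0.
#' @param n_floor floor (whales); 0 means unconstrained.
#' @return `genetic_floor_ok()`: `TRUE` iff `n_min >= n_floor`.
#' @rdname n_floor_from_haplotypes
#' @export
genetic_floor_ok <- function(n_min, n_floor) {
  stopifnot(all(n_min > 0), all(n_floor >= 0))
  n_min >= n_floor
}

#' Observation set for a scenario
#'
#' Selects the absolute estimates and the scenario's index series from the
#' abundance table and attaches a data signature (which series and years
#' enter the likelihood). Scenarios combined by model averaging must share
#' the same signature, otherwise their marginal likelihoods are not
#' comparable.
#'
#' @param spec scenario, as [scenario_spec()].
#' @param abundance abundance table, as [whale_abundance()].
#' @return list with elements `absolute` (tibble), `indices` (named list of
#'   tibbles) and `signature` (string).
#' @export
observation_set <- function(spec, abundance = whale_abundance()) {
  absolute <- abundance[abundance$series_id == "ABS", ]
  idx <- spec$index_set[[1]]
  indices <- lapply(idx, function(s) abundance[abundance$series_id == s, ])
  names(indices) <- idx
  sig_parts <- c(paste0("ABS:", paste(absolute$year, collapse = ",")),
                 vapply(idx, function(s) {
                   paste0(s, ":", paste(indices[[s]]$year, collapse = ","))
                 }, character(1)))
  list(absolute = absolute, indices = indices,
       signature = paste(sort(sig_parts), collapse = ";"))
}

# Vectorized total log-likelihood over draws. `N` is a draws x years matrix of
# model abundances at `years`; returns a vector of log-likelihoods.
.loglik_matrix <- function(N, years, observations, n_min, n_floor) {
  n <- nrow(N)
  ll <- numeric(n)
  obs_abs <- observations$absolute
  if (nrow(obs_abs) > 0) {
    sig <- lognormal_sigma(obs_abs$cv)
    for (i in seq_len(nrow(obs_abs))) {
      Nc <- N[, match(obs_abs$year[i], years)]
      ll <- ll - log(sig[i]) - 0.5 * log(2 * pi) -
        (log(obs_abs$estimate[i]) - log(Nc))^2 / (2 * sig[i]^2)
    }
  }
  for (series in observations$indices) {
    sig <- lognormal_sigma(series$cv)
    w <- 1 / sig^2
    W <- sum(w)
    E <- matrix(log(series$estimate), n, nrow(series), byrow = TRUE) -
      log(N[, match(series$year, years), drop = FALSE])
    ebar <- as.vector(E %*% w) / W
    dev <- E - ebar
    ll <- ll - (length(w) - 1) / 2 * log(2 * pi) - sum(log(sig)) -
      0.5 * log(W) - 0.5 * as.vector(dev^2 %*% w)
  }
  if (n_floor > 0) ll[n_min < n_floor] <- -Inf
  ll
}
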
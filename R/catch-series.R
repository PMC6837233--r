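#' Annualize pre-modern catch periods
#'
#' Pre-modern catches are reported as period totals. Each period total
#' (separately for the minimum and maximum reconstruction, and including the
#' pelagic component) is spread uniformly over the years of the period,
#' giving annual minimum and maximum landings on the 1830-1972 grid (zero
#' outside documented years).
#'
#' @param periods tibble of catch periods, as [whale_catch_periods()].
#' @return tibble with columns `year` (1830-1972), `premodern_min`,
#'   `premodern_max` (whales per year).
#' @examples
#' annualize_periods()
#' @export
annualize_periods <- function(periods = whale_catch_periods()) {
  n <- nrow(periods)
  if (n > 1) {
    o <- order(periods$start_year)
    p <- periods[o, ]
    if (any(p$start_year[-1] <= p$end_year[-n])) {
      stop("overlapping catch periods", call. = FALSE)
    }
  }
  years <- 1830:1972
  lo <- numeric(length(years))
  hi <- numeric(length(years))
  for (i in seq_len(nrow(periods))) {
    span <- periods$start_year[i]:periods$end_year[i]
    ny <- length(span)
    idx <- match(span, years)
    lo[idx] <- lo[idx] + (periods$brazil_min[i] + periods$pelagic[i]) / ny
    hi[idx] <- hi[idx] + (periods$brazil_max[i] + periods$pelagic[i]) / ny
  }
  tibble::tibble(year = years, premodern_min = lo, premodern_max = hi)
}

#' Interpolate the pre-modern catch series
#'
#' The true pre-modern landings are treated as unknown between the minimum
#' and maximum reconstructions and indexed by a single parameter
#' `theta` in \[0, 1\]: `C_t = C_t_min + theta * (C_t_max - C_t_min)`.
#'
#' @param theta interpolation parameter in \[0, 1\].
#' @param annual annualized series from [annualize_periods()].
#' @return tibble with columns `year`, `catch`.
#' @examples
#' interpolate_premodern(0.5)
#' @export
interpolate_premodern <- function(theta, annual = annualize_periods()) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("theta must be a single value in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    year = annual$year,
    catch = annual$premodern_min +
      theta * (annual$premodern_max - annual$premodern_min)
  )
}

#' Sample struck-and-lost rate factors
#'
#' Landed catches understate total kills because some struck whales were lost
#' at sea and dependent calves died with their mothers. Scalar multiplicative
#' correction factors are assigned era-specific priors: normal
#' N(1.71, 0.073^2) for the pre-modern era and N(1.0185, 0.0028^2) for the
#' modern era (both truncated below at 1). Under the `C4_split` mode an
#' additional early-modern factor for 1904-1918 is drawn as 1 + lambda with
#' lambda half-normal (scale 0.15/qnorm(0.975)) truncated to \[0, 0.30\], so
#' that P(factor > 1.15) = 0.05 and P(factor > 1.30) = 0.
#'
#' @param n number of draws.
#' @param mode one of `"both_eras"`, `"none"`, `"modern_only"`, `"C4_split"`.
#' @param priors prior table, as [whale_loss_rate_priors()].
#' @return tibble with `n` rows and columns `premodern_factor`,
#'   `modern_factor`, `early_modern_factor` (all 1 where unused).
#' @examples
#' set.seed(1)
#' colMeans(sample_loss_rates(1000, "both_eras"))
#' @export
sample_loss_rates <- function(n, mode = "both_eras",
                              priors = whale_loss_rate_priors()) {
  if (!mode %in% c("both_eras", "none", "modern_only", "C4_split")) {
    stop("unknown slr_mode '", mode, "'", call. = FALSE)
  }
  one <- rep(1, n)
  if (mode == "none") {
    return(tibble::tibble(premodern_factor = one, modern_factor = one,
                          early_modern_factor = one))
  }
  prow <- function(label) priors[priors$era_label == label, ]
  rtruncnorm_low <- function(n, mean, sd, lower) {
    # truncation at `lower` is > 9 sd below both prior means; resampling is
    # effectively a no-op but keeps the support correct
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  pm <- prow("premodern"); md <- prow("modern")
  premod <- rtruncnorm_low(n, pm$location, pm$scale, pm$lower_trunc)
  modern <- rtruncnorm_low(n, md$location, md$scale, md$lower_trunc)
  if (mode == "modern_only") premod <- one
  # outside C-4 the whole modern era shares one factor
  early <- modern
  if (mode == "C4_split") {
    em <- prow("early_modern_C4")
    lam <- abs(rnorm(n, 0, em$scale))
    cap <- em$upper_trunc - 1
    while (any(bad <- lam > cap)) lam[bad] <- abs(rnorm(sum(bad), 0, em$scale))
    early <- 1 + lam
  }
  tibble::tibble(premodern_factor = premod, modern_factor = modern,
                 early_modern_factor = early)
}

# Years of the early-modern window used by the C-4 scenario.
.early_modern_years <- c(1904L, 1918L)

# Scenario-resolved catch components on the 1830-1972 grid: pre-modern
# min/delta and the modern column for the scenario's allocation, plus the
# early-modern indicator. Shared by assemble_removals() and the SIR engine.
.catch_components <- function(spec,
                              periods = whale_catch_periods(),
                              modern = whale_modern_catches()) {
  annual <- annualize_periods(periods)
  years <- annual$year
  mod <- numeric(length(years))
  idx <- match(modern$year, years)
  mcol <- switch(spec$allocation,
    "core" = modern$core,
    "core+falkland" = modern$core + modern$falkland,
    "fringe" = modern$fringe,
    "overlap" = modern$overlap,
    stop("unknown allocation '", spec$allocation, "'", call. = FALSE)
  )
  mod[idx] <- mcol
  list(
    year = years,
    premodern_min = annual$premodern_min,
    premodern_delta = annual$premodern_max - annual$premodern_min,
    modern = mod,
    early_mask = years >= .early_modern_years[1] & years <= .early_modern_years[2]
  )
}

#' Assemble the corrected removal series for one parameter draw
#'
#' Combines the interpolated pre-modern landings and the scenario's modern
#' catch allocation with the struck-and-lost factors of a single draw:
#' `removal_t = premodern_factor * C_t_premodern(theta) +
#' modern_factor_t * C_t_modern`. Under the `C4_split` mode the early-modern
#' factor applies to modern catches in 1904-1918 and the modern factor to
#' later years. If the scenario excludes pre-modern catches that component is
#' zero.
#'
#' @param spec scenario, as [scenario_spec()].
#' @param theta pre-modern interpolation parameter in \[0, 1\].
#' @param loss one-row tibble of loss factors, as one row of
#'   [sample_loss_rates()].
#' @param periods,modern catch tables (defaults: packaged fixtures).
#' @return tibble with columns `year` (1830-1972), `removal`.
#' @examples
#' loss <- tibble::tibble(premodern_factor = 1, modern_factor = 1,
#'                        early_modern_factor = 1)
#' sum(assemble_removals(scenario_spec("RC"), theta = 1, loss)$removal) # 66135
#' @export
assemble_removals <- function(spec, theta, loss,
                              periods = whale_catch_periods(),
                              modern = whale_modern_catches()) {
  stopifnot(nrow(loss) == 1)
  comp <- .catch_components(spec, periods, modern)
  pre <- if (spec$include_premodern) {
    loss$premodern_factor * (comp$premodern_min + theta * comp$premodern_delta)
  } else {
    0
  }
  mf <- ifelse(comp$early_mask, loss$early_modern_factor, loss$modern_factor)
  tibble::tibble(year = comp$year, removal = pre + mf * comp$modern)
}
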
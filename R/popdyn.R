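#' One annual step of the generalized logistic model
#'
#' The population follows deterministic Pella-Tomlinson dynamics:
#' `N[t+1] = N[t] + N[t] * r_max * (1 - (N[t]/K)^z) - removal[t]`,
#' with growth applied before the removal is subtracted. The shape parameter
#' `z` sets the fraction of carrying capacity at which annual production
#' peaks (see [msyl_fraction()]).
#'
#' @param N current abundance (whales), > 0.
#' @param K carrying capacity (whales).
#' @param r_max maximum per-year growth rate.
#' @param z shape parameter, > 0.
#' @param removal whales removed this year.
#' @return next-year abundance (whales); may fall below the extinction floor
#'   of one whale, in which case callers must mark the trajectory invalid.
#' @examples
#' logistic_step(10000, K = 27000, r_max = 0.088, z = 2.39) # about 10798
#' @export
logistic_step <- function(N, K, r_max, z, removal = 0) {
  if (any(N <= 0)) stop("abundance must be positive", call. = FALSE)
  N + N * r_max * (1 - (N / K)^z) - removal
}

#' Project a population trajectory
#'
#' Projects the model forward from equilibrium at carrying capacity in the
#' first catch year, applying the removal series annually; removals are zero
#' after the series ends (the projection to 2030 assumes no future removals).
#' A trajectory that ever drops below the extinction floor of one whale is
#' flagged invalid.
#'
#' @param K,r_max,z population parameters, see [logistic_step()].
#' @param removals tibble with columns `year`, `removal` (whales/yr), as from
#'   [assemble_removals()].
#' @param start_year first year, at which `N = K`.
#' @param end_year final projection year.
#' @return tibble with columns `year`, `abundance`, and attribute `valid`.
#' @examples
#' rem <- tibble::tibble(year = 1830:1972, removal = 0)
#' traj <- project_population(20000, 0.09, 2.39, rem)
#' attr(traj, "valid")
#' @export
project_population <- function(K, r_max, z, removals,
                               start_year = 1830, end_year = 2030) {
  years <- start_year:end_year
  rem <- setNames(rep(0, length(years)), years)
  hit <- as.character(removals$year)
  rem[hit[hit %in% names(rem)]] <-
    removals$removal[removals$year %in% years]
  N <- numeric(length(years))
  N[1] <- K
  valid <- TRUE
  for (i in seq_along(years)[-length(years)]) {
    N[i + 1] <- logistic_step(N[i], K, r_max, z, rem[i])
    if (N[i + 1] < 1) {
      valid <- FALSE
      N[(i + 1):length(years)] <- NA_real_
      break
    }
  }
  out <- tibble::tibble(year = years, abundance = N)
  attr(out, "valid") <- valid
  out
}

#' Solve for carrying capacity given recent abundance
#'
#' The assessment avoids a direct prior on carrying capacity by assigning a
#' prior to a recent abundance and back-calculating the trajectory: given a
#' removal history and growth parameters, the carrying capacity is the value
#' `K` whose forward projection passes through `n_recent` at `recent_year`.
#' Because abundance at any year is strictly increasing in `K`, the solution
#' is found by bisection on `[n_recent, k_upper]` (with doubling expansion of
#' the upper bound).
#'
#' @param n_recent abundance (whales) at `recent_year`.
#' @param recent_year calendar year of the recent-abundance prior.
#' @param r_max,z growth parameters.
#' @param removals removal series tibble (`year`, `removal`).
#' @param k_upper initial bisection upper bound (whales).
#' @param rel_tol relative tolerance on `K`.
#' @return carrying capacity (whales), or `NA` if no valid trajectory can
#'   attain `n_recent` (the draw is rejected, not an error).
#' @examples
#' rem <- tibble::tibble(year = 1830:1972, removal = 0)
#' solve_carrying_capacity(14264, 2008, 0.088, 2.39, rem) # equals n_recent
#' @export
solve_carrying_capacity <- function(n_recent, recent_year, r_max, z, removals,
                                    k_upper = 5e5, rel_tol = 1e-10) {
  stopifnot(n_recent > 0)
  years <- min(removals$year, 1830):recent_year
  value_at <- function(K) {
    traj <- project_population(K, r_max, z, removals,
                               start_year = years[1], end_year = recent_year)
    if (!attr(traj, "valid")) return(NA_real_)
    traj$abundance[traj$year == recent_year]
  }
  lo <- n_recent
  hi <- k_upper
  f_hi <- value_at(hi)
  expansions <- 0
  while ((is.na(f_hi) || f_hi < n_recent) && expansions < 6) {
    hi <- hi * 2
    f_hi <- value_at(hi)
    expansions <- expansions + 1
  }
  if (is.na(f_hi) || f_hi < n_recent) return(NA_real_)
  f_lo <- value_at(lo)
  if (!is.na(f_lo) && f_lo >= n_recent) return(lo)
  while (hi - lo > rel_tol * hi) {
    mid <- (lo + hi) / 2
    f <- value_at(mid)
    if (!is.na(f) && abs(f - n_recent) <= 1e-9 * n_recent) return(mid)
    if (!is.na(f) && f >= n_recent) hi <- mid else lo <- mid
  }
  hi
}

#' Abundance fraction at maximum production (MSYL)
#'
#' For the generalized logistic model, annual production
#' `N * r_max * (1 - (N/K)^z)` is maximized at
#' `N/K = (1 + z)^(-1/z)`, the maximum sustainable yield level. `z = 2.39`
#' puts it at 60% of carrying capacity, `z = 5.04` at 70% and `z = 11.22`
#' at 80%; `z = 1` recovers the ordinary logistic value of one half.
#'
#' @param z shape parameter, > 0.
#' @return fraction of carrying capacity (unitless in (0, 1)).
#' @examples
#' round(msyl_fraction(2.39), 2) # 0.6
#' @export
msyl_fraction <- function(z) {
  if (any(z <= 0)) stop("z must be positive", call. = FALSE)
  (1 + z)^(-1 / z)
}

#' Summaries of a single trajectory
#'
#' @param traj trajectory tibble from [project_population()] (must be valid).
#' @param K carrying capacity used to generate it.
#' @param status_years years at which to report `N/K`.
#' @return one-row tibble: `n_min`, `year_min`, `max_depletion`
#'   (`n_min / K`), and one `status_<year>` column per requested year.
#' @examples
#' rem <- tibble::tibble(year = 1830:1972, removal = 0)
#' trajectory_stats(project_population(1000, 0.1, 2.39, rem), 1000)
#' @export
trajectory_stats <- function(traj, K,
                             status_years = c(2006, 2008, 2012, 2019, 2030)) {
  if (!isTRUE(attr(traj, "valid"))) {
    stop("trajectory is invalid (crossed the extinction floor)", call. = FALSE)
  }
  i <- which.min(traj$abundance)
  status <- traj$abundance[match(status_years, traj$year)] / K
  out <- tibble::tibble(n_min = traj$abundance[i], year_min = traj$year[i],
                        max_depletion = traj$abundance[i] / K)
  for (j in seq_along(status_years)) {
    out[[paste0("status_", status_years[j])]] <- status[j]
  }
  out
}
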
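#' Modelling scenarios
#'
#' The assessment is organized around a reference case (RC) and a grid of
#' sensitivity scenarios that vary one ingredient at a time: the year whose
#' abundance receives the prior (D-1), the set of relative-abundance indices
#' fitted (D-2 to D-6), an informative life-history prior on the maximum
#' growth rate (D-7), exclusion of pre-modern catches and/or struck-and-lost
#' corrections (C-1 to C-3), a separate early-modern loss-rate prior
#' (C-4), alternative catch allocations (C-5 to C-7), a genetic lower bound
#' on minimum abundance (G-1, G-2), and alternative density-dependence shape
#' parameters (M-1, M-2).
#'
#' @param name scenario identifier, one of [scenario_names()].
#' @return `scenario_spec()` returns a one-row tibble with columns `name`,
#'   `recent_year`, `rmax_prior` (`"uniform"` or `"informative"`),
#'   `index_set` (list column of character vectors), `include_premodern`,
#'   `allocation`, `slr_mode`, `n_floor`, `z`.
#' @examples
#' scenario_spec("RC")
#' scenario_spec("M-2")$z # 11.22
#' @export
scenario_spec <- function(name) {
  reg <- .scenario_registry()
  if (!name %in% reg$name) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  }
  reg[reg$name == name, ]
}

#' @rdname scenario_spec
#' @export
scenario_names <- function() .scenario_registry()$name

#' @rdname scenario_spec
#' @details `averaging_scenarios()` returns the subset combined by
#'   Bayes-factor model averaging. Scenarios that fit different data (D-2 to
#'   D-6) have non-comparable likelihoods; scenarios that drop plausible data
#'   (C-1 to C-3) are exploratory only; and the genetic-floor scenarios
#'   (G-1, G-2) duplicate the reference case posterior almost exactly, so all
#'   of these are excluded from the average.
#' @export
averaging_scenarios <- function() {
  c("RC", "D-1", "D-7", "C-4", "C-5", "C-6", "C-7", "M-1", "M-2")
}

.scenario_registry <- function() {
  raw <- .read_fixture("scenarios.csv",
                       c("name", "recent_year", "rmax_prior", "index_set",
                         "include_premodern", "allocation", "slr_mode",
                         "n_floor", "z"))
  raw$index_set <- lapply(raw$index_set, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "+", fixed = TRUE)[[1]]
  })
  raw$include_premodern <- as.logical(raw$include_premodern)
  stopifnot(all(raw$z > 0), all(raw$n_floor >= 0),
            all(raw$slr_mode %in% c("both_eras", "none", "modern_only", "C4_split")),
            all(raw$allocation %in% c("core", "core+falkland", "fringe", "overlap")))
  raw
}
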
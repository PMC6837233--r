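#' Packaged whaling and abundance tables
#'
#' The assessment is driven entirely by published tables: pre-modern (1830 to
#' 1924) Brazilian shore-based and US pelagic catches reported as period
#' totals with a minimum and maximum reconstruction; modern (1904 to 1972)
#' annual catches under four alternative feeding-ground allocation
#' hypotheses (Core, Core + Falkland, Fringe, Overlap); ship-survey estimates
#' of absolute abundance in 2008 and 2012; and three indices of relative
#' abundance from the feeding grounds (FG) and breeding grounds (BG1, BG2).
#' These loaders read the versioned CSV fixtures shipped with the package and
#' return tibbles with a fixed column schema.
#'
#' A handful of per-row values in the modern catch table are typographically
#' ambiguous in the source; they were reconciled against the unambiguous
#' printed column totals (see [validate_checksums()]), which every packaged
#' column reproduces exactly.
#'
#' @return A tibble. `whale_catch_periods()` has columns `start_year`,
#'   `end_year`, `brazil_min`, `brazil_max`, `pelagic` (whales per period);
#'   `whale_modern_catches()` has `year`, `core`, `falkland`, `fringe`,
#'   `overlap` (whales per year, fractional under the Fringe hypothesis);
#'   `whale_abundance()` has `series_id` (`ABS`, `FG`, `BG1`, `BG2`), `year`,
#'   `estimate` (whales), `cv`.
#' @examples
#' whale_catch_periods()
#' sum(whale_modern_catches()$core) # 31170
#' @name whale_tables
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "whalesir")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture not found: ", file, call. = FALSE)
  }
  path
}

.read_fixture <- function(file, schema) {
  df <- tryCatch(
    read.csv(.extdata(file), stringsAsFactors = FALSE),
    error = function(e) stop("failed to read fixture '", file, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(schema, names(df))
  if (length(missing) > 0) {
    stop("fixture '", file, "' is garbled: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[schema])
}

#' @rdname whale_tables
#' @export
whale_catch_periods <- function() {
  out <- .read_fixture("premodern_catches.csv",
                       c("start_year", "end_year", "brazil_min", "brazil_max", "pelagic"))
  stopifnot(all(out$start_year <= out$end_year),
            all(out$brazil_min <= out$brazil_max),
            all(out$pelagic >= 0),
            all(out$start_year >= 1830), all(out$end_year <= 1924))
  out
}

#' @rdname whale_tables
#' @export
whale_modern_catches <- function() {
  out <- .read_fixture("modern_catches.csv",
                       c("year", "core", "falkland", "fringe", "overlap"))
  stopifnot(all(out$year >= 1904), all(out$year <= 1972),
            all(as.matrix(out[-1]) >= 0))
  out
}

#' @param series optional character vector restricting to some of
#'   `ABS`, `FG`, `BG1`, `BG2`.
#' @rdname whale_tables
#' @export
whale_abundance <- function(series = NULL) {
  out <- .read_fixture("abundance.csv", c("series_id", "year", "estimate", "cv"))
  stopifnot(all(out$estimate > 0), all(out$cv > 0))
  if (!is.null(series)) {
    out <- dplyr::filter(out, .data$series_id %in% series)
  }
  out
}

#' @rdname whale_tables
#' @export
whale_loss_rate_priors <- function() {
  .read_fixture("loss_rate_priors.csv",
                c("era_label", "family", "location", "scale",
                  "lower_trunc", "upper_trunc"))
}

# Printed column totals used as digitization checksums.
.printed_totals <- function() {
  tibble::tibble(
    column = c("brazil_min", "brazil_max", "pelagic",
               "premodern_total_min", "premodern_total_max",
               "core", "falkland", "fringe", "overlap"),
    printed = c(11481, 34708, 257, 11738, 34965,
                31170, 219, 31847, 27334)
  )
}

#' Validate the packaged catch tables against printed column totals
#'
#' Each catch table was digitized from a printed source whose total row is
#' unambiguous. This check recomputes every column total and compares it with
#' the printed value; the assessment refuses to run from tables that fail.
#'
#' @param periods pre-modern catch periods, as from [whale_catch_periods()].
#' @param modern modern annual catches, as from [whale_modern_catches()].
#' @return A tibble with columns `column`, `printed`, `computed`, `pass`,
#'   with attribute `pass` (scalar logical).
#' @examples
#' validate_checksums()
#' @export
validate_checksums <- function(periods = whale_catch_periods(),
                               modern = whale_modern_catches()) {
  if (nrow(periods) == 0 || nrow(modern) == 0) {
    stop("checksum validation failed: no rows", call. = FALSE)
  }
  computed <- c(
    brazil_min = sum(periods$brazil_min),
    brazil_max = sum(periods$brazil_max),
    pelagic = sum(periods$pelagic),
    premodern_total_min = sum(periods$brazil_min + periods$pelagic),
    premodern_total_max = sum(periods$brazil_max + periods$pelagic),
    core = sum(modern$core),
    falkland = sum(modern$falkland),
    fringe = sum(modern$fringe),
    overlap = sum(modern$overlap)
  )
  out <- .printed_totals()
  out$computed <- unname(computed[out$column])
  out$pass <- abs(out$computed - out$printed) < 1e-9
  attr(out, "pass") <- all(out$pass)
  out
}

.assert_checksums <- function(periods = whale_catch_periods(),
                              modern = whale_modern_catches()) {
  report <- validate_checksums(periods, modern)
  if (!attr(report, "pass")) {
    bad <- report$column[!report$pass]
    stop("catch table checksum failure for column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(report)
}
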
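#' Water-year calendar helpers
#'
#' Simulations use June--May water years. Synthetic series use exact 365-day
#' years (leap days dropped) so that water-year arithmetic is exact; a water
#' year is labelled by its starting calendar year (WY1991 = Jun 1991--May 1992).
#'
#' @param start_year first water year label (calendar year of the June start)
#' @param n_years number of water years
#' @return `water_year_dates()`: a `Date` vector of length `365 * n_years`.
#' @export
water_year_dates <- function(start_year, n_years) {
  d <- seq(as.Date(sprintf("%d-06-01", start_year)),
           by = "day", length.out = ceiling(n_years * 366.5))
  d <- d[format(d, "%m-%d") != "02-29"]
  d[seq_len(365L * n_years)]
}

#' @rdname water_year_dates
#' @param n_days number of daily records starting at June 1 of `start_year`
#' @return `water_year_index()`: integer vector mapping each day to its water
#'   year (1-based).
#' @export
water_year_index <- function(n_days, start_year = 1L) {
  ((seq_len(n_days) - 1L) %/% 365L) + 1L
}

#' @rdname water_year_dates
#' @param labels optional labels; defaults to `start_year + 0:(n_years-1)`
#' @return `water_year_labels()`: integer labels for each complete water year.
#' @export
water_year_labels <- function(start_year, n_years) {
  start_year + seq_len(n_years) - 1L
}

n_complete_years <- function(n_days) n_days %/% 365L
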
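#' Daily rainfall series
#'
#' A gauge record of daily precipitation. Dates must be strictly
#' increasing and rainfall non-negative; days may be absent (gaps), but
#' window operations error on gaps unless told to treat missing days as
#' dry.
#'
#' @param date `Date` vector, strictly increasing.
#' @param rain_mm Non-negative daily rainfall depth in mm.
#' @return A tibble with class `rain_series`.
#' @export
rain_series <- function(date, rain_mm) {
  date <- as.Date(date)
  if (anyNA(date) || anyNA(rain_mm)) stop("rain series must not contain NA.", call. = FALSE)
  if (is.unsorted(date, strictly = TRUE)) {
    stop("rain series dates must be strictly increasing.", call. = FALSE)
  }
  if (any(rain_mm < 0)) stop("rainfall must be non-negative.", call. = FALSE)
  structure(tibble::tibble(date = date, rain_mm = as.numeric(rain_mm)),
            class = c("rain_series", class(tibble::tibble())))
}

#' Read a rainfall CSV (columns `date`, `rain_mm`)
#' @param path CSV path with ISO-8601 dates.
#' @return A `rain_series`.
#' @export
read_rain_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rain_series(as.Date(df$date), df$rain_mm)
}

# month arithmetic with rollback so e.g. Jan 31 + 1 month -> Feb 28/29
add_months <- function(date, n) lubridate::add_with_rollback(date, base::months(n))

#' Mean monthly rainfall over a calendar-month window
#'
#' Sums daily rainfall over the half-open window `[window_start,
#' window_start + months)` (calendar months) and divides by the number of
#' window months. Division is always by `months`, never by elapsed days,
#' so a window spanning a leap day is still an average per calendar month.
#'
#' @param series A [rain_series()].
#' @param window_start First day of the window (`Date`).
#' @param months Number of calendar months in the window (default 12; a
#'   full year is used because of strong within-year seasonality).
#' @param missing `"error"` (default) to fail when any day in the window
#'   is absent from the series, or `"zero"` to treat absent days as dry.
#' @return Mean rainfall in mm per month.
#' @export
#' @examples
#' s <- rain_series(seq(as.Date("2000-01-01"), by = "day", length.out = 366),
#'                  rep(1, 366))
#' mean_monthly_rain(s, as.Date("2000-01-01"), 12) # 366/12
mean_monthly_rain <- function(series, window_start, months = 12L,
                              missing = c("error", "zero")) {
  missing <- match.arg(missing)
  window_start <- as.Date(window_start)
  window_end <- add_months(window_start, months) # half-open [start, end)
  idx <- series$date >= window_start & series$date < window_end
  if (missing == "error") {
    expected <- seq(window_start, window_end - 1, by = "day")
    absent <- expected[!expected %in% series$date]
    if (length(absent) > 0) {
      stop(sprintf("rain series does not cover the window [%s, %s): %d day(s) missing starting %s",
                   format(window_start), format(window_end),
                   length(absent), format(absent[1])), call. = FALSE)
    }
  }
  sum(series$rain_mm[idx]) / months
}

#' Developmental rainfall: the subject's first year of life
#'
#' Mean monthly rainfall over `[birth, birth + 12 months)`.
#'
#' @param series A [rain_series()].
#' @param birth Birth date.
#' @inheritParams mean_monthly_rain
#' @return mm per month.
#' @export
rain_development <- function(series, birth, missing = c("error", "zero")) {
  mean_monthly_rain(series, birth, months = 12L, missing = missing)
}

#' Adult rainfall: the year before a fertility event
#'
#' Mean monthly rainfall over the 12 months ending at the event anchor:
#' the first day of the cycling month (conception models), the pregnancy
#' end date (live-birth models), or the date the infant dies or reaches
#' 70 weeks (infant-survival models).
#'
#' @param series A [rain_series()].
#' @param event Anchor date; the window is `[event - 12 months, event)`.
#' @inheritParams mean_monthly_rain
#' @return mm per month.
#' @export
rain_adult <- function(series, event, missing = c("error", "zero")) {
  mean_monthly_rain(series, add_months(as.Date(event), -12L),
                    months = 12L, missing = missing)
}

#' Monthly proportional dominance-rank series
#'
#' One row per female-month giving the proportion of adult female
#' groupmates the female outranks (0 = bottom, 1 = top). Months are
#' stored as first-of-month `Date`s; gaps are allowed.
#'
#' @param female_id Female identifier.
#' @param month Month (`Date`, any day; floored to the first) or
#'   `"YYYY-MM"` strings.
#' @param rank Proportional rank in `[0, 1]`.
#' @return A tibble with class `rank_series`.
#' @export
rank_series <- function(female_id, month, rank) {
  month <- as_month(month)
  if (anyNA(rank) || any(rank < 0 | rank > 1)) {
    stop("ranks must lie in [0, 1] with no NA.", call. = FALSE)
  }
  df <- tibble::tibble(female_id = as.character(female_id),
                       month = month, rank = as.numeric(rank))
  if (anyDuplicated(df[c("female_id", "month")]) > 0) {
    stop("at most one rank entry per female-month.", call. = FALSE)
  }
  structure(df, class = c("rank_series", class(tibble::tibble())))
}

#' Read a rank CSV (columns `female_id`, `year_month`, `rank`)
#' @param path CSV path; `year_month` as `"YYYY-MM"`.
#' @return A `rank_series`.
#' @export
read_rank_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rank_series(df$female_id, df$year_month, df$rank)
}

as_month <- function(x) {
  if (is.character(x) && all(grepl("^\\d{4}-\\d{2}$", x))) {
    x <- paste0(x, "-01")
  }
  lubridate::floor_date(as.Date(x), "month")
}

#' Mean rank over a set of months (gap tolerant)
#'
#' Arithmetic mean of the female's available monthly ranks within the
#' requested months. Months with no rank entry are simply skipped, which
#' retains observations around occasional data gaps; it is an error for
#' the whole window to be empty (the record is then excluded upstream
#' with reason `missing_rank_window`).
#'
#' @param series A [rank_series()].
#' @param female Female identifier.
#' @param months `Date` vector of months (any day within each month).
#' @return Mean proportional rank.
#' @export
rank_window_mean <- function(series, female, months) {
  months <- as_month(months)
  r <- series$rank[series$female_id == as.character(female) &
                     series$month %in% months]
  if (length(r) == 0) {
    stop(sprintf("no rank data for female '%s' in window %s..%s",
                 female, format(min(months)), format(max(months))),
         call. = FALSE)
  }
  mean(r)
}

#' Three-month rank window centred on a month
#'
#' Mean of available ranks over the month itself plus the months
#' immediately before and after (used for rank at birth and for rank in
#' conception months).
#'
#' @inheritParams rank_window_mean
#' @param center Centre month.
#' @return Mean proportional rank.
#' @export
rank_window_3mo <- function(series, female, center) {
  center <- as_month(center)
  rank_window_mean(series, female,
                   c(add_months(center, -1L), center, add_months(center, 1L)))
}
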